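# Synthetic-data generators: Yule trees, trait histories simulated under
# the 2-state Markov model, NNI/jitter tree samples emulating a Bayesian
# posterior, and a fully assembled study-scale dataset with a planted
# character history.

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation: lineages split at per-lineage rate `birth`; the
#' process is stopped after the final split with one further exponential
#' waiting time, and all tips end at the present. When `depth` is given the
#' tree is rescaled so every root-to-tip path equals it.
#'
#' @param n_tips Number of tips (>= 3 for analyses; >= 2 accepted).
#' @param birth Speciation rate, > 0.
#' @param depth Optional root-to-tip depth after rescaling.
#' @return A binary, ultrametric `phylo` object.
#' @export
simulate_yule <- function(n_tips, birth = 1, depth = NULL) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop_binasr("n_tips must be >= 2")
  if (birth <= 0) stop_binasr("birth rate must be > 0")
  # active lineages: parent node and start time
  n_internal <- n_tips - 1L
  root <- n_tips + 1L
  next_internal <- root + 1L
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  edges <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  ne <- 0L
  t <- 0
  while (length(act_parent) < n_tips) {
    k <- length(act_parent)
    t <- t + rexp(1, birth * k)
    i <- sample.int(k, 1)
    node <- next_internal
    next_internal <- next_internal + 1L
    ne <- ne + 1L
    edges[ne, ] <- c(act_parent[i], node)
    elen[ne] <- t - act_start[i]
    act_parent <- c(act_parent[-i], node, node)
    act_start <- c(act_start[-i], t, t)
  }
  t <- t + rexp(1, birth * n_tips)
  for (i in seq_along(act_parent)) {
    ne <- ne + 1L
    edges[ne, ] <- c(act_parent[i], i)
    elen[ne] <- t - act_start[i]
  }
  tree <- structure(
    list(
      edge = edges[seq_len(ne), , drop = FALSE],
      edge.length = elen[seq_len(ne)],
      tip.label = paste0("t", seq_len(n_tips)),
      Nnode = n_internal
    ),
    class = "phylo", order = "cladewise"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (!is.null(depth)) {
    tree$edge.length <- tree$edge.length * (depth / t)
  }
  tree
}

#' Simulate a binary character along a tree
#'
#' Draws the root state from the model's stationary distribution and then
#' simulates the full continuous-time jump process along every branch, so
#' the realized number of change events (including multiple hits per
#' branch) is known exactly.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model A [rate_model()].
#' @return A list: `states` (tip-state tibble), `node_states` (integer
#'   vector over all nodes: the latent truth), `n_changes`, `n_gain`,
#'   `n_loss`.
#' @export
simulate_character <- function(tree, model) {
  check_branch_lengths(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  s <- numeric(ntot)
  pi <- stationary_dist(model)
  s[ntip + 1L] <- rbinom(1, 1, pi[2])
  n_gain <- 0L
  n_loss <- 0L
  for (e in rev(seq_len(nrow(edge)))) { # pre-order
    cur <- s[edge[e, 1L]]
    remaining <- elen[e]
    repeat {
      rate <- if (cur == 0) model$fw else model$bw
      w <- rexp(1, rate)
      if (w >= remaining) break
      remaining <- remaining - w
      if (cur == 0) {
        cur <- 1
        n_gain <- n_gain + 1L
      } else {
        cur <- 0
        n_loss <- n_loss + 1L
      }
    }
    s[edge[e, 2L]] <- cur
  }
  list(
    states = as_tip_states(tibble::tibble(
      taxon = tree$tip.label, state = as.integer(s[seq_len(ntip)])
    )),
    node_states = as.integer(s),
    n_changes = n_gain + n_loss,
    n_gain = n_gain,
    n_loss = n_loss
  )
}

#' Simulate a matrix of independent characters
#'
#' @inheritParams simulate_character
#' @param n_char Number of independent characters.
#' @return A taxa-by-characters 0/1 matrix with taxa as row names.
#' @export
simulate_characters <- function(tree, model, n_char) {
  m <- vapply(
    seq_len(n_char),
    function(i) simulate_character(tree, model)$node_states[seq_len(ape::Ntip(tree))],
    integer(ape::Ntip(tree))
  )
  rownames(m) <- tree$tip.label
  m
}

#' Perturb a tree into a posterior-like sample
#'
#' Generates `k` trees from a base tree by applying a Poisson-distributed
#' number of random NNI moves (via [phangorn::rNNI()]) and independent
#' log-normal branch-length multipliers (unit mean). This emulates the only
#' features of a Bayesian posterior sample that downstream summaries
#' consume: topology jitter, with reference clades absent from a fraction
#' of trees, and branch-length variation.
#'
#' @param tree A binary `phylo` with branch lengths.
#' @param k Number of trees.
#' @param nni_intensity Expected number of NNI moves per tree.
#' @param jitter_sd Standard deviation (log scale) of the branch-length
#'   multipliers.
#' @return A `multiPhylo` with attribute `"clade_freq"`: a tibble with the
#'   realized frequency of each base-tree clade across the sample.
#' @export
perturb_tree_sample <- function(tree, k, nni_intensity = 1, jitter_sd = 0.1) {
  if (!is_phylo(tree)) stop_binasr("expected a 'phylo' object")
  out <- vector("list", k)
  for (i in seq_len(k)) {
    ti <- tree
    nm <- rpois(1, nni_intensity)
    if (nm > 0) ti <- phangorn::rNNI(ti, moves = nm, n = 1)
    if (jitter_sd > 0) {
      mult <- exp(rnorm(length(ti$edge.length), -jitter_sd^2 / 2, jitter_sd))
      ti$edge.length <- ti$edge.length * mult
    }
    out[[i]] <- ti
  }
  out <- structure(out, class = "multiPhylo")
  # realized frequency of every base-tree clade across the sample
  base_sets <- descendant_tips(tree)
  ntip <- ape::Ntip(tree)
  base_keys <- vapply(
    (ntip + 1L):(ntip + tree$Nnode),
    function(v) clade_key(base_sets[[v]]), character(1)
  )
  counts <- setNames(numeric(length(base_keys)), base_keys)
  for (i in seq_len(k)) {
    sets <- descendant_tips(out[[i]])
    keys <- vapply(
      (ntip + 1L):(ntip + out[[i]]$Nnode),
      function(v) clade_key(sets[[v]]), character(1)
    )
    hit <- base_keys %in% keys
    counts[hit] <- counts[hit] + 1
  }
  attr(out, "clade_freq") <- tibble::tibble(
    node = (ntip + 1L):(ntip + tree$Nnode),
    n_tips = vapply(base_sets[(ntip + 1L):(ntip + tree$Nnode)], length, integer(1)),
    freq = as.numeric(counts) / k
  )
  out
}

#' Generate a study-scale synthetic dataset with a planted character history
#'
#' Builds a 58-tip binary tree whose clade structure mirrors the shape of
#' the cyanobacterial 16S study dataset: two basal unicellular lineages,
#' then a large clade whose ancestor gains multicellularity, containing
#' three named deep clades `C`, `AC` and `E` (all multicellular at their
#' roots). Seven unicellular reversal clades are planted inside `AC` and
#' `E`, with one regain of multicellularity inside an `E` reversal clade —
#' 9 planted transitions in total (1 gain, 7 losses, 1 regain), and the
#' clade block sizes are chosen so the tips split exactly 29:29 between the
#' states. A posterior-like sample of `k_trees` trees is generated with
#' [perturb_tree_sample()].
#'
#' Deep query nodes, matching the study's reporting: `node3` = ancestor of
#' `C` + `AC` + `E` (the multicellular gain), `node4` = ancestor of
#' `AC` + `E`, `node5` = ancestor of `E`. All three are multicellular in
#' the planted truth.
#'
#' @param seed Optional seed (set before all randomness).
#' @param k_trees Size of the perturbed tree sample.
#' @param nni_intensity,jitter_sd Perturbation parameters, see
#'   [perturb_tree_sample()].
#' @param depth Approximate root-to-tip depth of the consensus tree, in
#'   expected substitutions per site.
#' @return A list: `consensus` (phylo), `trees` (multiPhylo), `states`
#'   (tip-state tibble, 29:29), `queries` (list of exact-clade
#'   [node_query()]s for node3/4/5), `clades` (named list of tip sets),
#'   `truth` (planted transition counts and node states).
#' @export
simulate_study <- function(seed = NULL, k_trees = 1000, nni_intensity = 2,
                           jitter_sd = 0.15, depth = 0.45) {
  if (!is.null(seed)) set.seed(seed)

  lab <- function(prefix, n) paste0(prefix, "_", seq_len(n))
  yule_block <- function(n, prefix, d) {
    b <- simulate_yule(n, birth = 6, depth = d)
    b$tip.label <- lab(prefix, n)
    b
  }

  # newick fragment (no trailing ';') of a phylo or bare "label:length"
  frag <- function(x) {
    if (is_phylo(x)) sub(";$", "", write_newick(x)) else x
  }
  glue2 <- function(a, b, stem_a, stem_b) {
    parse_newick(sprintf(
      "(%s:%f,%s:%f);", frag(a), stem_a, frag(b), stem_b
    ))
  }
  # glue a list of subtrees onto a pectinate backbone with fixed stems
  glue_chain <- function(parts, stems, spine = 0.03) {
    cur <- parts[[length(parts)]]
    cur_stem <- stems[length(parts)]
    for (i in rev(seq_len(length(parts) - 1L))) {
      cur <- sprintf(
        "(%s:%f,%s:%f)", frag(parts[[i]]), stems[i], frag(cur), cur_stem
      )
      cur_stem <- spine
    }
    parse_newick(paste0(cur, ";"))
  }

  # -- clade AC: four unicellular reversal clades, each separated along the
  # spine by multicellular lineages so the planted losses stay independent
  # under parsimony
  ac <- glue_chain(
    list(
      yule_block(2, "AC_mc_a", 0.06),
      yule_block(5, "AC_uni_a", 0.08),
      yule_block(2, "AC_mc_b", 0.06),
      yule_block(3, "AC_uni_b", 0.08),
      yule_block(2, "AC_mc_c", 0.06),
      yule_block(2, "AC_uni_c", 0.06),
      yule_block(2, "AC_mc_d", 0.06),
      yule_block(2, "AC_uni_d", 0.06),
      "AC_mc_e_1:0.06"
    ),
    stems = c(0.04, 0.06, 0.04, 0.06, 0.04, 0.06, 0.04, 0.06, 0.06)
  )
  # -- clade E: three reversals (one containing a regain), interleaved with
  # multicellular blocks for the same reason
  e <- glue_chain(
    list(
      yule_block(5, "E_mc_a", 0.10),
      yule_block(8, "E_uni_a", 0.10),
      yule_block(4, "E_mc_b", 0.08),
      yule_block(4, "E_uni_b", 0.08),
      yule_block(3, "E_mc_c", 0.08),
      # fixed topology: the regain tip (E_uni_c_2) is nested between
      # unicellular tips so the planted loss + regain cannot collapse into
      # a single loss under parsimony
      "(E_uni_c_1:0.06,(E_uni_c_2:0.05,(E_uni_c_3:0.04,E_uni_c_4:0.04):0.02):0.02)",
      yule_block(2, "E_mc_d", 0.06)
    ),
    stems = c(0.04, 0.06, 0.04, 0.06, 0.04, 0.06, 0.06)
  )
  # -- clade C
  cc <- yule_block(5, "C_mc", 0.10)

  # -- backbone: (basal_1, (basal_2, (C, (AC, E))))
  ace <- glue2(ac, e, 0.06, 0.06) # node4 at root of (AC,E)
  big <- glue2(cc, ace, 0.07, 0.05) # node3 at root of (C,(AC,E))
  with_b2 <- glue2("basal_uni_2:0.30", big, 0.10, 0.08)
  consensus <- glue2("basal_uni_1:0.35", with_b2, 0.12, 0.05)

  # rescale to the requested depth and jitter lengths for realism
  depths <- ape::node.depth.edgelength(consensus)
  consensus$edge.length <- consensus$edge.length *
    (depth / max(depths[seq_len(ape::Ntip(consensus))]))
  consensus$edge.length <- consensus$edge.length *
    exp(rnorm(length(consensus$edge.length), -0.02, 0.2))

  tips <- consensus$tip.label
  uni <- c(
    grep("^basal_uni", tips, value = TRUE),
    grep("^AC_uni", tips, value = TRUE),
    grep("^E_uni", tips, value = TRUE)
  )
  regain <- "E_uni_c_2" # regains multicellularity inside a reversal clade
  uni <- setdiff(uni, regain)
  states <- as_tip_states(tibble::tibble(
    taxon = tips,
    state = as.integer(!tips %in% uni)
  ))
  stopifnot(sum(states$state == 0) == 29L, sum(states$state == 1) == 29L)

  clades <- list(
    C = grep("^C_mc", tips, value = TRUE),
    AC = grep("^AC_", tips, value = TRUE),
    E = grep("^E_", tips, value = TRUE)
  )
  queries <- list(
    node_query("node3", c(clades$C, clades$AC, clades$E), mode = "exact_clade"),
    node_query("node4", c(clades$AC, clades$E), mode = "exact_clade"),
    node_query("node5", clades$E, mode = "exact_clade")
  )

  trees <- perturb_tree_sample(consensus, k_trees,
    nni_intensity = nni_intensity, jitter_sd = jitter_sd
  )

  list(
    consensus = consensus,
    trees = trees,
    states = states,
    queries = queries,
    clades = clades,
    truth = list(
      n_changes = 9L, n_gain = 2L, n_loss = 7L,
      node_states = c(node3 = 1L, node4 = 1L, node5 = 1L),
      regain_tip = regain,
      seed = seed
    )
  )
}
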