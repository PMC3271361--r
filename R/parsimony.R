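# Unordered binary-character parsimony on rooted trees, implemented as a
# 2-state Sankoff dynamic program so polytomies and missing tips need no
# special cases. Branch lengths are ignored throughout.

BIG <- 1e9

# lean step-count path: post-order Sankoff up-pass only
fitch_prep <- function(tree) {
  check_node_numbering(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    edge = po$edge, ntip = ape::Ntip(tree),
    ntot = ape::Ntip(tree) + tree$Nnode,
    root = root_node(tree), tips = tree$tip.label
  )
}

fitch_steps_prepped <- function(prep, sv) {
  c0 <- numeric(prep$ntot)
  c1 <- numeric(prep$ntot)
  tipidx <- seq_len(prep$ntip)
  c0[tipidx] <- ifelse(!is.na(sv) & sv == 1, BIG, 0)
  c1[tipidx] <- ifelse(!is.na(sv) & sv == 0, BIG, 0)
  edge <- prep$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    a0 <- c0[ch]
    a1 <- c1[ch]
    c0[p] <- c0[p] + if (a0 < a1 + 1) a0 else a1 + 1
    c1[p] <- c1[p] + if (a1 < a0 + 1) a1 else a0 + 1
  }
  as.integer(round(min(c0[prep$root], c1[prep$root])))
}

# Core DP. Returns, per node and state s:
#   cost  C[v,s]: minimum changes within the subtree of v given v = s
#   down  D[v,s]: minimum changes outside the subtree (incl. the stem edge)
# plus conditional min/max counts of gains (0->1) and losses (1->0) inside
# the subtree over subtree-optimal reconstructions.
parsimony_engine <- function(tree, states) {
  if (!is_phylo(tree)) stop_binasr("expected a 'phylo' object")
  sv <- state_vector(tree, states)
  if (all(is.na(sv))) stop_binasr("all tip states missing")
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge

  c0 <- numeric(ntot)
  c1 <- numeric(ntot)
  c0[seq_len(ntip)] <- ifelse(!is.na(sv) & sv == 1, BIG, 0)
  c1[seq_len(ntip)] <- ifelse(!is.na(sv) & sv == 0, BIG, 0)

  # conditional directional counts inside the subtree, given the node state
  mng0 <- mng1 <- mxg0 <- mxg1 <- numeric(ntot) # gains | state 0 / 1
  mnl0 <- mnl1 <- mxl0 <- mxl1 <- numeric(ntot) # losses

  nedge <- nrow(edge)
  m0 <- numeric(nedge)
  m1 <- numeric(nedge)
  for (e in seq_len(nedge)) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    # messages: best subtree cost of child given parent state
    a0 <- c0[ch] # child kept 0
    a1 <- c1[ch] # child kept 1
    m0[e] <- min(a0, a1 + 1)
    m1[e] <- min(a0 + 1, a1)
    c0[p] <- c0[p] + m0[e]
    c1[p] <- c1[p] + m1[e]

    # directional counts over the argmin child states
    acc <- function(parent_state) {
      ok0 <- (a0 + (parent_state == 1)) <= (m_ <- if (parent_state == 0) m0[e] else m1[e]) + 1e-9
      ok1 <- (a1 + (parent_state == 0)) <= m_ + 1e-9
      gain_edge <- function(s_child) if (parent_state == 0 && s_child == 1) 1 else 0
      loss_edge <- function(s_child) if (parent_state == 1 && s_child == 0) 1 else 0
      g <- c(
        if (ok0) c(mng0[ch] + gain_edge(0)) else NULL,
        if (ok1) c(mng1[ch] + gain_edge(1)) else NULL
      )
      G <- c(
        if (ok0) c(mxg0[ch] + gain_edge(0)) else NULL,
        if (ok1) c(mxg1[ch] + gain_edge(1)) else NULL
      )
      l <- c(
        if (ok0) c(mnl0[ch] + loss_edge(0)) else NULL,
        if (ok1) c(mnl1[ch] + loss_edge(1)) else NULL
      )
      L <- c(
        if (ok0) c(mxl0[ch] + loss_edge(0)) else NULL,
        if (ok1) c(mxl1[ch] + loss_edge(1)) else NULL
      )
      list(ming = min(g), maxg = max(G), minl = min(l), maxl = max(L))
    }
    r0 <- acc(0)
    r1 <- acc(1)
    mng0[p] <- mng0[p] + r0$ming
    mxg0[p] <- mxg0[p] + r0$maxg
    mnl0[p] <- mnl0[p] + r0$minl
    mxl0[p] <- mxl0[p] + r0$maxl
    mng1[p] <- mng1[p] + r1$ming
    mxg1[p] <- mxg1[p] + r1$maxg
    mnl1[p] <- mnl1[p] + r1$minl
    mxl1[p] <- mxl1[p] + r1$maxl
  }

  root <- root_node(tree)
  steps <- min(c0[root], c1[root])

  # down pass (pre-order = reverse post-order edges)
  d0 <- numeric(ntot)
  d1 <- numeric(ntot)
  for (e in rev(seq_len(nedge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    s0 <- c0[p] - m0[e] # siblings' contribution given parent = 0
    s1 <- c1[p] - m1[e]
    d0[ch] <- min(d0[p] + s0, d1[p] + 1 + s1)
    d1[ch] <- min(d0[p] + 1 + s0, d1[p] + s1)
  }

  in0 <- (c0 + d0) <= steps + 1e-9
  in1 <- (c1 + d1) <= steps + 1e-9

  list(
    steps = as.integer(round(steps)), sv = sv, ntip = ntip, ntot = ntot,
    edge = edge, m0 = m0, m1 = m1,
    c0 = c0, c1 = c1, d0 = d0, d1 = d1, in0 = in0, in1 = in1,
    mng0 = mng0, mng1 = mng1, mxg0 = mxg0, mxg1 = mxg1,
    mnl0 = mnl0, mnl1 = mnl1, mxl0 = mxl0, mxl1 = mxl1,
    root = root
  )
}

#' Minimum number of character changes (Fitch parsimony)
#'
#' Generalized Fitch/Sankoff step count for a binary character on a rooted
#' tree; polytomies are handled natively and tips with missing state
#' contribute the full state set.
#'
#' @param tree A `phylo` object.
#' @param states A tip-state table covering all tips (see [as_tip_states()]).
#' @return Integer: the minimum number of state changes.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' st <- tibble::tibble(taxon = c("A", "B", "C", "D"), state = c(0, 0, 1, 1))
#' fitch_steps(tr, st)
#' @export
fitch_steps <- function(tree, states) {
  if (!is_phylo(tree)) stop_binasr("expected a 'phylo' object")
  sv <- state_vector(tree, states)
  if (all(is.na(sv))) stop_binasr("all tip states missing")
  fitch_steps_prepped(fitch_prep(tree), sv)
}

#' Most-parsimonious-reconstruction state sets per node
#'
#' For every node, the set of states occurring in at least one
#' most-parsimonious reconstruction (MPR). A node is *uniquely best* when the
#' set is a singleton and *equivocal* when it is \{0, 1\}.
#'
#' @inheritParams fitch_steps
#' @return An object of class `mpr` with elements `step_count`, `nodes` (a
#'   tibble: `node`, `type`, `set0`, `set1`, `uniquely_best`) and the ranges
#'   of directional transition counts over all MPRs.
#' @export
mpr_state_sets <- function(tree, states) {
  eng <- parsimony_engine(tree, states)
  nodes <- tibble::tibble(
    node = seq_len(eng$ntot),
    type = ifelse(seq_len(eng$ntot) <= eng$ntip, "tip", "internal"),
    label = c(tree$tip.label, rep(NA_character_, eng$ntot - eng$ntip)),
    set0 = eng$in0,
    set1 = eng$in1
  )
  nodes$uniquely_best <- xor(nodes$set0, nodes$set1)
  rng <- transition_ranges(eng)
  structure(
    list(
      step_count = eng$steps,
      nodes = nodes,
      min_n_gain = rng$min_gain, max_n_gain = rng$max_gain,
      min_n_loss = rng$min_loss, max_n_loss = rng$max_loss,
      tree = tree
    ),
    class = "mpr"
  )
}

#' @export
print.mpr <- function(x, ...) {
  cat(
    "MPR: ", x$step_count, " steps; gains in [", x$min_n_gain, ", ",
    x$max_n_gain, "], losses in [", x$min_n_loss, ", ", x$max_n_loss,
    "] over all reconstructions\n",
    sep = ""
  )
  invisible(x)
}

transition_ranges <- function(eng) {
  root <- eng$root
  ming <- minl <- Inf
  maxg <- maxl <- -Inf
  if (eng$in0[root]) {
    ming <- min(ming, eng$mng0[root])
    maxg <- max(maxg, eng$mxg0[root])
    minl <- min(minl, eng$mnl0[root])
    maxl <- max(maxl, eng$mxl0[root])
  }
  if (eng$in1[root]) {
    ming <- min(ming, eng$mng1[root])
    maxg <- max(maxg, eng$mxg1[root])
    minl <- min(minl, eng$mnl1[root])
    maxl <- max(maxl, eng$mxl1[root])
  }
  list(
    min_gain = as.integer(ming), max_gain = as.integer(maxg),
    min_loss = as.integer(minl), max_loss = as.integer(maxl)
  )
}

#' Directional transition counts under a chosen or enumerated MPR
#'
#' Counts gains (0 to 1) and losses (1 to 0) either for one deterministic
#' most-parsimonious reconstruction, or — with `policy = "enumerate"` — as
#' the minimum and maximum of each direction over *all* MPRs (computed by
#' dynamic programming, so large trees are fine). The "at least k reversals"
#' style of statement corresponds to the minimum loss count over MPRs.
#'
#' Tie-break policies for the single reconstruction: `"deltran"` keeps the
#' parent's state at ties (changes pushed tipward), `"acctran"` prefers a
#' change at ties (changes pulled rootward), `"minimize_losses"` picks among
#' MPRs one attaining the minimal loss count. Root ties resolve to state 0.
#'
#' @inheritParams fitch_steps
#' @param policy One of `"deltran"`, `"acctran"`, `"minimize_losses"`,
#'   `"enumerate"`.
#' @return A one-row tibble. For the single-reconstruction policies:
#'   `n_gain`, `n_loss`, `steps`, plus the reconstruction as an attribute
#'   `"node_states"`. For `"enumerate"`: `min_n_gain`, `max_n_gain`,
#'   `min_n_loss`, `max_n_loss`, `steps`.
#' @export
directional_transitions <- function(tree, states,
                                    policy = c(
                                      "deltran", "acctran",
                                      "minimize_losses", "enumerate"
                                    )) {
  policy <- match.arg(policy)
  eng <- parsimony_engine(tree, states)
  if (policy == "enumerate") {
    rng <- transition_ranges(eng)
    return(tibble::tibble(
      min_n_gain = rng$min_gain, max_n_gain = rng$max_gain,
      min_n_loss = rng$min_loss, max_n_loss = rng$max_loss,
      steps = eng$steps
    ))
  }
  asg <- resolve_reconstruction(eng, policy)
  pa <- asg[eng$edge[, 1L]]
  ch <- asg[eng$edge[, 2L]]
  out <- tibble::tibble(
    n_gain = sum(pa == 0L & ch == 1L),
    n_loss = sum(pa == 1L & ch == 0L),
    steps = eng$steps
  )
  attr(out, "node_states") <- asg
  out
}

# deterministic pre-order assignment of one MPR
resolve_reconstruction <- function(eng, policy) {
  asg <- rep(NA_integer_, eng$ntot)
  root <- eng$root
  if (policy == "minimize_losses") {
    cand <- c(if (eng$in0[root]) 0L, if (eng$in1[root]) 1L)
    vals <- vapply(cand, function(s) {
      if (s == 0L) eng$mnl0[root] else eng$mnl1[root]
    }, numeric(1))
    asg[root] <- cand[which.min(vals)] # ties resolve to state 0 (first)
  } else {
    asg[root] <- if (eng$in0[root]) 0L else 1L
  }
  edge <- eng$edge
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    ps <- asg[p]
    # child states consistent with a subtree-optimal reconstruction
    m <- if (ps == 0L) eng$m0[e] else eng$m1[e]
    ok0 <- (eng$c0[ch] + (ps == 1L)) <= m + 1e-9
    ok1 <- (eng$c1[ch] + (ps == 0L)) <= m + 1e-9
    if (ok0 && ok1) {
      asg[ch] <- switch(policy,
        deltran = ps,
        acctran = 1L - ps,
        minimize_losses = {
          l0 <- eng$mnl0[ch] + (ps == 1L)
          l1 <- eng$mnl1[ch]
          if (l0 <= l1) 0L else 1L
        }
      )
    } else {
      asg[ch] <- if (ok0) 0L else 1L
    }
  }
  asg
}
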