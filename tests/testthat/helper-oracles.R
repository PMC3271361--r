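# Independent oracles used across the suite: exhaustive enumeration for
# parsimony and likelihood (transition matrices via Matrix::expm, not the
# package's closed form), plus small random-instance generators.

# random rooted tree, optionally with polytomies and missing states
rand_instance <- function(n_tips, p_missing = 0.15, p_polytomy = 0.3) {
  tree <- ape::rtree(n_tips)
  if (runif(1) < p_polytomy && n_tips > 3) {
    # collapse a random internal edge into a polytomy
    tree$edge.length[sample(which(tree$edge[, 2] > n_tips), 1)] <- 0
    tree <- ape::di2multi(tree, tol = 1e-12)
    tree$edge.length <- tree$edge.length + 0.05
  }
  sv <- sample(c(0L, 1L), n_tips, replace = TRUE)
  sv[runif(n_tips) < p_missing] <- NA_integer_
  if (all(is.na(sv))) sv[1] <- 0L
  names(sv) <- tree$tip.label
  list(tree = tree, sv = sv, states = tibble::tibble(
    taxon = tree$tip.label, state = sv
  ))
}

# exhaustive parsimony: enumerate all assignments of internal nodes and
# missing tips; returns min steps, per-node MPR sets, directional ranges
brute_parsimony <- function(tree, sv) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  edge <- tree$edge
  free <- c(which(is.na(sv)), (ntip + 1L):ntot)
  asg <- integer(ntot)
  asg[seq_len(ntip)] <- sv
  best <- Inf
  sets <- matrix(FALSE, ntot, 2)
  ming <- minl <- Inf
  maxg <- maxl <- -Inf
  for (mask in 0:(2^length(free) - 1)) {
    asg[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
    ch <- sum(asg[edge[, 1]] != asg[edge[, 2]])
    if (ch < best) {
      best <- ch
      sets[, ] <- FALSE
      ming <- minl <- Inf
      maxg <- maxl <- -Inf
    }
    if (ch == best) {
      for (v in seq_len(ntot)) sets[v, asg[v] + 1L] <- TRUE
      g <- sum(asg[edge[, 1]] == 0 & asg[edge[, 2]] == 1)
      l <- sum(asg[edge[, 1]] == 1 & asg[edge[, 2]] == 0)
      ming <- min(ming, g)
      maxg <- max(maxg, g)
      minl <- min(minl, l)
      maxl <- max(maxl, l)
    }
  }
  list(
    steps = best, sets = sets,
    min_gain = ming, max_gain = maxg, min_loss = minl, max_loss = maxl
  )
}

# exhaustive likelihood: sum over all ancestral assignments, transition
# matrices from Matrix::expm
brute_loglik <- function(tree, sv, fw, bw) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  edge <- tree$edge
  Q <- matrix(c(-fw, fw, bw, -bw), 2, 2, byrow = TRUE)
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  pi <- c(bw, fw) / (fw + bw)
  free <- c(which(is.na(sv)), (ntip + 1L):ntot)
  asg <- integer(ntot)
  asg[seq_len(ntip)] <- sv
  tot <- 0
  for (mask in 0:(2^length(free) - 1)) {
    asg[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
    pr <- pi[asg[ntip + 1L] + 1L]
    for (e in seq_len(nrow(edge))) {
      pr <- pr * P[[e]][asg[edge[e, 1]] + 1L, asg[edge[e, 2]] + 1L]
    }
    tot <- tot + pr
  }
  log(tot)
}

# exhaustive marginal: P(node = 1 | tips)
brute_marginal_p1 <- function(tree, sv, fw, bw, node) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  edge <- tree$edge
  Q <- matrix(c(-fw, fw, bw, -bw), 2, 2, byrow = TRUE)
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  pi <- c(bw, fw) / (fw + bw)
  free <- c(which(is.na(sv)), (ntip + 1L):ntot)
  asg <- integer(ntot)
  asg[seq_len(ntip)] <- sv
  tot <- 0
  tot1 <- 0
  for (mask in 0:(2^length(free) - 1)) {
    asg[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
    pr <- pi[asg[ntip + 1L] + 1L]
    for (e in seq_len(nrow(edge))) {
      pr <- pr * P[[e]][asg[edge[e, 1]] + 1L, asg[edge[e, 2]] + 1L]
    }
    tot <- tot + pr
    if (asg[node] == 1L) tot1 <- tot1 + pr
  }
  tot1 / tot
}

# engine-agnostic tree equality: same labelled topology and branch lengths
expect_same_tree <- function(a, b, tol = 1e-9) {
  expect_setequal(a$tip.label, b$tip.label)
  keys_a <- sort(vapply(
    (ape::Ntip(a) + 1L):(ape::Ntip(a) + a$Nnode),
    function(v) paste(sort(ape::extract.clade(a, v)$tip.label), collapse = "|"),
    character(1)
  ))
  keys_b <- sort(vapply(
    (ape::Ntip(b) + 1L):(ape::Ntip(b) + b$Nnode),
    function(v) paste(sort(ape::extract.clade(b, v)$tip.label), collapse = "|"),
    character(1)
  ))
  expect_identical(keys_a, keys_b)
  if (!is.null(a$edge.length) && !is.null(b$edge.length)) {
    da <- ape::cophenetic.phylo(a)
    db <- ape::cophenetic.phylo(b)
    db <- db[rownames(da), colnames(da)]
    expect_lt(max(abs(da - db)), tol * max(1, max(da)))
  }
}
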