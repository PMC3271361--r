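# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_binasr <- function(..., class = "binasr_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

is_phylo <- function(x) inherits(x, "phylo")

as_multiphylo <- function(trees) {
  if (is_phylo(trees)) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  if (!inherits(trees, "multiPhylo")) {
    if (is.list(trees) && all(vapply(trees, is_phylo, logical(1)))) {
      class(trees) <- "multiPhylo"
    } else {
      stop_binasr("expected a 'phylo' or 'multiPhylo' object")
    }
  }
  if (length(trees) == 0L) stop_binasr("tree sample is empty")
  trees
}

# the node with no parent; usually ntip + 1, but not guaranteed for trees
# manipulated by other packages
root_node <- function(tree) {
  r <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])
  if (length(r) != 1L) stop_binasr("tree has no unique root")
  r
}

# canonical digest of a tip-label set, used to join nodes across trees
clade_key <- function(labels) {
  paste(sort(labels), collapse = "\r")
}

# descendant tip-label sets for every node (tips included), as a list
# indexed by node number
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  out <- vector("list", ntot)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# validate a tip-state table against a tree and return an integer vector
# (0, 1 or NA) ordered as tree$tip.label
state_vector <- function(tree, states) {
  tab <- as_tip_states(states)
  idx <- match(tree$tip.label, tab$taxon)
  if (anyNA(idx)) {
    missing <- tree$tip.label[is.na(idx)]
    stop_binasr(
      "tips absent from the state table: ",
      paste(missing, collapse = ", ")
    )
  }
  out <- tab$state[idx]
  names(out) <- tree$tip.label
  out
}

check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop_binasr("tree has no branch lengths; likelihood methods require them")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_binasr("branch lengths must be present and non-negative")
  }
  invisible(tree)
}

check_node_numbering <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  if (max(tree$edge) != ntot || min(tree$edge) < 1L) {
    stop_binasr(
      "tree node numbering is not compact (1..ntip+nnode); ",
      "re-parse it, e.g. parse_newick(write_newick(tree))"
    )
  }
  invisible(tree)
}

# pre-computed post-order structure for the likelihood kernel
postorder_prep <- function(tree) {
  check_branch_lengths(tree)
  check_node_numbering(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    edge = po$edge,
    elen = po$edge.length,
    ntip = ape::Ntip(tree),
    nnode = tree$Nnode,
    root = root_node(tree),
    tips = tree$tip.label
  )
}

# per-tip conditional likelihoods for one or more characters; `states` is a
# tibble (taxon, state) or a taxa x characters matrix of 0/1/NA
tip_partials <- function(tree, states) {
  if (is.matrix(states)) {
    if (is.null(rownames(states))) {
      stop_binasr("character matrix must have taxa as row names")
    }
    idx <- match(tree$tip.label, rownames(states))
    if (anyNA(idx)) {
      stop_binasr(
        "tips absent from the character matrix: ",
        paste(tree$tip.label[is.na(idx)], collapse = ", ")
      )
    }
    m <- states[idx, , drop = FALSE]
  } else {
    m <- matrix(state_vector(tree, states), ncol = 1)
  }
  storage.mode(m) <- "double"
  tip0 <- ifelse(is.na(m) | m == 0, 1, 0)
  tip1 <- ifelse(is.na(m) | m == 1, 1, 0)
  if (any(colSums(tip0 * tip1) == nrow(m))) {
    stop_binasr("a character has no non-missing observations")
  }
  list(tip0 = tip0, tip1 = tip1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
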