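#' Define a reference node by its tip content
#'
#' A node query names an ancestor of interest by a set of tip labels.
#' `"exact_clade"` matching finds the node whose descendant tip set equals
#' the query set exactly (and reports the node as absent otherwise), which
#' reproduces the "node absent in a fraction of trees" accounting of
#' pie-chart summaries. `"mrca"` matching takes the most recent common
#' ancestor of the query tips, which exists in every tree, and is the usual
#' semantics of Bayesian node queries; it also tolerates partial tip lists.
#'
#' @param name Query name, e.g. `"node3"`.
#' @param tips Character vector of tip labels (non-empty).
#' @param mode `"exact_clade"` or `"mrca"`.
#' @return An object of class `node_query`.
#' @export
node_query <- function(name, tips, mode = c("exact_clade", "mrca")) {
  mode <- match.arg(mode)
  tips <- unique(as.character(tips))
  if (!length(tips)) stop_binasr("query tip set is empty")
  structure(list(name = name, tips = tips, mode = mode), class = "node_query")
}

as_query_list <- function(queries) {
  if (inherits(queries, "node_query")) return(list(queries))
  if (!is.list(queries) || !all(vapply(queries, inherits, logical(1), "node_query"))) {
    stop_binasr("queries must be a node_query or a list of them")
  }
  queries
}

#' Locate a query node in one tree
#'
#' @param tree A `phylo` object.
#' @param query A [node_query()].
#' @return The matched node number, or `NA` when an exact-clade query has no
#'   matching node in this tree.
#' @export
match_node <- function(tree, query) {
  missing <- setdiff(query$tips, tree$tip.label)
  if (length(missing)) {
    stop_binasr("query tips missing from tree: ", paste(missing, collapse = ", "))
  }
  if (length(query$tips) >= ape::Ntip(tree)) {
    stop_binasr("query tip set must be a strict subset of the tree's tips")
  }
  if (query$mode == "mrca") {
    if (length(query$tips) == 1L) {
      return(match(query$tips, tree$tip.label))
    }
    return(ape::getMRCA(tree, query$tips))
  }
  key <- clade_key(query$tips)
  sets <- descendant_tips(tree)
  for (v in (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)) {
    if (clade_key(sets[[v]]) == key) return(v)
  }
  NA_integer_
}

#' Aggregate maximum-likelihood reconstructions over a tree sample
#'
#' For every tree in the sample, obtains transition rates (a fixed
#' [rate_model()], a grid token, or `"estimate"` for an independent ML fit
#' per tree), runs [marginal_asr()], and records the query-node state
#' probabilities where the node is matched. Per-query means are taken over
#' the matched trees; the fraction of trees where an exact-clade node is
#' absent is reported separately, as are trees where the fit failed.
#'
#' @param trees A `multiPhylo` (or single `phylo`) with branch lengths.
#' @param states A tip-state table.
#' @param queries A [node_query()] or list of them.
#' @param rates `"estimate"`, a grid name (`"F1"`..`"F6"`), an `"fw:bw"`
#'   literal, or a `rate_model`.
#' @param kind Model kind for per-tree estimation.
#' @param n_starts Starting points per fit (passed to [fit_mk()]).
#' @param trace Keep the per-tree, per-query probabilities as attribute
#'   `"trace"`.
#' @return An `asr_summary` tibble: `query`, `method`, `n_trees`,
#'   `n_matched`, `n_failed`, `absent_frac`, `mean_p0`, `mean_p1`.
#' @export
summarize_ml <- function(trees, states, queries, rates = "estimate",
                         kind = c("AsymmMk", "MK1"), n_starts = 5,
                         trace = FALSE) {
  kind <- match.arg(kind)
  trees <- as_multiphylo(trees)
  queries <- as_query_list(queries)
  spec <- resolve_rates(rates)
  estimate <- identical(spec, "estimate")
  qn <- vapply(queries, `[[`, character(1), "name")

  rows <- vector("list", length(trees))
  n_failed <- 0L
  for (i in seq_along(trees)) {
    tree <- trees[[i]]
    res <- tryCatch(
      {
        model <- if (estimate) {
          fit_mk(tree, states, kind = kind, n_starts = n_starts)$model
        } else {
          spec
        }
        rec <- marginal_asr(tree, states, model)
        nodes <- vapply(queries, function(q) match_node(tree, q), integer(1))
        tibble::tibble(
          tree = i,
          query = qn,
          node = nodes,
          p0 = ifelse(is.na(nodes), NA_real_, rec$nodes$p0[nodes]),
          p1 = ifelse(is.na(nodes), NA_real_, rec$nodes$p1[nodes])
        )
      },
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- res
  }
  tr <- dplyr::bind_rows(rows)
  if (nrow(tr) == 0L) stop_binasr("all trees failed")
  out <- tr |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(
      n_trees = length(trees),
      n_matched = sum(!is.na(.data$node)),
      n_failed = n_failed,
      absent_frac = mean(is.na(.data$node)), # among successfully evaluated trees
      mean_p0 = mean(.data$p0, na.rm = TRUE),
      mean_p1 = mean(.data$p1, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = "ML", .after = "query")
  out <- out[match(qn, out$query), ]
  class(out) <- c("asr_summary", class(out))
  if (trace) attr(out, "trace") <- tr
  out
}

#' Aggregate parsimony reconstructions over a tree sample
#'
#' For every tree, computes MPR state sets and classifies each query node as
#' uniquely state 0, uniquely state 1, equivocal (both states occur among
#' MPRs), or absent (exact-clade query not present in that tree). The four
#' fractions sum to one.
#'
#' @inheritParams summarize_ml
#' @return An `asr_summary` tibble: `query`, `method`, `n_trees`,
#'   `n_matched`, `absent_frac`, `unique0_frac`, `unique1_frac`,
#'   `equivocal_frac`.
#' @export
summarize_mp <- function(trees, states, queries, trace = FALSE) {
  trees <- as_multiphylo(trees)
  queries <- as_query_list(queries)
  qn <- vapply(queries, `[[`, character(1), "name")
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tree <- trees[[i]]
    mpr <- mpr_state_sets(tree, states)
    nodes <- vapply(queries, function(q) match_node(tree, q), integer(1))
    cls <- ifelse(
      is.na(nodes), "absent",
      ifelse(mpr$nodes$set0[nodes] & mpr$nodes$set1[nodes], "equivocal",
        ifelse(mpr$nodes$set0[nodes], "unique0", "unique1")
      )
    )
    rows[[i]] <- tibble::tibble(tree = i, query = qn, class = cls)
  }
  tr <- dplyr::bind_rows(rows)
  out <- tr |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(
      n_trees = length(trees),
      n_matched = sum(.data$class != "absent"),
      absent_frac = mean(.data$class == "absent"),
      unique0_frac = mean(.data$class == "unique0"),
      unique1_frac = mean(.data$class == "unique1"),
      equivocal_frac = mean(.data$class == "equivocal"),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = "MP", .after = "query")
  out <- out[match(qn, out$query), ]
  class(out) <- c("asr_summary", class(out))
  if (trace) attr(out, "trace") <- tr
  out
}
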