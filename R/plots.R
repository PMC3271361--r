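# ggplot2 visualisations of result objects (convenience surface)

#' Plot an ancestral-state summary as stacked per-node bars
#'
#' The bar decomposition mirrors pie-chart summaries over a tree sample:
#' for ML summaries, mean state probabilities scaled by the fraction of
#' trees in which the node was matched, with the absent fraction shown in
#' white/grey; for MP summaries, the uniquely-best, equivocal and absent
#' fractions.
#'
#' @param object An `asr_summary` from [summarize_ml()] or [summarize_mp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asr_summary <- function(object, ...) {
  if ("mean_p1" %in% names(object)) {
    long <- tibble::tibble(
      query = rep(object$query, 3),
      part = rep(c("state 0", "state 1", "node absent"), each = nrow(object)),
      frac = c(
        object$mean_p0 * (1 - object$absent_frac),
        object$mean_p1 * (1 - object$absent_frac),
        object$absent_frac
      )
    )
  } else {
    long <- tibble::tibble(
      query = rep(object$query, 4),
      part = rep(
        c("state 0", "state 1", "equivocal", "node absent"),
        each = nrow(object)
      ),
      frac = c(
        object$unique0_frac, object$unique1_frac,
        object$equivocal_frac, object$absent_frac
      )
    )
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$query, y = .data$frac, fill = .data$part
  )) +
    ggplot2::geom_col(colour = "grey30", width = 0.7) +
    ggplot2::scale_fill_manual(values = c(
      "state 0" = "gold", "state 1" = "black",
      "equivocal" = "grey60", "node absent" = "white"
    )) +
    ggplot2::labs(x = NULL, y = "fraction over tree sample", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the observed vs shuffled parsimony-step distributions
#'
#' @param object A `conservatism_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservatism_test <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$steps, fill = .data$distribution
  )) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      position = "identity", alpha = 0.6, binwidth = 1
    ) +
    ggplot2::geom_vline(
      xintercept = c(object$observed_mean, object$null_mean),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "parsimony steps", y = "density",
      title = sprintf("conservatism test: p = %.4g", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot posterior distributions of node state-1 probabilities
#'
#' One histogram panel per query node of the per-draw probability of the
#' multicellular state, the posterior analogue of per-node pie charts.
#'
#' @param object An `rjmcmc_sample` with queries.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rjmcmc_sample <- function(object, ...) {
  cols <- grep("^p1_", names(object$draws), value = TRUE)
  if (!length(cols)) stop_binasr("sample has no query columns to plot")
  d <- tidyr::pivot_longer(
    object$draws[, cols],
    dplyr::all_of(cols),
    names_to = "query", values_to = "p1", names_prefix = "p1_"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p1)) +
    ggplot2::geom_histogram(binwidth = 0.02, fill = "black") +
    ggplot2::facet_wrap(~query) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = "posterior probability of state 1", y = "draws"
    ) +
    ggplot2::theme_minimal()
}
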