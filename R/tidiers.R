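# broom-style tidiers for the package's fitted objects

#' @rdname tidiers
#' @name tidiers
#' @title Tidy and glance methods
#' @description Broom-style one-row (`glance()`) and long-format (`tidy()`)
#'   summaries of the package's result objects.
#' @param x A fitted object.
#' @param ... Unused.
NULL

#' @rdname tidiers
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("fw", "bw"),
    estimate = c(x$model$fw, x$model$bw)
  )
}

#' @rdname tidiers
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, fw = x$model$fw, bw = x$model$bw,
    logLik = x$loglik, boundary = x$boundary,
    convergence = x$convergence, n_starts = nrow(x$starts)
  )
}

#' @rdname tidiers
#' @export
tidy.marginal_asr <- function(x, ...) x$nodes

#' @rdname tidiers
#' @export
tidy.mpr <- function(x, ...) x$nodes

#' @rdname tidiers
#' @export
glance.mpr <- function(x, ...) {
  tibble::tibble(
    step_count = x$step_count,
    min_n_gain = x$min_n_gain, max_n_gain = x$max_n_gain,
    min_n_loss = x$min_n_loss, max_n_loss = x$max_n_loss
  )
}

#' @rdname tidiers
#' @export
tidy.rjmcmc_sample <- function(x, ...) x$draws

#' @rdname tidiers
#' @export
glance.rjmcmc_sample <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    iterations = x$config$iterations,
    burnin = x$config$burnin,
    thin = x$config$thin,
    p_asymm = mean(x$draws$model == "AsymmMk"),
    mean_fw = mean(x$draws$fw),
    mean_bw = mean(x$draws$bw),
    mean_m = mean(x$draws$m),
    seed = x$config$seed %||% NA_integer_
  )
}

#' @rdname tidiers
#' @export
tidy.conservatism_test <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(distribution = "observed", steps = x$observed),
    tibble::tibble(distribution = "null", steps = x$null)
  )
}

#' @rdname tidiers
#' @export
glance.conservatism_test <- function(x, ...) {
  tibble::tibble(
    observed_mean = x$observed_mean,
    null_mean = x$null_mean,
    p_value = x$p_value,
    n_trees = length(x$observed),
    n_shuffles = x$n_shuffles,
    statistic = x$statistic,
    seed = x$seed %||% NA_integer_
  )
}
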