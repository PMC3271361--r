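#' Construct a one- or two-rate binary Markov model
#'
#' `rate_model()` describes a continuous-time 2-state Markov chain with
#' forward rate `fw` (state 0 to 1, e.g. unicellular to multicellular) and
#' backward rate `bw` (1 to 0), both per unit branch length. `kind` is
#' `"MK1"` when the two rates are constrained equal and `"AsymmMk"`
#' otherwise. The stationary distribution is `pi = (bw, fw) / (fw + bw)`,
#' which is also the root prior used by all likelihood computations.
#'
#' @param fw Forward rate, > 0.
#' @param bw Backward rate, > 0; defaults to `fw`.
#' @param kind `"MK1"` or `"AsymmMk"`; inferred from the rates when `NULL`.
#' @return An object of class `rate_model`.
#' @examples
#' rate_model(1.62, 2.99)
#' @export
rate_model <- function(fw, bw = fw, kind = NULL) {
  if (!is.numeric(fw) || !is.numeric(bw) || fw <= 0 || bw <= 0) {
    stop_binasr("rates must be positive")
  }
  if (is.null(kind)) kind <- if (isTRUE(all.equal(fw, bw))) "MK1" else "AsymmMk"
  kind <- match.arg(kind, c("MK1", "AsymmMk"))
  if (kind == "MK1" && !isTRUE(all.equal(fw, bw))) {
    stop_binasr("MK1 requires fw == bw")
  }
  structure(list(kind = kind, fw = fw, bw = bw), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(x$kind, " model: fw = ", format(x$fw), ", bw = ", format(x$bw), "\n",
    sep = ""
  )
  invisible(x)
}

#' Stationary distribution of a rate model
#' @param model A `rate_model`.
#' @return Numeric vector `c(pi0, pi1)`.
#' @export
stationary_dist <- function(model) {
  s <- model$fw + model$bw
  c(pi0 = model$bw / s, pi1 = model$fw / s)
}

#' The fixed transition-rate grid F1-F6
#'
#' Six fixed rate settings used to probe the sensitivity of reconstructions
#' to the transition rates: four asymmetric settings (F1-F4, AsymmMk) and two
#' symmetric ones (F5-F6, MK1).
#'
#' @return A tibble with columns `name`, `fw`, `bw`, `kind`.
#' @export
rate_grid <- function() {
  tibble::tibble(
    name = paste0("F", 1:6),
    fw = c(0.90, 2.70, 5.40, 0.45, 0.90, 2.70),
    bw = c(2.70, 0.90, 0.45, 5.40, 0.90, 2.70),
    kind = c(rep("AsymmMk", 4), rep("MK1", 2))
  )
}

#' Resolve a rate specification token
#'
#' Accepts a `rate_model`, the string `"estimate"`, a grid name (`"F1"` ..
#' `"F6"`), or an explicit `"fw:bw"` literal such as `"5.4:0.45"`.
#'
#' @param x The specification.
#' @return A `rate_model`, or the string `"estimate"`.
#' @export
resolve_rates <- function(x) {
  if (inherits(x, "rate_model")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(rate_model(x[1], x[2]))
  if (is.character(x) && length(x) == 1L) {
    if (identical(x, "estimate")) return("estimate")
    g <- rate_grid()
    hit <- match(x, g$name)
    if (!is.na(hit)) {
      return(rate_model(g$fw[hit], g$bw[hit], kind = g$kind[hit]))
    }
    if (grepl("^[0-9.eE+-]+:[0-9.eE+-]+$", x)) {
      v <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
      if (!anyNA(v)) return(rate_model(v[1], v[2]))
    }
  }
  stop_binasr("unknown rate specification: ", deparse(x))
}

#' Transition probability matrix of the 2-state chain
#'
#' Closed form for the matrix exponential of the binary rate matrix:
#' `P00(t) = (bw + fw exp(-(fw+bw) t)) / (fw+bw)` and
#' `P11(t) = (fw + bw exp(-(fw+bw) t)) / (fw+bw)`.
#'
#' @param model A `rate_model`.
#' @param t Branch length, >= 0.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @export
transition_prob <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop_binasr("branch length must be a single non-negative number")
  }
  fw <- model$fw
  bw <- model$bw
  s <- fw + bw
  e <- exp(-s * t)
  p00 <- (bw + fw * e) / s
  p11 <- (fw + bw * e) / s
  matrix(c(p00, 1 - p11, 1 - p00, p11),
    nrow = 2,
    dimnames = list(c("0", "1"), c("0", "1"))
  )
}

#' Log-likelihood of tip states under a rate model
#'
#' Felsenstein pruning over the rooted tree, with the root prior fixed at
#' the model's stationary distribution. Tips with missing state contribute
#' the conditional vector (1, 1). For a matrix of characters the joint
#' (summed) log-likelihood is returned.
#'
#' @param tree A `phylo` object with branch lengths on all edges.
#' @param states A tip-state table, or a taxa-by-characters 0/1/NA matrix
#'   with taxa as row names.
#' @param model A `rate_model`.
#' @return The natural-log likelihood.
#' @export
mk_loglik <- function(tree, states, model) {
  prep <- postorder_prep(tree)
  tp <- tip_partials(tree, states)
  mk_loglik_prepped(prep, tp, model$fw, model$bw)
}

mk_loglik_prepped <- function(prep, tp, fw, bw) {
  C_mk_loglik(
    prep$edge, prep$elen, prep$ntip, prep$nnode,
    tp$tip0, tp$tip1, fw, bw, prep$root
  )
}

#' Marginal ancestral state reconstruction
#'
#' For every node, the posterior probability of each state given all tip
#' data and the model (inside-outside message passing; because every
#' 2-state chain at stationarity is reversible, this equals re-rooting the
#' tree at each node). Reported node probabilities are the normalized
#' "relative likelihoods" used in pie-chart summaries.
#'
#' @inheritParams mk_loglik
#' @param states A tip-state table (single character).
#' @return An object of class `marginal_asr`: list with `nodes` (tibble
#'   `node`, `type`, `label`, `p0`, `p1`), `loglik` and `model`.
#' @export
marginal_asr <- function(tree, states, model) {
  check_branch_lengths(tree)
  sv <- state_vector(tree, states)
  if (all(is.na(sv))) stop_binasr("all tip states missing")
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  nedge <- nrow(edge)
  fw <- model$fw
  bw <- model$bw
  s <- fw + bw
  pi <- c(bw, fw) / s

  # up-pass: normalized partials + per-node log scale
  up <- matrix(1, ntot, 2)
  up[seq_len(ntip), 1] <- ifelse(!is.na(sv) & sv == 1, 0, 1)
  up[seq_len(ntip), 2] <- ifelse(!is.na(sv) & sv == 0, 0, 1)
  logsc <- numeric(ntot)
  # per-edge messages toward the parent, kept for the down-pass
  msg <- matrix(NA_real_, nedge, 2)
  P <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    ex <- exp(-s * elen[e])
    p00 <- (bw + fw * ex) / s
    p11 <- (fw + bw * ex) / s
    Pe <- matrix(c(p00, 1 - p11, 1 - p00, p11), 2, 2)
    P[[e]] <- Pe
    m <- Pe %*% up[ch, ]
    msg[e, ] <- m
    up[p, ] <- up[p, ] * m
    mx <- max(up[p, ])
    if (mx > 0 && mx < 1e-280) {
      up[p, ] <- up[p, ] / mx
      logsc[p] <- logsc[p] + log(mx)
    }
  }
  root <- root_node(tree)
  lik_root <- sum(pi * up[root, ])
  loglik <- log(lik_root) + sum(logsc)

  # down-pass: for each node the likelihood of the data outside its subtree
  # given its state (unnormalized; per-node normalization absorbs scaling)
  down <- matrix(NA_real_, ntot, 2)
  down[root, ] <- pi
  children <- split(seq_len(nedge), edge[, 1L])
  for (e in rev(seq_len(nedge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    sib_e <- setdiff(children[[as.character(p)]], e)
    sib <- c(1, 1)
    for (se in sib_e) sib <- sib * msg[se, ]
    h <- down[p, ] * sib # outside info at parent, for each parent state
    down[ch, ] <- as.numeric(t(P[[e]]) %*% h)
    mx <- max(down[ch, ])
    if (mx > 0) down[ch, ] <- down[ch, ] / mx
  }

  post <- up * down
  norm <- rowSums(post)
  if (any(norm <= 0 | !is.finite(norm))) {
    stop_binasr("zero posterior mass at a node; inconsistent data")
  }
  post <- post / norm
  nodes <- tibble::tibble(
    node = seq_len(ntot),
    type = ifelse(seq_len(ntot) <= ntip, "tip", "internal"),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    p0 = post[, 1],
    p1 = post[, 2]
  )
  structure(
    list(nodes = nodes, loglik = loglik, model = model, tree = tree),
    class = "marginal_asr"
  )
}

#' @export
print.marginal_asr <- function(x, ...) {
  cat("Marginal ancestral reconstruction (", x$model$kind, "), lnL = ",
    format(x$loglik),
    "\n",
    sep = ""
  )
  print(x$nodes, ...)
  invisible(x)
}

#' Maximum-likelihood estimation of transition rates
#'
#' Maximizes the pruning log-likelihood over log-rates with bounded
#' quasi-Newton (L-BFGS-B) from multiple starting points spanning 1e-3 to
#' 1e2. Rates are bounded in `[1e-8, 1e3]`; fits ending within numerical
#' reach of a bound are flagged `boundary`. Ties between starts (lnL within
#' 1e-8) are broken toward the lowest `fw`.
#'
#' @inheritParams mk_loglik
#' @param kind `"AsymmMk"` (free forward/backward rates) or `"MK1"` (one
#'   shared rate).
#' @param n_starts Number of starting points (>= 1).
#' @return An object of class `mk_fit`: list with `model`, `loglik`,
#'   `kind`, `boundary`, `convergence` and a tibble `starts`.
#' @export
fit_mk <- function(tree, states, kind = c("AsymmMk", "MK1"), n_starts = 5) {
  kind <- match.arg(kind)
  prep <- postorder_prep(tree)
  tp <- tip_partials(tree, states)
  fit_mk_prepped(prep, tp, kind, n_starts)
}

fit_mk_prepped <- function(prep, tp, kind, n_starts = 5) {
  lb <- log(1e-8)
  ub <- log(1e3)
  npar <- if (kind == "MK1") 1L else 2L
  negll <- function(lpar) {
    r <- exp(lpar)
    fw <- r[1]
    bw <- r[npar]
    v <- mk_loglik_prepped(prep, tp, fw, bw)
    if (!is.finite(v)) 1e10 else -v
  }
  base <- exp(seq(log(1e-3), log(1e2), length.out = max(n_starts, 2L)))[
    seq_len(max(n_starts, 1L))
  ]
  starts <- lapply(base, function(r) rep(log(r), npar))
  if (npar == 2L && length(starts) >= 4L) {
    # include asymmetric starts
    starts[[2]] <- log(c(0.1, 3))
    starts[[4]] <- log(c(3, 0.1))
  }
  rows <- vector("list", length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    o <- tryCatch(
      optim(starts[[i]], negll,
        method = "L-BFGS-B", lower = lb, upper = ub,
        control = list(factr = 1e-8 / .Machine$double.eps, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(o)) {
      rows[[i]] <- tibble::tibble(
        start_rate = base[i], fw = NA_real_, bw = NA_real_,
        loglik = NA_real_, convergence = NA_integer_
      )
      next
    }
    fw <- exp(o$par[1])
    bw <- exp(o$par[npar])
    rows[[i]] <- tibble::tibble(
      start_rate = base[i], fw = fw, bw = bw,
      loglik = -o$value, convergence = o$convergence
    )
    better <- is.null(best) ||
      (-o$value > best$loglik + 1e-8) ||
      (abs(-o$value - best$loglik) <= 1e-8 && fw < best$fw)
    if (better) {
      best <- list(fw = fw, bw = bw, loglik = -o$value, conv = o$convergence)
    }
  }
  if (is.null(best) || !is.finite(best$loglik) || best$loglik <= -1e9) {
    stop_binasr("likelihood not finite at any start")
  }
  tol <- 1e-6
  boundary <- any(abs(log(c(best$fw, best$bw)) - lb) < tol) ||
    any(abs(log(c(best$fw, best$bw)) - ub) < tol)
  structure(
    list(
      model = rate_model(best$fw, best$bw, kind = kind),
      loglik = best$loglik,
      kind = kind,
      boundary = boundary,
      convergence = best$conv,
      starts = dplyr::bind_rows(rows)
    ),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(x$kind, " fit: fw = ", format(x$model$fw), ", bw = ",
    format(x$model$bw), ", lnL = ", format(x$loglik),
    if (x$boundary) " [boundary]" else "", "\n",
    sep = ""
  )
  invisible(x)
}
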