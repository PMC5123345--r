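#' MCMC convergence diagnostics
#'
#' Scalar diagnostics for MCMC traces: `ess()` is the effective sample size
#' `n * var(x) / S(0)` with the spectral density at frequency zero `S(0)`
#' estimated from an AIC-selected autoregressive fit; `geweke_z()` compares
#' the means of the first `frac1` and last `frac2` of the chain, with
#' variances from the same spectral estimator; `split_rhat()` is the
#' potential scale reduction factor of the two chain halves, and
#' `gelman_rubin()` the multi-chain version.  `burnin_maxess()` picks the
#' burn-in among candidate fractions that maximizes the effective sample
#' size of the remainder (the max-ESS rule).
#'
#' @param x numeric vector (one scalar trace).
#' @return `ess()`: scalar; `geweke_z()`: z-score; `split_rhat()`,
#'   `gelman_rubin()`: scalar R-hat; `burnin_maxess()`: integer index of the
#'   first post-burn-in sample.
#' @export
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(n)
  s0 <- spectrum0_ar(x)
  if (!is.finite(s0) || s0 <= 0) return(n)
  min(n, n * v / s0)
}

spectrum0_ar <- function(x) {
  n <- length(x)
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = min(n - 1L,
                                                           floor(10 * log10(n)))),
                  error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' @rdname ess
#' @param frac1,frac2 fractions of the chain compared by the Geweke test.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 100) stop("trace too short for the Geweke diagnostic (need >= 100)")
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1L, n)]
  va <- spectrum0_ar(a) / length(a)
  vb <- spectrum0_ar(b) / length(b)
  if (va + vb <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' @rdname ess
#' @export
split_rhat <- function(x) {
  n <- length(x)
  h <- n %/% 2L
  gelman_rubin(list(x[seq_len(h)], x[seq.int(n - h + 1L, n)]))
}

#' @rdname ess
#' @param chains list of numeric vectors (equal lengths).
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("Gelman-Rubin needs >= 2 chains")
  n <- min(lengths(chains))
  ch <- lapply(chains, function(c) c[seq_len(n)])
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  if (B == 0) return(1)   # identical chains: degenerate case is "converged"
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname ess
#' @param fracs candidate burn-in fractions.
#' @export
burnin_maxess <- function(x, fracs = seq(0, 0.5, by = 0.1)) {
  n <- length(x)
  cand <- unique(pmin(n - 10L, floor(fracs * n)))
  cand <- cand[cand >= 0]
  if (!length(cand)) return(1L)
  es <- vapply(cand, function(b) ess(x[(b + 1L):n]), 0)
  cand[which.max(es)] + 1L
}

#' Diagnostic report for a fitted chain
#'
#' Per-scalar effective sample size and Geweke z-score (plus split R-hat)
#' for the model parameters and the two log densities of a trace.
#'
#' @param trace a `dltrs` fit or its trace data frame.
#' @param burnin first retained sample index (defaults to the fit's max-ESS
#'   choice, or 1 for a raw data frame).
#' @return a data frame of class `dltrs_diagnostics`.
#' @export
diagnostics <- function(trace, burnin = NULL) {
  if (inherits(trace, "dltrs")) {
    if (is.null(burnin)) burnin <- trace$burnin
    trace <- trace$trace
  }
  if (is.null(burnin)) burnin <- 1L
  cols <- intersect(c("delta", "mu", "tau", "m", "cv", "log_seq", "log_tree"),
                    names(trace))
  tr <- trace[seq.int(burnin, nrow(trace)), cols, drop = FALSE]
  if (nrow(tr) < 100) stop("need >= 100 post-burn-in samples for diagnostics")
  out <- data.frame(
    scalar = cols,
    mean = vapply(tr, mean, 0),
    sd = vapply(tr, stats::sd, 0),
    ess = vapply(tr, ess, 0),
    geweke_z = vapply(tr, function(x)
      if (stats::sd(x) > 0) geweke_z(x) else 0, 0),
    split_rhat = vapply(tr, function(x)
      if (stats::sd(x) > 0) split_rhat(x) else 1, 0),
    row.names = NULL)
  class(out) <- c("dltrs_diagnostics", "data.frame")
  out
}

#' @export
print.dltrs_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (post burn-in):\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  conv <- all(abs(x$geweke_z) < 3) && all(x$ess >= 100)
  if (!conv) cat("warning: convergence indicators outside comfort zone",
                 "(|z| >= 3 or ESS < 100)\n")
  invisible(x)
}
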