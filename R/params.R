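#' DLTRS model parameters
#'
#' Bundles the five rate parameters of the model: `delta` (gene duplication
#' rate), `mu` (gene loss rate) and `tau` (lateral transfer rate), all in
#' events per gene lineage per time unit; `m`, the mean edge substitution
#' rate (substitutions/site/time); and `cv`, the coefficient of variation of
#' the iid gamma edge-rate law of the relaxed molecular clock.
#'
#' @param delta,mu,tau non-negative rates.
#' @param m positive mean edge rate.
#' @param cv positive coefficient of variation.
#' @return an object of class `dltrs_params` (a named numeric vector).
#' @examples
#' dltrs_params(delta = 0.2, mu = 0.3, tau = 0.1, m = 1, cv = 0.5)
#' @export
dltrs_params <- function(delta, mu, tau, m = 1, cv = 0.5) {
  th <- c(delta = delta, mu = mu, tau = tau, m = m, cv = cv)
  if (any(!is.finite(th))) stop("all parameters must be finite")
  if (delta < 0 || mu < 0 || tau < 0) stop("rates must be >= 0")
  if (m <= 0) stop("mean edge rate m must be > 0")
  if (cv <= 0) stop("coefficient of variation cv must be > 0")
  structure(th, class = "dltrs_params")
}

#' @export
print.dltrs_params <- function(x, ...) {
  cat("DLTRS parameters: delta =", x[["delta"]], " mu =", x[["mu"]],
      " tau =", x[["tau"]], " m =", x[["m"]], " cv =", x[["cv"]], "\n")
  invisible(x)
}

as_params <- function(theta) {
  if (inherits(theta, "dltrs_params")) return(theta)
  if (is.numeric(theta) && length(theta) == 5) {
    if (is.null(names(theta))) names(theta) <- c("delta", "mu", "tau", "m", "cv")
    return(dltrs_params(theta[["delta"]], theta[["mu"]], theta[["tau"]],
                        theta[["m"]], theta[["cv"]]))
  }
  stop("'theta' must be a dltrs_params object or a named length-5 numeric")
}
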