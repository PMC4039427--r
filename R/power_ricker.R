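# Power Ricker breakage curve: the size model at the heart of the package.

#' Construct a Power Ricker parameter triple
#'
#' The Power Ricker curve is a unimodal function of stem diameter
#' \deqn{p(x) = p_{max} \left(\frac{x}{x_{max}} e^{1 - x/x_{max}}\right)^\alpha}
#' where `p_max` is the maximum breakage probability, `x_max` the DBH (cm)
#' at which breakage probability peaks, and `alpha` a dimensionless scaling
#' factor: the larger `alpha`, the steeper the rise to the mode and the
#' flatter the curve around it relative to its shoulders.
#'
#' @param p_max maximum breakage probability, in (0, 1).
#' @param x_max DBH at maximum breakage probability, cm, > 0.
#' @param alpha flatness scaling factor, > 0.
#' @return an object of class `power_ricker_params`.
#' @examples
#' pr <- power_ricker_params(0.28, 17, 2)
#' power_ricker(17, pr) # equals p_max at the mode
#' @export
power_ricker_params <- function(p_max, x_max, alpha) {
  check_number(p_max, "p_max", lower = 0, upper = 1,
               closed_lower = TRUE, closed_upper = FALSE)
  check_number(x_max, "x_max", lower = 0, closed_lower = FALSE)
  check_number(alpha, "alpha", lower = 0, closed_lower = FALSE)
  structure(list(p_max = p_max, x_max = x_max, alpha = alpha),
            class = "power_ricker_params")
}

#' @export
print.power_ricker_params <- function(x, ...) {
  cat(sprintf("Power Ricker parameters: p_max = %.4g, x_max = %.4g cm, alpha = %.4g\n",
              x$p_max, x$x_max, x$alpha))
  invisible(x)
}

#' Evaluate the Power Ricker breakage probability
#'
#' @param x stem DBH in cm; vectorised; all values must be > 0.
#' @param params a [power_ricker_params()] object (or coercible list).
#' @return breakage probabilities in `[0, p_max]`, maximised exactly at
#'   `x = x_max`.
#' @export
power_ricker <- function(x, params) {
  params <- as_power_ricker(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("DBH values must be finite and > 0")
  # log-scale kernel avoids overflow for large alpha or extreme x
  lk <- params$alpha * (log(x) - log(params$x_max) + 1 - x / params$x_max)
  params$p_max * exp(lk)
}

as_power_ricker <- function(params) {
  if (inherits(params, "power_ricker_params")) return(params)
  if (is.list(params) && all(c("p_max", "x_max", "alpha") %in% names(params)))
    return(power_ricker_params(params$p_max, params$x_max, params$alpha))
  if (is.numeric(params) && length(params) == 3L)
    return(power_ricker_params(params[[1]], params[[2]], params[[3]]))
  stopf("cannot interpret 'params' as a Power Ricker triple")
}

#' Bernoulli log-likelihood of the size model
#'
#' Sum over stems of `d_i log p_i + (1 - d_i) log(1 - p_i)` with `p_i`
#' the Power Ricker probability at the stem's DBH. Returns `-Inf` (not an
#' error) when a stem's outcome has probability zero under `params`.
#'
#' @param params a [power_ricker_params()] object.
#' @param trees data frame with columns `dbh` (cm, > 0) and `broken`
#'   (0/1), one row per stem.
#' @return scalar log-likelihood.
#' @export
pr_log_likelihood <- function(params, trees) {
  if (!is.data.frame(trees) || nrow(trees) == 0L)
    stopf("'trees' must be a non-empty data frame")
  if (!all(c("dbh", "broken") %in% names(trees)))
    stopf("'trees' needs columns 'dbh' and 'broken'")
  d <- trees$broken
  if (!all(d %in% c(0, 1))) stopf("'broken' must be 0/1")
  p <- power_ricker(trees$dbh, params)
  ll <- sum(ifelse(d == 1, log(p), log1p(-p)))
  if (is.nan(ll)) -Inf else ll
}
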