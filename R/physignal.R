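# Phylogenetic signal statistics for species-level susceptibility.
# Both are implemented from the phylogenetic covariance matrix directly,
# so the permutation machinery and the likelihood profile are transparent
# and testable against simulation.

# match a named value vector to a tree's tips; error on mismatch
match_tips <- function(tree, values) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stopf("tree must have branch lengths")
  if (is.null(names(values))) stopf("'values' must be named by tip label")
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stopf("values missing for tips: %s", paste(head(missing, 5), collapse = ", "))
  v <- values[tree$tip.label]
  if (any(!is.finite(v))) stopf("tip values must be finite")
  v
}

# Blomberg's observed/expected MSE0/MSE ratio given precomputed pieces
k_ratio_obs <- function(x, invC, one_invC) {
  ahat <- sum(one_invC * x) / sum(one_invC)
  dev <- x - ahat
  mse0 <- sum(dev^2)
  mse <- drop(crossprod(dev, invC %*% dev))
  mse0 / mse
}

#' Blomberg's K with a tip-permutation test
#'
#' K compares the observed ratio of the ordinary to the phylogenetically
#' corrected mean squared error against its expectation under Brownian
#' motion on the given tree; K = 1 matches Brownian expectation, K < 1
#' means less signal than Brownian motion, K > 1 more. The p-value is the
#' proportion of random tip relabellings with K at least as large as
#' observed, with the +1 correction: `p = (r + 1) / (n_perm + 1)`.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param values named numeric vector of per-species scalars (tip labels
#'   as names), non-constant.
#' @param n_perm number of tip permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `signal_result`: `statistic`, `p_value`,
#'   `n_tips`, `method`.
#' @export
blomberg_K <- function(tree, values, n_perm = 999L, seed = 1L) {
  v <- match_tips(tree, values)
  n <- length(v)
  if (n < 4L) stopf("need at least 4 tips")
  if (var(v) == 0) stopf("values are constant; K is undefined")
  n_perm <- check_count(n_perm, "n_perm", lower = 0L)

  C <- ape::vcv(tree)[names(v), names(v)]
  invC <- solve(C)
  one_invC <- rowSums(invC)
  # expected MSE0/MSE under Brownian motion on this tree
  expected <- (sum(diag(C)) - n / sum(invC)) / (n - 1)

  obs_ratio <- k_ratio_obs(v, invC, one_invC)
  K <- obs_ratio / expected

  p <- NA_real_
  if (n_perm > 0L) {
    perm_K <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      k_ratio_obs(sample(v), invC, one_invC) / expected
    }, 0))
    p <- (sum(perm_K >= K) + 1) / (n_perm + 1)
  }
  structure(list(statistic = K, p_value = p, n_tips = n,
                 method = sprintf("Blomberg's K, %d tip permutations", n_perm)),
            class = "signal_result")
}

# profile log-likelihood of Pagel's lambda (mean and variance profiled out)
lambda_loglik <- function(lambda, v, C) {
  n <- length(v)
  Cl <- lambda_vcv(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  invC_v <- backsolve(ch, forwardsolve(t(ch), v))
  invC_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  ahat <- sum(invC_v) / sum(invC_1)
  dev <- v - ahat
  invC_dev <- backsolve(ch, forwardsolve(t(ch), dev))
  s2 <- sum(dev * invC_dev) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Lambda multiplies the off-diagonal (shared-history) entries of the
#' phylogenetic covariance matrix: 0 erases phylogenetic covariance, 1
#' preserves it. The estimate maximises the Gaussian profile likelihood
#' over `[0, lambda_max]`, where `lambda_max` keeps the transformed
#' matrix positive definite (> 1 for ultrametric trees). The p-value is
#' a likelihood-ratio test against lambda = 0 on one degree of freedom.
#'
#' @inheritParams blomberg_K
#' @return object of class `signal_result` with `statistic` (the lambda
#'   estimate), `p_value`, `n_tips`, `loglik`, `loglik0`, `method`.
#' @export
pagel_lambda <- function(tree, values) {
  v <- match_tips(tree, values)
  n <- length(v)
  if (n < 4L) stopf("need at least 4 tips")
  if (var(v) == 0) stopf("values are constant; lambda is undefined")
  C <- ape::vcv(tree)[names(v), names(v)]
  off <- max(C[upper.tri(C)])
  if (off <= 1e-12) stopf("star phylogeny: lambda is unidentifiable")
  lambda_max <- min(diag(C)) / off # keeps C(lambda) diagonally dominant-ish
  lambda_max <- max(lambda_max, 1)

  opt <- optimize(lambda_loglik, c(0, lambda_max), v = v, C = C,
                  maximum = TRUE, tol = 1e-6)
  # guard the interior optimum against the boundaries
  cand <- c(opt$maximum, 0, lambda_max)
  ll <- vapply(cand, lambda_loglik, 0, v = v, C = C)
  best <- which.max(ll)
  lam <- cand[best]; ll_hat <- ll[best]
  ll0 <- lambda_loglik(0, v, C)
  stat <- max(0, 2 * (ll_hat - ll0))
  structure(list(statistic = lam, p_value = pchisq(stat, 1, lower.tail = FALSE),
                 n_tips = n, loglik = ll_hat, loglik0 = ll0,
                 method = "Pagel's lambda, likelihood-ratio vs lambda = 0"),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g (n = %d tips)\n",
              x$method, x$statistic, x$p_value, x$n_tips))
  invisible(x)
}
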