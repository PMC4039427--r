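# Adaptive random-walk Metropolis sampler for the Power Ricker size model.
#
# Sampling is done on the unconstrained scale
#   theta = (logit p_max, log x_max, log alpha)
# with independent normal priors on theta (i.e. lognormal priors on x_max
# and alpha, logit-normal on p_max), updated one coordinate at a time.
# Proposal standard deviations adapt in batches during burn-in only, so
# the retained chain is a valid time-homogeneous Markov chain.

#' Default vague priors for the size model
#'
#' Proper but weak: `logit(p_max) ~ N(0, 10)`, `x_max ~ LogNormal(log 20, 2)`,
#' `alpha ~ LogNormal(0, 2)`. The lognormal scales span several orders of
#' magnitude around typical stem diameters so the data dominate.
#'
#' @return named list of prior means and sds on the transformed scale.
#' @export
pr_default_priors <- function() {
  list(logit_pmax_mean = 0,        logit_pmax_sd = 10,
       log_xmax_mean   = log(20),  log_xmax_sd   = 2,
       log_alpha_mean  = 0,        log_alpha_sd  = 2)
}

#' MCMC configuration for the size model
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain (after which thinning applies).
#' @param n_burnin iterations discarded; adaptation happens only here.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer; spawns one independent stream per chain.
#' @param proposal_sd initial random-walk sds for
#'   (logit p_max, log x_max, log alpha).
#' @param adapt_batch batch size for Robbins-Monro style scale adaptation.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 20000L, n_burnin = 5000L,
                        thin = 5L, seed = 1L,
                        proposal_sd = c(0.25, 0.1, 0.15),
                        adapt_batch = 50L) {
  n_chains <- check_count(n_chains, "n_chains", lower = 1L)
  n_iter <- check_count(n_iter, "n_iter", lower = 1L)
  n_burnin <- check_count(n_burnin, "n_burnin", lower = 0L)
  thin <- check_count(thin, "thin", lower = 1L)
  if (n_iter <= n_burnin) stopf("n_iter (%d) must exceed n_burnin (%d)", n_iter, n_burnin)
  if (n_chains < 2L) warnf("fewer than 2 chains: split R-hat cannot detect poor mixing")
  if (!is.numeric(proposal_sd) || length(proposal_sd) != 3L || any(proposal_sd <= 0))
    stopf("'proposal_sd' must be 3 positive numbers")
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = check_count(seed, "seed"),
                 proposal_sd = proposal_sd,
                 adapt_batch = check_count(adapt_batch, "adapt_batch", lower = 10L)),
            class = "mcmc_config")
}

# log posterior on theta scale (priors are normal on theta directly)
pr_log_post <- function(theta, lx, x, d, priors) {
  lp <- dnorm(theta[1], priors$logit_pmax_mean, priors$logit_pmax_sd, log = TRUE) +
        dnorm(theta[2], priors$log_xmax_mean, priors$log_xmax_sd, log = TRUE) +
        dnorm(theta[3], priors$log_alpha_mean, priors$log_alpha_sd, log = TRUE)
  p <- plogis(theta[1]) * exp(exp(theta[3]) * (lx - theta[2] + 1 - x / exp(theta[2])))
  ll <- sum(d * log(p) + (1 - d) * log1p(-p))
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

#' Sample the posterior of the Power Ricker size model
#'
#' Adaptive Metropolis-within-Gibbs on the transformed parameters, with
#' chains started from independent over-dispersed prior draws. Individual
#' parameters may be pinned to known values via `fixed`, which is useful
#' for reduced-problem validation against brute-force grid posteriors.
#'
#' @param trees data frame with columns `dbh` and `broken`; rows with
#'   missing DBH are dropped with a message.
#' @param priors list as returned by [pr_default_priors()].
#' @param mcmc an [mcmc_config()].
#' @param fixed optional named list pinning any of `p_max`, `x_max`,
#'   `alpha` to constants (they are then not sampled).
#' @return object of class `pr_chains`: a list with `draws` (one matrix
#'   per chain, columns `p_max`, `x_max`, `alpha`, natural scale, thinned
#'   post-burn-in), `accept` rates per parameter, and the configuration.
#' @export
sample_posterior <- function(trees, priors = pr_default_priors(),
                             mcmc = mcmc_config(), fixed = NULL) {
  if (!is.data.frame(trees) || !all(c("dbh", "broken") %in% names(trees)))
    stopf("'trees' must be a data frame with 'dbh' and 'broken'")
  keep <- is.finite(trees$dbh) & trees$dbh > 0
  if (any(!keep)) {
    message(sprintf("dropping %d stems without usable DBH", sum(!keep)))
    trees <- trees[keep, , drop = FALSE]
  }
  d <- as.numeric(trees$broken)
  if (!all(d %in% c(0, 1))) stopf("'broken' must be 0/1")
  if (sum(d) == 0L) stopf("degenerate data: no broken stems, breakage probability is unidentified")
  if (sum(d) == length(d)) stopf("degenerate data: all stems broken, breakage probability is unidentified")
  x <- as.numeric(trees$dbh); lx <- log(x)

  free <- c(p_max = TRUE, x_max = TRUE, alpha = TRUE)
  theta_fix <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), names(free))
    if (length(bad)) stopf("unknown fixed parameter(s): %s", paste(bad, collapse = ", "))
    if (!is.null(fixed$p_max)) { free["p_max"] <- FALSE; theta_fix[1] <- qlogis(fixed$p_max) }
    if (!is.null(fixed$x_max)) { free["x_max"] <- FALSE; theta_fix[2] <- log(fixed$x_max) }
    if (!is.null(fixed$alpha)) { free["alpha"] <- FALSE; theta_fix[3] <- log(fixed$alpha) }
  }

  prior_mu <- c(priors$logit_pmax_mean, priors$log_xmax_mean, priors$log_alpha_mean)
  prior_sd <- c(priors$logit_pmax_sd, priors$log_xmax_sd, priors$log_alpha_sd)
  seeds <- spawn_seeds(mcmc$seed, mcmc$n_chains)
  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin

  run_chain <- function(chain_seed) with_seed(chain_seed, {
    # over-dispersed but sane starting point; bounded retries for finite density
    theta <- NULL
    for (attempt in 1:100) {
      cand <- prior_mu + rnorm(3) * pmin(prior_sd, c(2, 0.7, 0.7))
      cand[!free] <- theta_fix[!free]
      if (is.finite(pr_log_post(cand, lx, x, d, priors))) { theta <- cand; break }
    }
    if (is.null(theta)) stopf("could not find a starting point with finite posterior density")

    ls_prop <- log(mcmc$proposal_sd)
    lp_cur <- pr_log_post(theta, lx, x, d, priors)
    out <- matrix(NA_real_, n_keep, 3L)
    acc <- att <- c(0, 0, 0)
    batch_acc <- batch_att <- c(0, 0, 0)
    k <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      for (j in which(free)) {
        prop <- theta
        prop[j] <- theta[j] + rnorm(1, 0, exp(ls_prop[j]))
        lp_new <- pr_log_post(prop, lx, x, d, priors)
        att[j] <- att[j] + 1; batch_att[j] <- batch_att[j] + 1
        if (log(runif(1)) < lp_new - lp_cur) {
          theta <- prop; lp_cur <- lp_new
          acc[j] <- acc[j] + 1; batch_acc[j] <- batch_acc[j] + 1
        }
      }
      if (it <= mcmc$n_burnin && it %% mcmc$adapt_batch == 0L) {
        # nudge each proposal scale toward the 0.44 one-dimensional optimum
        delta <- min(0.1, 1 / sqrt(it / mcmc$adapt_batch))
        rate <- ifelse(batch_att > 0, batch_acc / pmax(batch_att, 1), 0.44)
        ls_prop <- ls_prop + ifelse(rate > 0.44, delta, -delta) * (batch_att > 0)
        batch_acc <- batch_att <- c(0, 0, 0)
      }
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0L) {
        k <- k + 1L
        out[k, ] <- c(plogis(theta[1]), exp(theta[2]), exp(theta[3]))
      }
    }
    colnames(out) <- c("p_max", "x_max", "alpha")
    list(draws = out[seq_len(k), , drop = FALSE], accept = acc / pmax(att, 1))
  })

  chains <- lapply(seeds, run_chain)
  structure(list(
    draws = lapply(chains, `[[`, "draws"),
    accept = do.call(rbind, lapply(chains, `[[`, "accept")),
    free = free, config = mcmc, priors = priors,
    n_stems = length(d), n_broken = sum(d)
  ), class = "pr_chains")
}

#' @export
print.pr_chains <- function(x, ...) {
  cat(sprintf("Power Ricker posterior: %d chains x %d retained draws (%d stems, %d broken)\n",
              length(x$draws), nrow(x$draws[[1]]), x$n_stems, x$n_broken))
  invisible(x)
}

# ---- convergence diagnostics ------------------------------------------------

# split R-hat (each chain halved) for one parameter
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(v) {
    n <- length(v) %/% 2L
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial positive sequence, pooled chains
ess_geyer <- function(chain_list) {
  m <- length(chain_list); n <- length(chain_list[[1]])
  if (n < 4L) return(NA_real_)
  W <- mean(vapply(chain_list, var, 0))
  if (W == 0) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  rho <- rowMeans(vapply(chain_list, function(v) {
    a <- acf(v, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * var(v) / W
  }, numeric(max_lag + 1L)))
  # sum consecutive pairs while positive
  tau <- 0; lag <- 1L
  while (lag + 1L <= max_lag) {
    pair <- rho[lag + 1L] + rho[lag + 2L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + pair
    lag <- lag + 2L
  }
  m * n / (1 + 2 * tau)
}

#' Summarise posterior draws
#'
#' Pooled posterior mean and central 95% interval per parameter, plus
#' split R-hat and effective sample size. Sets a `warning` flag when any
#' free parameter's R-hat exceeds 1.05.
#'
#' @param chains a `pr_chains` object from [sample_posterior()].
#' @param rhat_threshold mixing threshold (default 1.05).
#' @return object of class `pr_posterior_summary` with a `table`
#'   data frame (mean, q2.5, q97.5, rhat, ess, n per parameter).
#' @export
summarize_posterior <- function(chains, rhat_threshold = 1.05) {
  if (!inherits(chains, "pr_chains")) stopf("'chains' must come from sample_posterior()")
  if (length(chains$draws) == 0L || nrow(chains$draws[[1]]) == 0L)
    stopf("no retained draws to summarise")
  pars <- colnames(chains$draws[[1]])
  pooled <- do.call(rbind, chains$draws)
  tab <- do.call(rbind, lapply(pars, function(p) {
    per_chain <- lapply(chains$draws, function(m) m[, p])
    v <- pooled[, p]
    data.frame(parameter = p,
               mean = mean(v),
               q2.5 = unname(quantile(v, 0.025, type = 7)),
               q97.5 = unname(quantile(v, 0.975, type = 7)),
               rhat = split_rhat(per_chain),
               ess = ess_geyer(per_chain),
               n = length(v))
  }))
  rownames(tab) <- NULL
  free_rhat <- tab$rhat[chains$free[tab$parameter]]
  warn <- any(!is.finite(free_rhat)) || any(free_rhat > rhat_threshold, na.rm = TRUE)
  structure(list(table = tab, warning = warn, accept = chains$accept,
                 n_stems = chains$n_stems, n_broken = chains$n_broken),
            class = "pr_posterior_summary")
}

#' @export
print.pr_posterior_summary <- function(x, ...) {
  cat("Posterior summary (pooled chains):\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  if (isTRUE(x$warning)) cat("WARNING: split R-hat above threshold; chains may not have mixed.\n")
  invisible(x)
}

#' Size-standardised breakage residuals
#'
#' For each stem, `residual_i = d_i - pbar_i` where `pbar_i` is the
#' posterior-mean breakage probability at the stem's DBH (the probability
#' averaged over retained draws, not the curve at the posterior-mean
#' parameters). Positive residuals mean the stem broke more readily than
#' expected for its size. Stems without usable DBH are excluded and
#' counted, not errored on.
#'
#' @param trees data frame with `tree_id`, `dbh`, `broken`.
#' @param chains a `pr_chains` object fitted to (a superset of) the data.
#' @return data frame `tree_id`, `p_expected`, `residual`, with attribute
#'   `n_excluded`.
#' @export
breakage_residuals <- function(trees, chains) {
  if (!inherits(chains, "pr_chains")) stopf("'chains' must come from sample_posterior()")
  if (!all(c("dbh", "broken") %in% names(trees)))
    stopf("'trees' needs 'dbh' and 'broken'")
  id <- trees$tree_id %||% seq_len(nrow(trees))
  keep <- is.finite(trees$dbh) & trees$dbh > 0
  n_excl <- sum(!keep)
  if (n_excl > 0L) message(sprintf("residuals: excluded %d stems without usable DBH", n_excl))
  x <- trees$dbh[keep]; d <- as.numeric(trees$broken[keep])
  draws <- do.call(rbind, chains$draws)
  lx <- log(x)
  # accumulate posterior-mean probability draw by draw (memory-light)
  pbar <- numeric(length(x))
  for (i in seq_len(nrow(draws))) {
    a <- draws[i, "alpha"]; lxm <- log(draws[i, "x_max"])
    pbar <- pbar + draws[i, "p_max"] * exp(a * (lx - lxm + 1 - x / draws[i, "x_max"]))
  }
  pbar <- pbar / nrow(draws)
  out <- data.frame(tree_id = id[keep], p_expected = pbar, residual = d - pbar)
  attr(out, "n_excluded") <- n_excl
  out
}
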