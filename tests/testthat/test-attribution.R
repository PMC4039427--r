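test_that("rank_scale implements mean-rank-for-ties and the affine map", {
  expect_equal(rank_scale(c(-0.1, 0.3, 0.3)), c(-1, 0.5, 0.5))
  expect_equal(rank_scale(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(sort(rank_scale(c(2, -7, 0.4))), c(-1, 0, 1))
  expect_error(rank_scale(1), "at least 2")
  expect_error(rank_scale(c(1, NA)), "finite")
  # invariant under strictly monotone transforms; mean ~ 0
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- rnorm(50)
      expect_equal(rank_scale(x), rank_scale(exp(x)))
      expect_equal(rank_scale(x), rank_scale(qlogis(plogis(x))))
      expect_equal(mean(rank_scale(x)), 0, tolerance = 1e-12)
    }
  })
})

test_that("family filter removes small families and unidentified stems", {
  trees <- data.frame(
    species_id = c(rep("s1", 5), rep("s2", 4), NA),
    family_id = c(rep("fA", 5), rep("fB", 4), "fC"))
  expect_message(out <- filter_min_family(trees, 5), "kept 5 of 10")
  expect_true(all(out$family_id == "fA"))
  expect_equal(attr(out, "n_removed"), 5L)
  expect_message(out1 <- filter_min_family(trees, 1), "kept 9")
  expect_equal(nrow(out1), 9L) # only the unidentified stem goes
  expect_error(filter_min_family(trees, 100), ">= 100")
})

test_that("REML matches the balanced one-way ANOVA estimator", {
  d <- oneway_data(k = 8, m = 6, sd_b = 1, sd_e = 0.7, seed = 1)
  fit <- fit_lmm(d, "y", random = "plot")
  agg <- tapply(d$y, d$plot_id, mean)
  msb <- 6 * var(agg)
  msw <- sum((d$y - ave(d$y, d$plot_id))^2) / (8 * 5)
  expect_equal(fit$variance_components[["plot"]], (msb - msw) / 6, tolerance = 1e-6)
  expect_equal(fit$variance_components[["residual"]], msw, tolerance = 1e-6)
  expect_false(fit$boundary)
})

test_that("zero between-group signal hits the boundary with a flag", {
  d <- data.frame(plot_id = rep(sprintf("g%d", 1:6), each = 3),
                  y = rep(c(-1, 0, 1), 6)) # identical plot means
  fit <- fit_lmm(d, "y", random = "plot")
  expect_equal(fit$variance_components[["plot"]], 0, tolerance = 1e-10)
  expect_true(fit$boundary)
})

test_that("ML variance components match the brute-force grid oracle", {
  d <- crossed_data(n_fam = 3, n_plot = 4, n = 60, sd_f = 0.8, sd_p = 0.6,
                    sd_e = 1, seed = 7)
  fit <- suppressMessages(fit_lmm(d, "y", random = c("family", "plot"), method = "ML"))
  oracle <- ml_grid_oracle(d)
  expect_equal(fit$variance_components[["family"]], oracle$sigma2_family, tolerance = 1e-2)
  expect_equal(fit$variance_components[["plot"]], oracle$sigma2_plot, tolerance = 1e-2)
  expect_equal(fit$variance_components[["residual"]], oracle$sigma2_resid, tolerance = 1e-2)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-3)
})

test_that("fit_lmm validates design and grouping inputs", {
  d <- crossed_data(3, 4, 40, 0.5, 0.5, 1, seed = 2)
  d$dup <- d$stand_age_z
  expect_error(fit_lmm(d, "y", fixed = c("stand_age_z", "dup"),
                       random = c("family", "plot")), "rank deficient")
  expect_error(fit_lmm(d, "z", random = "plot"), "not in data")
  expect_error(fit_lmm(d[, c("y", "family_id")], "y", random = "plot"), "grouping")
})

test_that("variance percentages partition correctly", {
  fake <- function(v) structure(list(variance_components = v), class = "lmm_fit")
  pct <- variance_percentages(fake(c(family = 10, species = 11, plot = 6, residual = 73)))
  expect_equal(unname(pct), c(10, 11, 6, 73))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  # scale invariance and single-component edge
  expect_equal(variance_percentages(fake(c(family = 20, species = 22, plot = 12, residual = 146))),
               pct)
  expect_equal(unname(variance_percentages(fake(c(plot = 3, residual = 0)))), c(100, 0))
  expect_error(variance_percentages(fake(c(plot = 0, residual = 0))), "zero")
  # property: sums to 100 for random component sets
  withr::with_seed(11, {
    for (i in 1:20) {
      v <- runif(4); names(v) <- c("family", "species", "plot", "residual")
      expect_equal(sum(variance_percentages(fake(v))), 100, tolerance = 1e-9)
    }
  })
})

test_that("omega_F is the proportional reduction of a component", {
  fake <- function(v, n = 100) structure(list(variance_components = v,
                                              method = "REML", n = n),
                                         class = "lmm_fit")
  u <- fake(c(plot = 1.00, residual = 1))
  expect_equal(omega_F(u, fake(c(plot = 0.64, residual = 1)), "plot")$omega_F, 0.36)
  expect_equal(omega_F(u, fake(c(plot = 1.00, residual = 1)), "plot")$omega_F, 0)
  expect_warning(r <- omega_F(u, fake(c(plot = 1.10, residual = 1)), "plot"), "grew")
  expect_equal(r$omega_F, -0.10)
  expect_error(omega_F(fake(c(plot = 0, residual = 1)),
                       fake(c(plot = 0, residual = 1)), "plot"), "zero")
  expect_error(omega_F(u, fake(c(plot = 1, residual = 1), n = 99), "plot"),
               "different data")
})

test_that("model comparison arithmetic and nesting checks", {
  d <- crossed_data(4, 5, 200, 0.5, 0.5, 1, seed = 3)
  u <- fit_lmm(d, "y", random = c("family", "plot"), method = "ML")
  expect_error(compare_models(fit_lmm(d, "y", random = c("family", "plot")), u), "ML")
  same <- compare_models(u, u)
  expect_equal(same$delta_AIC, 0)
  expect_equal(same$lrt_p, 1)
  # AIC identity: delta_AIC = 2*df - LRT statistic for nested ML fits
  cns <- fit_lmm(d, "y", fixed = "stand_age_z", random = c("family", "plot"),
                 method = "ML")
  cm <- compare_models(u, cns)
  expect_equal(cm$delta_AIC, 2 * cm$df - cm$lrt_stat, tolerance = 1e-8)
})

test_that("LRT detects strong fixed effects and is calibrated under the null", {
  # power: a strong stem-level effect at n = 2000 is always found
  hits <- vapply(1:5, function(r) {
    d <- crossed_data(8, 10, 2000, 0.4, 0.4, 1, seed = 40 + r)
    withr::with_seed(60 + r, {
      d$x <- rnorm(nrow(d))
      d$y <- d$y + 0.3 * d$x
    })
    u <- fit_lmm(d, "y", random = c("family", "plot"), method = "ML")
    cns <- fit_lmm(d, "y", fixed = "x", random = c("family", "plot"),
                   method = "ML")
    cm <- compare_models(u, cns)
    cm$delta_AIC < 0 && cm$lrt_p < 0.01
  }, TRUE)
  expect_true(all(hits))
  # type-I calibration: stem-level null predictor gives uniform p
  ps <- vapply(1:150, function(r) {
    d <- oneway_data(k = 10, m = 15, sd_b = 0.5, sd_e = 1, seed = 200 + r)
    withr::with_seed(300 + r, d$x <- rnorm(nrow(d)))
    u <- fit_lmm(d, "y", random = "plot", method = "ML")
    cns <- fit_lmm(d, "y", fixed = "x", random = "plot", method = "ML")
    compare_models(u, cns)$lrt_p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("variance partition recovers the generative taxon > plot ordering", {
  # residuals against the true generative curve isolate the attribution
  # stage from MCMC noise; default world has taxon sds above the plot sd
  res <- t(vapply(1:10, function(r) {
    sc <- synth_config(seed = 600 + r, frac_base_only = 0)
    sim <- simulate_forest(sc)
    tr <- sim$trees
    tr$residual <- tr$broken - power_ricker(tr$dbh, sc$true_params)
    tr <- suppressMessages(filter_min_family(tr))
    tr$scaled_rank <- rank_scale(tr$residual)
    fit <- suppressWarnings(suppressMessages(fit_lmm(tr, "scaled_rank")))
    pct <- variance_percentages(fit)
    cond <- tr$scaled_rank - predict(fit$mermod)
    by_sp <- tapply(cond, tr$species_id, mean)
    keep <- intersect(sim$tree$tip.label, names(by_sp)[!is.na(by_sp)])
    k <- blomberg_K(ape::keep.tip(sim$tree, keep), by_sp[keep],
                    n_perm = 199, seed = r)
    c(taxon = unname(pct["family"] + pct["species"]),
      plot = unname(pct["plot"]), kp = k$p_value)
  }, c(taxon = 0, plot = 0, kp = 0)))
  expect_gte(mean(res[, "taxon"] > res[, "plot"]), 0.9)
  # the residual layer carries no phylogenetic structure by construction:
  # its permutation p-values stay unremarkable
  expect_gte(mean(res[, "kp"] > 0.05), 0.8)
})
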