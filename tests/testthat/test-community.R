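test_that("Gower distance: hand examples and missing-data handling", {
  tab <- data.frame(v1 = c(0, 1, 0), v2 = c(0, 0.5, 1))
  d <- gower_distance(tab) # ranges are 1 and 1
  expect_equal(d[1, 2], (1 + 0.5) / 2)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  # identical rows -> 0; maximal difference in every variable -> 1
  expect_equal(gower_distance(data.frame(a = c(1, 1, 2), b = c(3, 3, 5)))[1, 2], 0)
  expect_equal(gower_distance(data.frame(a = c(0, 1), b = c(0, 2),
                                         f = c("x", "y")))[1, 2], 1)
  # zero-range variables are excluded with a warning
  expect_warning(dz <- gower_distance(data.frame(a = c(0, 1, 0.5), cst = 1)),
                 "zero-range")
  expect_equal(dz[1, 2], 1)
  # pairwise-complete: the NA variable drops out of that pair only
  tabNA <- data.frame(v1 = c(0, 1, 0.5), v2 = c(0, NA, 1))
  dNA <- gower_distance(tabNA)
  expect_equal(dNA[1, 2], 1) # only v1 observed in both
  expect_equal(dNA[1, 3], (0.5 + 1) / 2)
})

test_that("Gower agrees with cluster::daisy on complete mixed data", {
  skip_if_not_installed("cluster")
  withr::with_seed(4, {
    tab <- data.frame(a = rnorm(12), b = runif(12, 0, 10),
                      f = sample(c("u", "v", "w"), 12, TRUE))
  })
  ours <- gower_distance(tab)
  ref <- as.matrix(cluster::daisy(transform(tab, f = factor(f)), metric = "gower"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("PCoA is exact classical scaling", {
  withr::with_seed(6, pts <- cbind(rnorm(15), rnorm(15)))
  d <- as.matrix(dist(pts))
  ord <- pcoa_axes(d, n_axes = 2)
  # planar Euclidean input: exactly two meaningful eigenvalues
  expect_equal(length(ord$eigenvalues[ord$eigenvalues > 1e-8]), 2L)
  expect_equal(as.matrix(dist(ord$scores)), d, tolerance = 1e-10, ignore_attr = TRUE)
  # against an independently coded double-centering computation
  tab <- data.frame(a = c(0, 1, 0.3, 0.8), b = c(1, 0, 0.6, 0.2), f = c("x", "x", "y", "y"))
  g <- gower_distance(tab)
  n <- 4; J <- diag(n) - 1 / n
  eig <- eigen(-0.5 * J %*% g^2 %*% J, symmetric = TRUE)
  ref <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  ord2 <- pcoa_axes(g, 2)
  expect_equal(abs(ord2$scores), abs(ref), tolerance = 1e-10, ignore_attr = TRUE)
  # all-equal objects: no positive eigenvalues
  expect_error(pcoa_axes(matrix(0, 3, 3), 1), "positive eigenvalues")
  # anchoring flips the axis so the anchor loads positively
  anch <- pcoa_axes(d, 2, anchors = data.frame(a1 = pts[, 1]))
  expect_gte(cor(pts[, 1], anch$scores[, 1]), 0)
})

test_that("trait imputation honours observed cells and seeds", {
  withr::with_seed(2, {
    full <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  })
  expect_identical(unclass(impute_traits(full))[, ], full[, ])
  # perfectly collinear columns: the imputed value sits on the line
  coll <- cbind(x = full[, "a"], y = 2 * full[, "a"] + 1, z = full[, "b"])
  coll[5, "y"] <- NA
  imp <- impute_traits(coll, noise = FALSE)
  expect_equal(unname(imp[5, "y"]), unname(2 * coll[5, "x"] + 1), tolerance = 1e-6)
  # stochastic completion is seed-reproducible
  holey <- full; holey[cbind(c(3, 9, 21), c(1, 2, 3))] <- NA
  expect_identical(impute_traits(holey, seed = 5), impute_traits(holey, seed = 5))
  expect_false(identical(impute_traits(holey, seed = 5), impute_traits(holey, seed = 6)))
  bad <- full; bad[, 2] <- NA
  expect_error(impute_traits(bad), "fewer than 2")
})

test_that("major axis regression: exact line, symmetry, degeneracies", {
  fit <- major_axis_regression(c(0, 1, 2), c(0, 2, 4))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  withr::with_seed(8, {
    x <- rnorm(60); y <- 1.4 * x + rnorm(60, 0, 0.4)
  })
  expect_equal(major_axis_regression(x, y)$slope,
               1 / major_axis_regression(y, x)$slope, tolerance = 1e-10)
  expect_error(major_axis_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("DBH interpolation completes flagged stems only", {
  trees <- data.frame(
    tree_id = sprintf("t%d", 1:6),
    dbh = c(10, 20, 30, NA, NA, 15),
    measured_at_base = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    basal_measure = c(11, 22, 33, 16.5, 5.5, NA))
  out <- interpolate_dbh(trees)
  fit <- attr(out, "ma_fit")
  # calibration points are exactly on dbh = basal/1.1
  expect_equal(fit$slope, 1 / 1.1, tolerance = 1e-9)
  expect_equal(out$dbh[4], 16.5 / 1.1, tolerance = 1e-9)
  expect_equal(out$dbh[5], 5, tolerance = 1e-9)
  expect_identical(out$dbh[c(1:3, 6)], trees$dbh[c(1:3, 6)])
  # no flagged stems: data unchanged
  expect_identical(interpolate_dbh(trees[1:3, ])$dbh, trees$dbh[1:3])
  expect_error(interpolate_dbh(trees[4:5, ]), "calibration")
})

test_that("calibration R^2 of the generator matches its target", {
  sim <- simulate_forest(synth_config(n_stems = 3000, seed = 14))
  out <- interpolate_dbh(sim$trees)
  expect_lt(abs(attr(out, "ma_fit")$r_squared - 0.95), 0.02)
  expect_true(all(is.finite(out$dbh)))
})

test_that("basal-area adjustment follows the three damage categories", {
  trees <- data.frame(
    tree_id = sprintf("t%d", 1:5),
    plot_id = "p1",
    species_id = c("A", "A", "B", "B", "C"),
    dbh = c(10, 20, 10, 10, 40),
    broken = c(0, 1, 1, 1, 0),
    dead = c(0, 1, 0, 0, 0),
    height_to_break = c(NA, 4, 15, 0, NA))
  st <- basal_area_states(trees)
  ba <- function(d) pi * (d / 2)^2
  expect_equal(st$before["p1", "A"], ba(10) + ba(20))
  # dead stem contributes nothing; unaffected unchanged
  expect_equal(st$after["p1", "A"], ba(10))
  expect_equal(st$after["p1", "C"], ba(40))
  # max observed ratio keeps full BA, ratio 0 keeps none
  expect_equal(st$max_ratio, 1.5)
  expect_equal(st$after["p1", "B"], ba(10) * (1.5 / 1.5) + ba(10) * 0)
  expect_true(all(st$after <= st$before + 1e-12))
  # broken living stem without height is an error naming the stem
  trees$height_to_break[3] <- NA
  expect_error(basal_area_states(trees), "t3")
})

test_that("monotone damage holds on simulated forests", {
  for (s in 1:3) {
    sim <- simulate_forest(synth_config(n_stems = 800, seed = 20 + s,
                                        frac_base_only = 0))
    st <- basal_area_states(sim$trees)
    expect_true(all(st$after <= st$before + 1e-9))
  }
})

test_that("CWM and FDis: hand examples and invariances", {
  st <- structure(list(
    before = matrix(c(2, 2, 1, 0), 2, 2, dimnames = list(c("p1", "p2"), c("A", "B"))),
    after = matrix(c(1, 2, 1, 0), 2, 2, dimnames = list(c("p1", "p2"), c("A", "B"))),
    max_ratio = 1.5), class = "community_state")
  tr <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), "ax"))
  m <- cwm(st, tr)
  expect_equal(m$before["p1", "ax"], 1 / 3) # weights 2/3, 1/3
  expect_equal(m$before["p2", "ax"], 0)     # single-species plot
  expect_equal(m$after["p1", "ax"], 0.5)
  fd <- fdis(st, tr)
  expect_equal(unname(fd$before["p2"]), 0)            # one species
  expect_equal(unname(fd$after["p1"]), 0.5)           # equal weights, d = 1
  # weights 0.1/0.9 at distance 1: FDis = 0.18
  st2 <- st; st2$before[1, ] <- c(0.1, 0.9); st2$after[1, ] <- c(0.1, 0.9)
  expect_equal(unname(fdis(st2, tr)$before["p1"]), 0.18)
  # translation invariance and weight normalisation
  expect_equal(fdis(st, tr + 100)$before, fd$before)
  st3 <- st; st3$before <- st$before * 7
  expect_equal(cwm(st3, tr)$before, m$before)
  # CWM bounded by contributing trait values
  expect_true(all(m$before >= min(tr) & m$before <= max(tr)))
  # zero-BA plot is an error
  st4 <- st; st4$after["p2", ] <- 0
  expect_error(cwm(st4, tr), "zero total basal area")
})

test_that("paired t-test matches hand arithmetic", {
  d <- c(1, -1, 1, -1, 2)
  r <- paired_t(rep(0, 5), d)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r$t, 2 / 3, tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p_value, 2 * pt(-2 / 3, 4))
  ref <- t.test(d)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_error(paired_t(1:5, 1:5 + 2), "zero-variance")
  expect_error(paired_t(1:3, 1:2), "paired")
})
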