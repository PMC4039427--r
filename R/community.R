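# Community-level stage: variable reduction by ordination, trait-matrix
# completion, the storm-specific basal-area adjustment, and before/after
# comparisons of community-weighted means and functional dispersion.

#' Gower dissimilarity for mixed variables
#'
#' Range-normalised numeric contributions, simple mismatch for binary or
#' factor variables, averaged pairwise-complete over the variables
#' observed in both objects. Values lie in [0, 1]. Variables with zero
#' range are excluded with a warning (they carry no information).
#'
#' @param table data frame or matrix, objects in rows.
#' @return symmetric `dist`-like matrix with zero diagonal.
#' @export
gower_distance <- function(table) {
  table <- as.data.frame(table)
  n <- nrow(table)
  if (n < 2L) stopf("need at least 2 objects")
  cols <- lapply(table, function(col) {
    if (is.numeric(col)) {
      rng <- diff(range(col, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) return(NULL)
      list(type = "num", x = col, range = rng)
    } else {
      col <- as.character(col)
      if (length(unique(na.omit(col))) < 2L) return(NULL)
      list(type = "cat", x = col)
    }
  })
  dropped <- names(table)[vapply(cols, is.null, TRUE)]
  if (length(dropped))
    warnf("excluding zero-range variable(s): %s", paste(dropped, collapse = ", "))
  cols <- Filter(Negate(is.null), cols)
  if (!length(cols)) stopf("no informative variables left")

  num <- den <- matrix(0, n, n)
  for (cl in cols) {
    obs <- !is.na(cl$x)
    both <- outer(obs, obs, `&`)
    contrib <- matrix(0, n, n)
    if (cl$type == "num") {
      contrib[both] <- abs(outer(cl$x, cl$x, `-`))[both] / cl$range
    } else {
      contrib[both] <- (outer(cl$x, cl$x, `!=`))[both]
    }
    num <- num + contrib
    den <- den + both
  }
  if (any(den == 0 & row(den) != col(den)))
    stopf("some object pairs share no observed variables")
  d <- num / pmax(den, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred squared-distance Gram matrix.
#' Axis scores are eigenvectors scaled by the square root of their
#' eigenvalues; negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Gower) are dropped with a warning. An optional
#' anchor fixes the arbitrary axis signs: the correlation of the anchor
#' variable with its axis is made positive.
#'
#' @param distances symmetric dissimilarity matrix.
#' @param n_axes number of axes to retain.
#' @param anchors optional data frame / matrix of variables (same row
#'   order) used to orient axes: column `i` anchors axis `i`.
#' @return object of class `ordination_result`: `scores` (objects x
#'   axes), `eigenvalues` (all positive ones, non-increasing), `loadings`
#'   (correlations of anchor variables with axes, when given).
#' @export
pcoa_axes <- function(distances, n_axes = 2L, anchors = NULL) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 2L || any(abs(d - t(d)) > 1e-8)) stopf("'distances' must be a symmetric matrix")
  n_axes <- check_count(n_axes, "n_axes", lower = 1L)
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (d^2) %*% J
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-9 & eig$values > 0
  if (!any(pos)) stopf("no positive eigenvalues; objects are indistinguishable")
  if (sum(!pos & eig$values < -1e-8 * max(eig$values)))
    warnf("dropping %d negative eigenvalue(s) (non-Euclidean input)",
          sum(eig$values < -1e-8 * max(eig$values)))
  if (n_axes > sum(pos))
    stopf("requested %d axes but only %d positive eigenvalues", n_axes, sum(pos))
  vals <- eig$values[pos][seq_len(n_axes)]
  scores <- eig$vectors[, which(pos)[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(vals), n_axes)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("axis", seq_len(n_axes))

  loadings <- NULL
  if (!is.null(anchors)) {
    anchors <- as.data.frame(anchors)
    for (i in seq_len(min(ncol(anchors), n_axes))) {
      cc <- suppressWarnings(cor(anchors[[i]], scores[, i],
                                 use = "pairwise.complete.obs"))
      if (is.finite(cc) && cc < 0) scores[, i] <- -scores[, i]
    }
    loadings <- suppressWarnings(cor(anchors, scores, use = "pairwise.complete.obs"))
  }
  structure(list(scores = scores, eigenvalues = eig$values[pos],
                 loadings = loadings),
            class = "ordination_result")
}

#' Complete a trait matrix by chained-equation regression imputation
#'
#' Missing cells start at column means; then, cycling over columns with
#' missing values, each column is regressed on all others (rows observed
#' in the original data) and its missing cells are refreshed with the
#' prediction plus Gaussian residual noise. A single stochastic
#' completion, seed-controlled.
#'
#' @param traits numeric matrix with `NA`s; every column needs >= 2
#'   observed values and every row >= 1.
#' @param n_iter number of full sweeps (default 10).
#' @param seed integer seed.
#' @param noise add residual noise to predictions (default TRUE)?
#' @return completed matrix with attribute `imputed` (logical mask).
#' @export
impute_traits <- function(traits, n_iter = 10L, seed = 1L, noise = TRUE) {
  if (!is.matrix(traits) || !is.numeric(traits)) stopf("'traits' must be a numeric matrix")
  n_iter <- check_count(n_iter, "n_iter", lower = 1L)
  miss <- is.na(traits)
  if (!any(miss)) return(structure(traits, imputed = miss))
  if (any(colSums(!miss) < 2L))
    stopf("column(s) with fewer than 2 observed values cannot be imputed: %s",
          paste(colnames(traits)[colSums(!miss) < 2L], collapse = ", "))
  if (any(rowSums(!miss) < 1L))
    stopf("row(s) with no observed values cannot be imputed")

  x <- traits
  for (j in seq_len(ncol(x))) x[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
  # internal sanitised names so user trait names cannot collide with the
  # model formula machinery
  safe <- paste0(".v", seq_len(ncol(x)))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      for (j in which(colSums(miss) > 0)) {
        obs <- !miss[, j]
        df <- as.data.frame(x)
        colnames(df) <- safe
        df$.resp <- x[, j]
        fit <- lm(reformulate(safe[-j], ".resp"), data = df[obs, , drop = FALSE])
        pred <- predict(fit, newdata = df[!obs, , drop = FALSE])
        sig <- summary(fit)$sigma
        if (!is.finite(sig)) sig <- 0
        x[!obs, j] <- pred + if (noise) rnorm(sum(!obs), 0, sig) else 0
      }
    }
  })
  structure(x, imputed = miss)
}

#' Major axis regression
#'
#' Symmetric line fit along the first principal axis of the bivariate
#' scatter: `slope = (s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) /
#' (2 s_xy)`, intercept through the means. Unlike ordinary least squares
#' it treats both variables as subject to error, which is the right model
#' when interpolating one diameter measurement from another.
#'
#' @param x,y paired numeric vectors, n >= 3, both with positive variance.
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation), `n`.
#' @export
major_axis_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxx == 0) stopf("x has zero variance; major axis undefined")
  if (syy == 0) stopf("y has zero variance; major axis undefined")
  if (sxy == 0) {
    if (syy == sxx) stopf("isotropic scatter: major axis direction undefined")
    # axis aligned with the higher-variance coordinate
    slope <- if (syy > sxx) Inf else 0
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  list(slope = slope, intercept = intercept,
       r_squared = cor(x, y)^2, n = length(x))
}

#' Interpolate missing DBH from base-of-stem measurements
#'
#' Fits a major axis regression of DBH on the base diameter over the
#' calibration stems (both measured), then predicts DBH for stems flagged
#' `measured_at_base` whose DBH is missing. Non-positive predictions are
#' rejected stem-wise (left `NA`) and counted.
#'
#' @param trees inventory data frame with `dbh`, `measured_at_base`,
#'   `basal_measure`.
#' @param calibration optional data frame with columns `basal_measure`
#'   and `dbh`; defaults to the fully-measured stems of `trees` that
#'   carry a base measurement.
#' @return `trees` with DBH completed; attributes `ma_fit` (the
#'   calibration fit, incl. `r_squared`) and `n_rejected`.
#' @export
interpolate_dbh <- function(trees, calibration = NULL) {
  need <- c("dbh", "measured_at_base", "basal_measure")
  if (!all(need %in% names(trees))) stopf("'trees' needs columns %s", paste(need, collapse = ", "))
  if (is.null(calibration)) {
    sel <- !trees$measured_at_base & is.finite(trees$dbh) & is.finite(trees$basal_measure)
    calibration <- trees[sel, c("basal_measure", "dbh")]
  }
  if (nrow(calibration) < 3L) stopf("no usable calibration data (need >= 3 pairs)")
  fit <- major_axis_regression(calibration$basal_measure, calibration$dbh)

  target <- trees$measured_at_base & !is.finite(trees$dbh)
  pred <- fit$intercept + fit$slope * trees$basal_measure[target]
  bad <- !is.finite(pred) | pred <= 0
  pred[bad] <- NA_real_
  trees$dbh[target] <- pred
  if (any(bad))
    message(sprintf("interpolate_dbh: rejected %d non-positive prediction(s)", sum(bad)))
  structure(trees, ma_fit = fit, n_rejected = sum(bad))
}

#' Plot-by-species basal area before and after the storm
#'
#' Basal area per stem is `pi * (DBH/2)^2` (cm^2). The before matrix sums
#' all stems. After the storm: unaffected stems keep their basal area,
#' stems that died lose all of it, and broken-but-living stems retain the
#' fraction given by their scaled height-to-break ratio — the ratio
#' `height[m] / DBH[cm]` divided by the maximum observed ratio (clamped
#' to [0, 1]), so a stem snapped at its base retains nothing and one
#' broken near the observed maximum retains almost everything.
#'
#' @param trees data frame with `plot_id`, `species_id`, `dbh`, `broken`,
#'   `dead`, `height_to_break`.
#' @return object of class `community_state`: matrices `before` and
#'   `after` (plots x species, cm^2) plus `max_ratio`.
#' @export
basal_area_states <- function(trees) {
  need <- c("plot_id", "species_id", "dbh", "broken", "dead")
  if (!all(need %in% names(trees))) stopf("'trees' needs columns %s", paste(need, collapse = ", "))
  trees <- trees[is.finite(trees$dbh), , drop = FALSE]
  broken_alive <- trees$broken == 1L & trees$dead == 0L
  if (any(broken_alive & !is.finite(trees$height_to_break)))
    stopf("broken living stem(s) lack height_to_break: %s",
          paste(head(trees$tree_id[broken_alive & !is.finite(trees$height_to_break)], 5),
                collapse = ", "))
  ba <- pi * (trees$dbh / 2)^2
  ratio <- trees$height_to_break / trees$dbh
  max_ratio <- suppressWarnings(max(ratio[broken_alive], na.rm = TRUE))
  if (!is.finite(max_ratio) || max_ratio <= 0) max_ratio <- 1
  retained <- rep(1, nrow(trees))
  retained[trees$dead == 1L] <- 0
  retained[broken_alive] <- pmin(pmax(ratio[broken_alive] / max_ratio, 0), 1)

  pl <- factor(trees$plot_id)
  sp <- factor(trees$species_id)
  before <- as.matrix(tapply(ba, list(pl, sp), sum, default = 0))
  after <- as.matrix(tapply(ba * retained, list(pl, sp), sum, default = 0))
  structure(list(before = before, after = after, max_ratio = max_ratio),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community state: %d plots x %d species; total basal area %.0f -> %.0f cm^2\n",
              nrow(x$before), ncol(x$before), sum(x$before), sum(x$after)))
  invisible(x)
}

# shared weighting helper: BA matrix rows -> weights summing to 1
ba_weights <- function(mat) {
  tot <- rowSums(mat)
  if (any(tot <= 0))
    stopf("plot(s) with zero total basal area: %s",
          paste(rownames(mat)[tot <= 0], collapse = ", "))
  mat / tot
}

check_state_traits <- function(state, traits) {
  stopifnot(inherits(state, "community_state"))
  if (!is.matrix(traits)) traits <- as.matrix(traits)
  missing <- setdiff(colnames(state$before), rownames(traits))
  if (length(missing))
    stopf("species without trait values: %s", paste(head(missing, 5), collapse = ", "))
  if (any(!is.finite(traits[colnames(state$before), ])))
    stopf("trait matrix must be complete (impute first)")
  traits[colnames(state$before), , drop = FALSE]
}

#' Community-weighted trait means before and after the storm
#'
#' `CWM(plot, axis) = sum_s w_s trait_s` with `w_s` the species' share of
#' the plot's basal area, computed separately on the before and after
#' matrices.
#'
#' @param state a `community_state`.
#' @param traits complete species x axis matrix (rownames = species).
#' @return list of matrices `before` and `after` (plots x axes).
#' @export
cwm <- function(state, traits) {
  tr <- check_state_traits(state, traits)
  list(before = ba_weights(state$before) %*% tr,
       after = ba_weights(state$after) %*% tr)
}

#' Functional dispersion before and after the storm
#'
#' Per plot, the basal-area-weighted mean Euclidean distance of species
#' to the weighted community centroid in trait space:
#' `FDis = sum_s w_s || trait_s - c ||` with `c = sum_s w_s trait_s`.
#'
#' @inheritParams cwm
#' @return list of numeric vectors `before` and `after` (one per plot).
#' @export
fdis <- function(state, traits) {
  tr <- check_state_traits(state, traits)
  one <- function(mat) {
    w <- ba_weights(mat)
    cent <- w %*% tr
    vapply(seq_len(nrow(w)), function(i) {
      dev <- sweep(tr, 2, cent[i, ], `-`)
      sum(w[i, ] * sqrt(rowSums(dev^2)))
    }, 0) |> setNames(rownames(mat))
  }
  list(before = one(state$before), after = one(state$after))
}

#' Paired two-sided t-test on per-plot values
#'
#' @param before,after equal-length paired numeric vectors (n >= 2).
#' @return list with `t`, `df`, `p_value`, `mean_diff` (after - before).
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stopf("'before' and 'after' must be paired")
  ok <- is.finite(before) & is.finite(after)
  d <- (after - before)[ok]
  n <- length(d)
  if (n < 2L) stopf("need at least 2 complete pairs")
  if (var(d) == 0) stopf("zero-variance differences; t statistic undefined")
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p_value = 2 * pt(-abs(t_stat), n - 1L),
       mean_diff = mean(d))
}
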