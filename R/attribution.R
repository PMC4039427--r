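# Variance attribution of size-standardised breakage: scaled-rank
# transform, crossed-random-effects mixed models, variance percentages,
# the omega_F relative-importance statistic, and AIC / likelihood-ratio
# comparisons of nested fixed-effect structures.

#' Rank-scale residuals to [-1, 1]
#'
#' Ranks with "mean rank for ties", then maps affinely so that the
#' smallest value goes to -1, the largest to +1 and the centre of the
#' rank range to 0: `scaled = (rank - (n+1)/2) / ((n-1)/2)`. The
#' transform removes the bimodality of Bernoulli residuals while
#' preserving order; negative values signify less breakage than expected
#' for the stem's size, positive values more.
#'
#' @param residuals numeric vector, length >= 2.
#' @return numeric vector of scaled ranks (mean 0 when untied).
#' @export
rank_scale <- function(residuals) {
  if (!is.numeric(residuals) || length(residuals) < 2L)
    stopf("need at least 2 residuals to rank")
  if (any(!is.finite(residuals))) stopf("residuals must be finite")
  n <- length(residuals)
  r <- rank(residuals, ties.method = "average")
  (r - (n + 1) / 2) / ((n - 1) / 2)
}

#' Drop rare families and unidentified stems
#'
#' Keeps only stems whose species is identified and whose family has at
#' least `min_n` identified individuals, the filter applied before the
#' mixed-model stage so singleton taxa cannot masquerade as variance.
#'
#' @param trees data frame with `species_id` and `family_id` (NA =
#'   unidentified).
#' @param min_n minimum family size (default 5).
#' @return the filtered data frame, with attribute `n_removed`.
#' @export
filter_min_family <- function(trees, min_n = 5L) {
  if (!all(c("species_id", "family_id") %in% names(trees)))
    stopf("'trees' needs 'species_id' and 'family_id'")
  min_n <- check_count(min_n, "min_n", lower = 1L)
  known <- !is.na(trees$species_id) & !is.na(trees$family_id)
  tab <- table(trees$family_id[known])
  ok_fam <- names(tab)[tab >= min_n]
  keep <- known & trees$family_id %in% ok_fam
  if (!any(keep))
    stopf("no stems left after requiring >= %d identified individuals per family", min_n)
  out <- trees[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  message(sprintf("family filter (>= %d per family): kept %d of %d stems",
                  min_n, nrow(out), nrow(trees)))
  out
}

#' Fit a Gaussian mixed model with crossed taxon and stand effects
#'
#' Thin, contract-stable wrapper around [lme4::lmer()]. The default
#' random structure is three independent random intercepts — family,
#' species nested in family (coded `family:species`), and plot — with
#' family/species crossed with plot. Fixed effects are supplied by
#' column name; an intercept is always included.
#'
#' @param data data frame with the response, fixed-effect columns, and
#'   grouping columns `family_id`, `species_id`, `plot_id` as needed.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param random subset of `c("family", "species", "plot")`.
#' @param method `"REML"` (variance components) or `"ML"` (AIC / LRT).
#' @return object of class `lmm_fit`: variance components (response
#'   units squared, named `family`, `species`, `plot`, `residual`),
#'   fixed-effect table, conditional modes per random level,
#'   log-likelihood, AIC, boundary flag, and the underlying `merMod`.
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    random = c("family", "species", "plot"),
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  random <- match.arg(random, several.ok = TRUE)
  if (!response %in% names(data)) stopf("response '%s' not in data", response)
  need <- c(family = "family_id", species = "species_id", plot = "plot_id")[random]
  miss <- setdiff(unname(need), names(data))
  if (length(miss)) stopf("missing grouping column(s): %s", paste(miss, collapse = ", "))
  if ("species" %in% random && !"family_id" %in% names(data))
    stopf("species-in-family coding needs 'family_id'")

  df <- data
  df$.fam <- if ("family_id" %in% names(df)) factor(df$family_id) else NULL
  if ("species" %in% random)
    df$.spp <- factor(paste(df$family_id, df$species_id, sep = ":"))
  if ("plot" %in% random) df$.plot <- factor(df$plot_id)

  if (length(fixed)) {
    miss <- setdiff(fixed, names(df))
    if (length(miss)) stopf("fixed effect column(s) not in data: %s", paste(miss, collapse = ", "))
    X <- model.matrix(reformulate(fixed), df)
    if (qr(X)$rank < ncol(X)) stopf("fixed-effect design matrix is rank deficient")
  }

  terms <- c(family = "(1 | .fam)", species = "(1 | .spp)", plot = "(1 | .plot)")[random]
  rhs <- paste(c(if (length(fixed)) fixed else "1", terms), collapse = " + ")
  form <- as.formula(paste(response, "~", rhs))
  fit <- lme4::lmer(form, data = df, REML = (method == "REML"),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- c(family = 0, species = 0, plot = 0, residual = 0)
  map <- c(.fam = "family", .spp = "species", .plot = "plot", Residual = "residual")
  for (i in seq_len(nrow(vc))) comp[map[vc$grp[i]]] <- vc$vcov[i]
  comp <- comp[c(intersect(c("family", "species", "plot"), random), "residual")]

  re <- lapply(lme4::ranef(fit), function(m) setNames(m[, 1], rownames(m)))
  names(re) <- map[names(re)]
  cf <- summary(fit)$coefficients

  structure(list(
    variance_components = comp,
    fixed_effects = data.frame(term = rownames(cf), estimate = cf[, 1],
                               std_error = cf[, 2], row.names = NULL),
    random_effect_predictions = re,
    log_likelihood = as.numeric(logLik(fit)),
    AIC = AIC(fit),
    n = nrow(df),
    method = method,
    boundary = any(comp[names(comp) != "residual"] < 1e-8),
    formula = deparse(form),
    mermod = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s): %s\n", x$method, x$formula))
  cat("Variance components:\n")
  print(round(x$variance_components, 5))
  if (x$boundary) cat("note: at least one variance component is at the zero boundary\n")
  invisible(x)
}

#' Variance components as percentages of the total
#'
#' Each component (including the residual) divided by the component sum,
#' times 100. This is the partition used to compare the importance of
#' taxon and stand scales.
#'
#' @param fit an `lmm_fit`.
#' @return named numeric vector summing to 100.
#' @export
variance_percentages <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  v <- fit$variance_components
  tot <- sum(v)
  if (tot <= 0) stopf("all variance components are zero; percentages undefined")
  100 * v / tot
}

#' Relative importance of a fixed effect (omega_F)
#'
#' `omega_F = 1 - omega_Rc / omega_R`: the proportional reduction of one
#' random term's REML variance component when the fixed effect is added
#' (unconstrained model omega_R, constrained model omega_Rc). A value of
#' 0.36 means the predictor removes 36% of the variance previously
#' attributed to that level. Negative values (the component grew) are
#' returned with a warning rather than suppressed.
#'
#' @param unconstrained,constrained REML `lmm_fit`s on identical data and
#'   random structure; `constrained` adds fixed term(s).
#' @param level which variance component: `"family"`, `"species"` or
#'   `"plot"`.
#' @return object of class `importance_result` with fields `omega_R`,
#'   `omega_Rc`, `omega_F`, `level`.
#' @export
omega_F <- function(unconstrained, constrained, level = c("plot", "family", "species")) {
  level <- match.arg(level)
  stopifnot(inherits(unconstrained, "lmm_fit"), inherits(constrained, "lmm_fit"))
  if (unconstrained$method != "REML" || constrained$method != "REML")
    warnf("omega_F is defined on REML variance components; got %s/%s",
          unconstrained$method, constrained$method)
  if (unconstrained$n != constrained$n)
    stopf("fits use different data (%d vs %d rows)", unconstrained$n, constrained$n)
  wR <- unconstrained$variance_components[[level]]
  wRc <- constrained$variance_components[[level]]
  if (is.null(wR) || wR <= 0)
    stopf("unconstrained variance component at level '%s' is zero; omega_F undefined", level)
  wF <- 1 - wRc / wR
  if (wF < 0) warnf("omega_F negative at level '%s': component grew when the fixed effect was added", level)
  structure(list(omega_R = wR, omega_Rc = wRc, omega_F = wF, level = level),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("omega_F at level '%s': %.1f%% (component %.5g -> %.5g)\n",
              x$level, 100 * x$omega_F, x$omega_R, x$omega_Rc))
  invisible(x)
}

#' Compare nested ML fits by AIC and likelihood ratio
#'
#' `delta_AIC = AIC(constrained) - AIC(unconstrained)` (negative favours
#' the added fixed effect); likelihood-ratio p-value from a chi-squared
#' distribution with the number of added fixed-effect parameters as
#' degrees of freedom.
#'
#' @param unconstrained,constrained ML `lmm_fit`s on identical data, the
#'   constrained model extending the unconstrained one by fixed term(s).
#' @return list with `delta_AIC`, `lrt_stat`, `df`, `lrt_p`.
#' @export
compare_models <- function(unconstrained, constrained) {
  stopifnot(inherits(unconstrained, "lmm_fit"), inherits(constrained, "lmm_fit"))
  if (unconstrained$method != "ML" || constrained$method != "ML")
    stopf("AIC / LRT comparisons require ML fits")
  if (unconstrained$n != constrained$n)
    stopf("fits are not nested: different data (%d vs %d rows)", unconstrained$n, constrained$n)
  df <- nrow(constrained$fixed_effects) - nrow(unconstrained$fixed_effects)
  if (df < 0) stopf("'constrained' has fewer fixed effects than 'unconstrained'")
  stat <- max(0, 2 * (constrained$log_likelihood - unconstrained$log_likelihood))
  list(delta_AIC = constrained$AIC - unconstrained$AIC,
       lrt_stat = stat,
       df = df,
       lrt_p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}
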