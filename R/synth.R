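# Synthetic forest-inventory generator.
#
# Emulates the sampling design of a subtropical forest inventory: square
# 30 m plots split into a 3 x 3 grid of 10 m subplots, with every stem
# >= 3 cm DBH mapped in the centre subplot and only stems >= 10 cm in the
# outer eight; ~100 species nested in families on a simulated phylogeny;
# unimodal size-dependent stem breakage with taxon and plot heterogeneity
# injected on the logit scale; phylogenetically structured traits with
# block-wise missingness.

#' Configuration for the synthetic forest generator
#'
#' Defaults reproduce the scale of the motivating field campaign: 27 plots,
#' about 100 species, 2,683 mapped stems, a breakage curve peaking at
#' 17 cm DBH with maximum probability 0.28 and flatness 2.0, and trait
#' missingness of 30% (wood xylem), 74% (wood mechanics), 6% (leaf) and
#' 3% (wood density).
#'
#' @param n_plots number of square study plots.
#' @param n_species species-pool size (>= 3 for a usable phylogeny).
#' @param n_families number of families, realised as clades of the tree.
#' @param n_stems total stems across all plots (allocated deterministically).
#' @param center_frac expected fraction of a plot's stems in the centre
#'   subplot (small stems are admitted only there).
#' @param dbh_meanlog,dbh_sdlog lognormal DBH distribution (cm) before
#'   threshold truncation; `dbh_sdlog = 0` gives a point mass.
#' @param dbh_min_center,dbh_min_outer mapping thresholds, cm.
#' @param true_params generative [power_ricker_params()].
#' @param sd_species,sd_family,sd_plot,sd_residual standard deviations of
#'   the logit-scale breakage offsets. Species offsets evolve by Brownian
#'   motion on the phylogeny; family and plot offsets are i.i.d. normal
#'   (families being clades, their offsets are phylogenetically structured
#'   by construction).
#' @param trait_effect logit-scale coefficient linking `breakage_trait` to
#'   breakage; negative means high trait values protect.
#' @param breakage_trait name of the trait axis wired to breakage.
#' @param mortality_given_breakage probability a broken stem dies.
#' @param missing_rates named vector of per-block missingness rates for
#'   `wood_xylem`, `wood_mech`, `leaf`, `wood_density` columns.
#' @param lambda_traits Pagel-lambda transform applied when simulating
#'   traits (1 = pure Brownian motion, 0 = star-like, no signal).
#' @param abundance_skew exponent of the rank-abundance power law.
#' @param abundance_trait_assoc -1, 0 or 1: abundance ranks aligned with
#'   descending total susceptibility (-1, the default: the dominant
#'   species are the storm-prone community core), random (0), or
#'   ascending (1).
#' @param centrality_effect in [0, 1]: share of the species-offset
#'   standard deviation carried by functional centrality (species with
#'   typical trait values are more susceptible than peripheral
#'   strategists); the remainder is Brownian motion on the tree.
#' @param dirichlet_conc gamma concentration for plot-level compositional
#'   jitter; smaller = stronger turnover between plots.
#' @param age_effect_frac fraction of the plot-offset variance carried by
#'   (standardised) stand age, with older stands breaking less.
#' @param frac_base_only fraction of stems measured at the stem base only
#'   (DBH to be interpolated later).
#' @param calib_frac fraction of fully-measured stems that also carry a
#'   base measurement, forming the interpolation calibration set.
#' @param calib_r2 target squared correlation of the DBH ~ base-diameter
#'   calibration relation.
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it, so outputs are bit-reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_plots = 27L, n_species = 100L, n_families = 25L,
                         n_stems = 2683L, center_frac = 0.55,
                         dbh_meanlog = log(9), dbh_sdlog = 0.8,
                         dbh_min_center = 3, dbh_min_outer = 10,
                         true_params = power_ricker_params(0.28, 17, 2.0),
                         sd_species = 0.6, sd_family = 0.5, sd_plot = 0.35,
                         sd_residual = 0,
                         trait_effect = -0.4, breakage_trait = "wood_density",
                         mortality_given_breakage = 0.3,
                         missing_rates = c(wood_xylem = 0.30, wood_mech = 0.74,
                                           leaf = 0.06, wood_density = 0.03),
                         lambda_traits = 1,
                         abundance_skew = 1.3, abundance_trait_assoc = -1,
                         dirichlet_conc = 4, centrality_effect = 0.6,
                         age_effect_frac = 0.36,
                         frac_base_only = 0.08, calib_frac = 0.25,
                         calib_r2 = 0.95,
                         seed = 1L) {
  check_count(n_plots, "n_plots", lower = 2L)
  check_count(n_species, "n_species", lower = 3L)
  check_count(n_families, "n_families", lower = 1L)
  if (n_families > n_species) stopf("n_families (%d) cannot exceed n_species (%d)", n_families, n_species)
  check_count(n_stems, "n_stems", lower = 1L)
  check_number(center_frac, "center_frac", 0, 1)
  check_number(dbh_sdlog, "dbh_sdlog", lower = 0)
  check_number(dbh_min_center, "dbh_min_center", lower = 0, closed_lower = FALSE)
  check_number(dbh_min_outer, "dbh_min_outer", lower = 0, closed_lower = FALSE)
  true_params <- as_power_ricker(true_params)
  for (nm in c("sd_species", "sd_family", "sd_plot", "sd_residual"))
    check_number(get(nm), nm, lower = 0)
  check_number(mortality_given_breakage, "mortality_given_breakage", 0, 1)
  if (is.null(names(missing_rates)) || any(missing_rates < 0) || any(missing_rates > 1))
    stopf("'missing_rates' must be a named vector of probabilities in [0, 1]")
  check_number(lambda_traits, "lambda_traits", 0, 1)
  check_number(centrality_effect, "centrality_effect", 0, 1)
  check_number(age_effect_frac, "age_effect_frac", 0, 1)
  check_number(frac_base_only, "frac_base_only", 0, 1)
  check_number(calib_frac, "calib_frac", 0, 1)
  check_number(calib_r2, "calib_r2", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_count(seed, "seed")
  structure(as.list(environment()), class = "synth_config")
}

# sub-stream seeds, one per generator, derived once from the master seed
synth_seeds <- function(config) {
  s <- spawn_seeds(config$seed, 6L)
  names(s) <- c("plots", "phylo", "inventory", "breakage", "missing", "spare")
  s
}

#' Generate plot-level stand descriptors
#'
#' Elevation, stand age, richness, three vegetation-layer covers plus
#' their total, stem density, and three diversity descriptors (rarefied
#' richness, Rao's quadratic entropy, phylogenetic diversity), all drawn
#' from fixed plausible distributions for a subtropical broad-leaved
#' forest on a 200-1,300 m elevation gradient.
#'
#' @param config a [synth_config()].
#' @return data frame with one row per plot.
#' @export
gen_plots <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(synth_seeds(config)[["plots"]], {
    n <- config$n_plots
    elevation <- runif(n, 250, 1200)
    stand_age <- exp(rnorm(n, log(60), 0.5)) # years; ~20-180
    richness <- pmax(1L, round(rnorm(n, 40, 10)))
    cover_upper <- pmin(100, pmax(5, rnorm(n, 60, 15)))
    cover_lower <- pmin(100, pmax(5, rnorm(n, 45, 15)))
    cover_shrub <- pmin(100, pmax(5, rnorm(n, 35, 15)))
    data.frame(
      plot_id = sprintf("p%02d", seq_len(n)),
      elevation = elevation,
      stand_age = stand_age,
      richness = richness,
      cover_upper = cover_upper,
      cover_lower = cover_lower,
      cover_shrub = cover_shrub,
      cover_total = pmin(100, cover_upper + 0.4 * cover_lower + 0.2 * cover_shrub),
      stem_density = exp(rnorm(n, log(1100), 0.35)), # stems / ha
      rarefied_richness = pmax(1, rnorm(n, 25, 6)),
      rao_q = pmax(0.01, rnorm(n, 0.4, 0.1)),
      phylo_diversity = pmax(1, rnorm(n, 15, 4))
    )
  })
}

# lambda-transform of a phylogenetic covariance matrix
lambda_vcv <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

#' Generate a species phylogeny, trait matrix and taxon offsets
#'
#' Simulates an ultrametric birth-death tree (rescaled to unit depth),
#' assigns families as clades (an ultrametric cut yielding `n_families`
#' groups), evolves seven trait axes by Brownian motion on the
#' lambda-transformed tree, and draws the taxon breakage offsets:
#' species offsets by Brownian motion (so susceptibility carries
#' phylogenetic signal), family offsets i.i.d. normal.
#'
#' @param config a [synth_config()].
#' @return list with `tree` (an `ape::phylo`), `traits` (species x 7
#'   matrix: `wood_xylem_1/2`, `wood_mech_1/2`, `leaf_1/2`,
#'   `wood_density`), and `pool` (data frame: `species_id`, `family_id`,
#'   `sp_offset`, `fam_offset`).
#' @export
gen_phylogeny_and_traits <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(synth_seeds(config)[["phylo"]], {
    n <- config$n_species
    tree <- ape::rphylo(n, birth = 1, death = 0)
    tree$tip.label <- sprintf("s%03d", seq_len(n))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth

    C <- ape::vcv(tree)
    ord <- tree$tip.label # vcv row order == tip label order
    # families: cut the ultrametric tree into n_families clades
    fam_idx <- cutree(hclust(as.dist(2 * (1 - C)), method = "average"),
                      k = config$n_families)
    fam_id <- sprintf("f%02d", fam_idx[ord])

    Cl <- lambda_vcv(C, config$lambda_traits)
    L <- chol(Cl + diag(1e-10, n))
    trait_names <- c("wood_xylem_1", "wood_xylem_2", "wood_mech_1",
                     "wood_mech_2", "leaf_1", "leaf_2", "wood_density")
    traits <- crossprod(L, matrix(rnorm(n * length(trait_names)), n))
    dimnames(traits) <- list(ord, trait_names)

    # species susceptibility: Brownian component blended with functional
    # centrality (species with typical trait values — the community core —
    # are the more storm-prone; peripheral strategists resist), the blend
    # weight set by centrality_effect
    bm <- drop(crossprod(chol(C + diag(1e-10, n)), rnorm(n)))
    comm_axes <- c("wood_xylem_1", "wood_xylem_2", "leaf_1", "leaf_2")
    dist_c <- sqrt(rowSums(sweep(traits[, comm_axes], 2,
                                 colMeans(traits[, comm_axes]), `-`)^2))
    g <- config$centrality_effect
    sp_off <- config$sd_species *
      (sqrt(1 - g^2) * bm + g * as.numeric(scale(-dist_c)))
    fam_off_lvl <- rnorm(config$n_families, 0, config$sd_family)
    pool <- data.frame(species_id = ord, family_id = fam_id,
                       sp_offset = sp_off,
                       fam_offset = fam_off_lvl[fam_idx[ord]])
    list(tree = tree, traits = traits, pool = pool)
  })
}

# deterministic allocation of n_stems across plots and strata
plan_stem_counts <- function(config) {
  n <- config$n_stems; k <- config$n_plots
  per_plot <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) per_plot[seq_len(extra)] <- per_plot[seq_len(extra)] + 1L
  center <- round(per_plot * config$center_frac)
  cbind(center = center, outer = per_plot - center)
}

# truncated lognormal quantile sampler; errors when no mass above the cut
rtrunc_lnorm <- function(n, meanlog, sdlog, lower) {
  if (sdlog == 0) {
    v <- exp(meanlog)
    if (v < lower)
      stopf("DBH distribution has no mass above the %g cm threshold", lower)
    return(rep(v, n))
  }
  p_lo <- plnorm(lower, meanlog, sdlog)
  if (p_lo > 1 - 1e-10)
    stopf("DBH distribution has no mass above the %g cm threshold", lower)
  qlnorm(p_lo + runif(n) * (1 - p_lo), meanlog, sdlog)
}

#' Generate the stem inventory
#'
#' Stems get plot coordinates on a 3 x 3 subplot grid (subplot 5 is the
#' centre). Centre-subplot stems are drawn from the DBH distribution
#' truncated at the small-stem threshold, outer stems at the large-stem
#' threshold. Species are sampled with plot-specific abundance weights: a
#' rank-abundance power law whose ranks follow the breakage-linked trait
#' (see [synth_config()]), jittered per plot by gamma noise. A fraction of
#' stems is flagged as measured at the stem base only (their `dbh` is the
#' latent truth, to be masked before analysis), and a calibration subset
#' carries both measurements.
#'
#' @param plots data frame from [gen_plots()].
#' @param pool species pool from [gen_phylogeny_and_traits()].
#' @param traits trait matrix from the same call (abundance-trait link).
#' @param config a [synth_config()].
#' @return data frame with one row per stem: `tree_id`, `plot_id`,
#'   `species_id`, `family_id`, `subplot`, `x`, `y`, `dbh`,
#'   `measured_at_base`, `basal_measure`.
#' @export
gen_inventory <- function(plots, pool, traits, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(plots) == 0L || nrow(pool) == 0L) stopf("empty plots or species pool")
  with_seed(synth_seeds(config)[["inventory"]], {
    ns <- nrow(pool)
    # total logit susceptibility of each species; aligning abundance with
    # it (-1, default) makes the dominant species the most storm-prone,
    # the dominance-reduction mechanism behind a post-storm rise in
    # evenness and functional dispersion
    suscept <- pool$sp_offset + pool$fam_offset +
      config$trait_effect * traits[pool$species_id, config$breakage_trait]
    base_rank <- switch(as.character(sign(config$abundance_trait_assoc)),
                        "-1" = rank(-suscept, ties.method = "first"),
                        "1"  = rank(suscept, ties.method = "first"),
                        "0"  = sample.int(ns))
    w_base <- base_rank^(-config$abundance_skew)

    counts <- plan_stem_counts(config)
    rows <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      w_plot <- w_base * rgamma(ns, shape = config$dirichlet_conc,
                                rate = config$dirichlet_conc)
      n_c <- counts[i, "center"]; n_o <- counts[i, "outer"]
      sp <- sample(pool$species_id, n_c + n_o, replace = TRUE,
                   prob = w_plot / sum(w_plot))
      subplot <- c(rep(5L, n_c), sample(c(1:4, 6:9), n_o, replace = TRUE))
      dbh <- c(rtrunc_lnorm(n_c, config$dbh_meanlog, config$dbh_sdlog,
                            config$dbh_min_center),
               rtrunc_lnorm(n_o, config$dbh_meanlog, config$dbh_sdlog,
                            config$dbh_min_outer))
      sx <- (subplot - 1L) %% 3L; sy <- (subplot - 1L) %/% 3L
      rows[[i]] <- data.frame(
        plot_id = plots$plot_id[i], species_id = sp,
        subplot = subplot,
        x = sx * 10 + runif(n_c + n_o, 0, 10),
        y = sy * 10 + runif(n_c + n_o, 0, 10),
        dbh = dbh)
    }
    trees <- do.call(rbind, rows)
    trees$tree_id <- sprintf("t%05d", seq_len(nrow(trees)))
    trees$family_id <- pool$family_id[match(trees$species_id, pool$species_id)]

    n <- nrow(trees)
    trees$measured_at_base <- runif(n) < config$frac_base_only
    calib <- !trees$measured_at_base & runif(n) < config$calib_frac
    # taper: base diameter exceeds DBH; noise tuned to the target R^2
    base_true <- 1.15 * trees$dbh
    noise_sd <- stats::sd(base_true) * sqrt((1 - config$calib_r2) / config$calib_r2)
    trees$basal_measure <- ifelse(trees$measured_at_base | calib,
                                  pmax(0.5, base_true + rnorm(n, 0, noise_sd)),
                                  NA_real_)
    trees[, c("tree_id", "plot_id", "species_id", "family_id", "subplot",
              "x", "y", "dbh", "measured_at_base", "basal_measure")]
  })
}

#' Simulate storm breakage and mortality on an inventory
#'
#' Per-stem breakage probability is the Power Ricker curve at the stem's
#' DBH with species, family and plot offsets plus a trait effect added on
#' the logit scale; outcomes are independent Bernoulli draws. Plot
#' offsets are composed of a standardised stand-age component (older
#' stands break less; share `age_effect_frac` of the plot variance) and
#' i.i.d. noise. Broken stems receive a height-to-break drawn so that
#' height[m]/DBH[cm] is uniform on [0, 1.5]; a configured fraction of
#' broken stems is marked dead.
#'
#' @param trees inventory from [gen_inventory()].
#' @param pool,traits from [gen_phylogeny_and_traits()].
#' @param plots from [gen_plots()].
#' @param config a [synth_config()].
#' @return `trees` with columns `broken`, `dead`, `height_to_break`,
#'   `p_break` (the latent probability) appended, plus attribute
#'   `plot_offsets`.
#' @export
gen_breakage <- function(trees, pool, traits, plots, config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(synth_seeds(config)[["breakage"]], {
    f <- config$age_effect_frac
    age_z <- as.numeric(scale(log(plots$stand_age)))
    plot_off <- config$sd_plot *
      (sqrt(f) * (-age_z) + sqrt(1 - f) * rnorm(nrow(plots)))
    names(plot_off) <- plots$plot_id

    i_sp <- match(trees$species_id, pool$species_id)
    eta_add <- pool$sp_offset[i_sp] + pool$fam_offset[i_sp] +
      plot_off[trees$plot_id] +
      config$trait_effect * traits[trees$species_id, config$breakage_trait] +
      rnorm(nrow(trees), 0, config$sd_residual)
    # centre on the realised community so the Power Ricker curve stays the
    # marginal (community-average) breakage curve; abundant susceptible
    # species would otherwise inflate the overall rate far above it
    eta_add <- eta_add - mean(eta_add)

    p0 <- power_ricker(trees$dbh, config$true_params)
    p <- plogis(qlogis(pmin(p0, 1 - 1e-12)) + eta_add)
    p[p0 == 0] <- 0
    trees$p_break <- p
    trees$broken <- as.integer(runif(nrow(trees)) < p)
    trees$dead <- as.integer(trees$broken == 1L &
                               runif(nrow(trees)) < config$mortality_given_breakage)
    ratio <- runif(nrow(trees), 0, 1.5)
    trees$height_to_break <- ifelse(trees$broken == 1L, ratio * trees$dbh, NA_real_)
    attr(trees, "plot_offsets") <- plot_off
    trees
  })
}

#' Inject block-wise missingness into a trait matrix
#'
#' Each cell goes missing independently with the rate of its column block
#' (matched by column-name prefix against `names(config$missing_rates)`).
#'
#' @param traits complete species x trait matrix.
#' @param config a [synth_config()].
#' @return the matrix with `NA`s inserted.
#' @export
inject_missing <- function(traits, config) {
  stopifnot(inherits(config, "synth_config"))
  rates <- config$missing_rates
  with_seed(synth_seeds(config)[["missing"]], {
    for (block in names(rates)) {
      cols <- grep(paste0("^", block), colnames(traits))
      if (!length(cols)) next
      for (j in cols)
        traits[runif(nrow(traits)) < rates[[block]], j] <- NA_real_
    }
    traits
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [gen_plots()], [gen_phylogeny_and_traits()],
#' [gen_inventory()], [gen_breakage()] and [inject_missing()]. Stems
#' flagged as measured at the base only have their DBH masked to `NA` in
#' the returned inventory (the latent value is retained in `dbh_true` for
#' validation), mirroring field data where those diameters must be
#' interpolated before analysis.
#'
#' @param config a [synth_config()].
#' @return list: `plots`, `tree` (phylogeny), `pool`, `traits_complete`,
#'   `traits_observed`, `trees`, `config`.
#' @export
simulate_forest <- function(config = synth_config()) {
  plots <- gen_plots(config)
  phy <- gen_phylogeny_and_traits(config)
  inv <- gen_inventory(plots, phy$pool, phy$traits, config)
  inv <- gen_breakage(inv, phy$pool, phy$traits, plots, config)
  inv$dbh_true <- inv$dbh
  inv$dbh[inv$measured_at_base] <- NA_real_
  list(plots = plots, tree = phy$tree, pool = phy$pool,
       traits_complete = phy$traits,
       traits_observed = inject_missing(phy$traits, config),
       trees = inv, config = config)
}
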