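# End-to-end orchestration: synth -> size model -> attribution ->
# community shift, with seeds, logging, standard-format I/O and a run
# manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed; per-stage seeds are spawned from it.
#' @param synth a [synth_config()], or `NULL` to read existing inputs.
#' @param mcmc an [mcmc_config()] (its seed is overridden by the spawned
#'   stage seed).
#' @param paths named list of input files (`trees`, `plots`, `traits`,
#'   `phylogeny`) used when `synth` is `NULL`.
#' @param stand_predictors plot-table columns tested as stand fixed
#'   effects (stand ordination axes `stand_axis_1/2` are computed).
#' @param trait_predictors trait axes tested as taxon fixed effects.
#' @param exclude_from_community trait axes dropped from CWM / FDis
#'   (default: the wood-mechanics axes, whose missingness is too high to
#'   impute credibly).
#' @param min_family_n family-size filter before the mixed models.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synth = synth_config(seed = seed),
                            mcmc = mcmc_config(),
                            paths = NULL,
                            stand_predictors = c("stand_age", "richness",
                                                 "stand_axis_1", "stand_axis_2"),
                            trait_predictors = c("wood_xylem_1", "wood_xylem_2",
                                                 "wood_mech_1", "wood_mech_2",
                                                 "wood_density", "leaf_1", "leaf_2"),
                            exclude_from_community = c("wood_mech_1", "wood_mech_2"),
                            min_family_n = 5L) {
  check_count(seed, "seed")
  if (is.null(synth)) {
    need <- c("trees", "plots", "traits", "phylogeny")
    if (is.null(paths) || !all(need %in% names(paths)))
      stopf("with synthesis disabled, 'paths' must name files: %s", paste(need, collapse = ", "))
    missing <- !vapply(paths[need], file.exists, TRUE)
    if (any(missing))
      stopf("input file(s) not found: %s", paste(unlist(paths[need][missing]), collapse = ", "))
  }
  structure(list(out_dir = out_dir, seed = seed, synth = synth, mcmc = mcmc,
                 paths = paths, stand_predictors = stand_predictors,
                 trait_predictors = trait_predictors,
                 exclude_from_community = exclude_from_community,
                 min_family_n = check_count(min_family_n, "min_family_n", 1L)),
            class = "pipeline_config")
}

#' Write a simulated forest to standard formats
#'
#' `trees.csv`, `plots.csv`, `traits.csv` (observed, with missingness),
#' `phylogeny.nwk` (Newick with branch lengths) and `synth_config.json`.
#'
#' @param sim result of [simulate_forest()].
#' @param dir target directory.
#' @return the directory, invisibly.
#' @export
write_forest <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trees, file.path(dir, "trees.csv"), row.names = FALSE)
  utils::write.csv(sim$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  tr <- data.frame(species_id = rownames(sim$traits_observed),
                   sim$traits_observed, row.names = NULL)
  utils::write.csv(tr, file.path(dir, "traits.csv"), row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "phylogeny.nwk"))
  cfg <- sim$config
  cfg$true_params <- unclass(cfg$true_params)
  jsonlite::write_json(unclass(cfg), file.path(dir, "synth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read forest inputs from standard formats
#'
#' @param paths named list with `trees`, `plots`, `traits`, `phylogeny`.
#' @return list with `trees`, `plots`, `traits` (matrix), `tree`.
#' @export
read_forest <- function(paths) {
  trees <- utils::read.csv(paths$trees)
  plots <- utils::read.csv(paths$plots)
  tr <- utils::read.csv(paths$traits)
  traits <- as.matrix(tr[, setdiff(names(tr), "species_id"), drop = FALSE])
  rownames(traits) <- tr$species_id
  list(trees = trees, plots = plots, traits = traits,
       tree = ape::read.tree(paths$phylogeny))
}

# stand ordination: Gower on standardised structure + diversity variables,
# two PCoA axes, stem density anchoring axis 1 positive
stand_axes <- function(plots) {
  vars <- c("cover_upper", "cover_lower", "cover_shrub", "cover_total",
            "stem_density", "rarefied_richness", "rao_q", "phylo_diversity")
  vars <- intersect(vars, names(plots))
  tab <- as.data.frame(scale(plots[, vars, drop = FALSE]))
  ord <- pcoa_axes(gower_distance(tab), n_axes = 2L,
                   anchors = plots[, intersect(c("stem_density", "rarefied_richness"),
                                               names(plots)), drop = FALSE])
  data.frame(plot_id = plots$plot_id,
             stand_axis_1 = ord$scores[, 1], stand_axis_2 = ord$scores[, 2])
}

# one predictor's four-fit block (REML +/- predictor, ML +/- predictor)
fit_predictor_block <- function(dat, predictor, levels) {
  base_fixed <- "elevation_z"
  u_reml <- fit_lmm(dat, "scaled_rank", base_fixed, method = "REML")
  c_reml <- fit_lmm(dat, "scaled_rank", c(base_fixed, predictor), method = "REML")
  u_ml <- fit_lmm(dat, "scaled_rank", base_fixed, method = "ML")
  c_ml <- fit_lmm(dat, "scaled_rank", c(base_fixed, predictor), method = "ML")
  cmpr <- compare_models(u_ml, c_ml)
  est <- c_reml$fixed_effects$estimate[c_reml$fixed_effects$term == predictor]
  row <- data.frame(predictor = predictor, n = u_reml$n,
                    delta_AIC = cmpr$delta_AIC, lrt_p = cmpr$lrt_p,
                    estimate = est,
                    direction = ifelse(est < 0, "down", "up"))
  for (lv in c("plot", "family", "species")) {
    row[[paste0("omega_F_", lv)]] <- if (lv %in% levels) {
      # a zero unconstrained component leaves omega_F undefined: report NA
      tryCatch(suppressWarnings(omega_F(u_reml, c_reml, lv)$omega_F),
               error = function(e) NA_real_)
    } else NA_real_
  }
  row
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic data generation (optional), the Bayesian
#' size model with residual extraction, variance attribution with
#' phylogenetic-signal tests, and the community-level before/after
#' comparison. Each stage writes its outputs under `out_dir` and the run
#' closes with a `manifest.json` recording seeds, stage timings, and
#' md5 hashes of every written file; a failing stage aborts the run with
#' a `FAILED_<stage>` marker file retained next to any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (inputs for later stages must
#'   then already exist in `out_dir`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "breakmodel", "attribution", "community")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- spawn_seeds(config$seed, 4L)
  names(stage_seeds) <- c("synth", "breakmodel", "attribution", "community")
  manifest <- list(seed = config$seed, stage_seeds = as.list(stage_seeds),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("stembreakr")),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    message(sprintf("[%s] starting", name))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e), file.path(out, paste0("FAILED_", name)))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "completed",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2))
    message(sprintf("[%s] done (%.1fs)", name, manifest$stages[[name]]$seconds))
    res
  }

  env <- new.env()

  run_stage("synth", function() {
    if (is.null(config$synth)) {
      inp <- read_forest(config$paths)
      env$trees <- inp$trees; env$plots <- inp$plots
      env$traits <- inp$traits; env$tree <- inp$tree
    } else {
      scfg <- config$synth
      scfg$seed <- stage_seeds[["synth"]]
      sim <- simulate_forest(scfg)
      write_forest(sim, file.path(out, "synth"))
      env$trees <- sim$trees; env$plots <- sim$plots
      env$traits <- sim$traits_observed; env$tree <- sim$tree
    }
  })

  run_stage("breakmodel", function() {
    trees <- interpolate_dbh(env$trees)
    mcfg <- config$mcmc
    mcfg$seed <- stage_seeds[["breakmodel"]]
    chains <- sample_posterior(trees, mcmc = mcfg)
    summ <- summarize_posterior(chains)
    res <- breakage_residuals(trees, chains)
    d <- file.path(out, "breakmodel"); dir.create(d, showWarnings = FALSE)
    draws <- do.call(rbind, lapply(seq_along(chains$draws), function(i)
      data.frame(chain = i, iteration = seq_len(nrow(chains$draws[[i]])),
                 chains$draws[[i]])))
    utils::write.csv(draws, file.path(d, "chains.csv"), row.names = FALSE)
    jsonlite::write_json(summ$table, file.path(d, "posterior_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(res, file.path(d, "residuals.csv"), row.names = FALSE)
    env$trees <- trees; env$chains <- chains; env$summary <- summ; env$residuals <- res
  })

  run_stage("attribution", function() {
    trees <- merge(env$trees, env$residuals[, c("tree_id", "residual")], by = "tree_id")
    trees <- filter_min_family(trees, config$min_family_n)
    trees$scaled_rank <- rank_scale(trees$residual)

    plots <- merge(env$plots, stand_axes(env$plots), by = "plot_id")
    plots$elevation_z <- as.numeric(scale(plots$elevation))
    dat <- merge(trees, plots, by = "plot_id")
    for (v in intersect(config$stand_predictors, names(dat)))
      dat[[v]] <- as.numeric(scale(dat[[v]]))

    base_reml <- fit_lmm(dat, "scaled_rank", "elevation_z", method = "REML")
    pct <- variance_percentages(base_reml)

    rows <- list()
    for (p in config$stand_predictors)
      rows[[p]] <- fit_predictor_block(dat, p, levels = "plot")
    for (p in config$trait_predictors) {
      dat_t <- dat
      dat_t[[p]] <- env$traits[dat$species_id, p]
      dat_t <- dat_t[is.finite(dat_t[[p]]), , drop = FALSE]
      dat_t[[p]] <- as.numeric(scale(dat_t[[p]]))
      rows[[p]] <- fit_predictor_block(dat_t, p, levels = c("family", "species"))
    }
    tab <- do.call(rbind, rows)

    # phylogenetic signal of species susceptibility: conditional modes of
    # the species-in-family term (+ its family's mode), and of the
    # conditional residuals aggregated per species
    re <- base_reml$random_effect_predictions
    spp_modes <- re$species
    sp_names <- sub("^.*:", "", names(spp_modes))
    fam_names <- sub(":.*$", "", names(spp_modes))
    sp_eff <- spp_modes + re$family[fam_names]
    names(sp_eff) <- sp_names
    keep_tips <- intersect(env$tree$tip.label, sp_names)
    sub_tree <- ape::keep.tip(env$tree, keep_tips)
    sig_seed <- spawn_seeds(stage_seeds[["attribution"]], 2L)
    signal <- list()
    if (length(keep_tips) >= 4L) {
      signal$species_effects <- list(
        blomberg = unclass(blomberg_K(sub_tree, sp_eff[keep_tips], seed = sig_seed[1])),
        pagel = unclass(pagel_lambda(sub_tree, sp_eff[keep_tips])))
      cond_res <- dat$scaled_rank - predict(base_reml$mermod, newdata = NULL)
      res_by_sp <- tapply(cond_res, dat$species_id, mean)
      rv <- res_by_sp[keep_tips]
      signal$conditional_residuals <- list(
        blomberg = unclass(blomberg_K(sub_tree, rv, seed = sig_seed[2])),
        pagel = unclass(pagel_lambda(sub_tree, rv)))
    }

    d <- file.path(out, "attribution"); dir.create(d, showWarnings = FALSE)
    utils::write.csv(tab, file.path(d, "fixed_effects.csv"), row.names = FALSE)
    jsonlite::write_json(list(variance_components = as.list(base_reml$variance_components),
                              percentages = as.list(pct)),
                         file.path(d, "variance_components.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(signal, file.path(d, "phylo_signal.json"),
                         auto_unbox = TRUE, digits = NA)
    env$attribution <- list(table = tab, percentages = pct, signal = signal)
  })

  run_stage("community", function() {
    keep_axes <- setdiff(colnames(env$traits), config$exclude_from_community)
    traits <- impute_traits(env$traits[, keep_axes, drop = FALSE],
                            seed = stage_seeds[["community"]])
    state <- basal_area_states(env$trees)
    m <- cwm(state, traits)
    fd <- fdis(state, traits)
    tests <- lapply(colnames(traits), function(ax)
      paired_t(m$before[, ax], m$after[, ax]))
    names(tests) <- colnames(traits)
    tests$FDis <- paired_t(fd$before, fd$after)

    d <- file.path(out, "community"); dir.create(d, showWarnings = FALSE)
    utils::write.csv(data.frame(plot_id = rownames(m$before),
                                before = m$before, after = m$after,
                                fdis_before = fd$before, fdis_after = fd$after,
                                row.names = NULL),
                     file.path(d, "cwm_fdis.csv"), row.names = FALSE)
    jsonlite::write_json(tests, file.path(d, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
    env$community <- list(cwm = m, fdis = fd, tests = tests)
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$input_hashes <- as.list(tools::md5sum(files))
  names(manifest$input_hashes) <- substring(files, nchar(out) + 2)
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(results = as.list(env))))
}
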