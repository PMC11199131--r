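#' Default pipeline configuration
#'
#' Flat named list of every tunable the pipeline stages use, with the
#' standard analysis values as defaults: fix filters (5 satellites, residual
#' 35, 5.5 m/s, 100 km study area), pseudo-absence scheme (5 km / 2 km
#' buffers, OCSVM nu), NEK candidate grid and distance scale, cross-validation
#' (k = 5 spatial folds from 100 assignment iterations, leave-one-individual-
#' out for the individual model), fishing kernel density (3 km grid, 5 km
#' radius) and the 5 NM subregion boundary, plus the synthetic study-system
#' sizes used when the pipeline simulates its own inputs.
#'
#' @param ... overrides (name = value).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    # synthetic world
    extent_km_x = 120, extent_km_y = 300, cell_m = 1000,
    n_individuals = 9, fixes_per_id = 200,
    a_true = 0.05, d0_km = 10, sigma_id = 1, bad_fix_rate = 0.05,
    n_industrial = 1200, n_artisanal = 600, nearshore_industrial_frac = 0.2,
    # telemetry filters
    min_sats = 5, max_residual = 35, vmax = 5.5, roa_km = 100,
    # pseudo-absences
    buffer_population_m = 5000, buffer_individual_m = 2000, ocsvm_nu = 0.1,
    # models
    nek_n_candidates = 10, nek_lo = 0.001, nek_hi = 0.9,
    elimination_tol = 0.001,
    # evaluation
    cv_k = 5, cv_n_iter = 100, block_side_m = NA,
    # risk
    kde_cell_m = 3000, kde_radius_m = 5000, subregion_nm_m = 9260)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Read / write a flat key = value config file
#' @param path file path.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_config
#' @param config config list.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

stage_dir <- function(outdir, stage) file.path(outdir, stage)

write_manifest <- function(dir, stage, seed, config) {
  files <- setdiff(list.files(dir), "manifest.json")
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         version = as.character(utils::packageVersion("cpfrisk")),
         files = as.list(stats::setNames(
           unname(tools::md5sum(file.path(dir, files))), files)),
         config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

need_stage <- function(outdir, stage) {
  if (!file.exists(file.path(outdir, stage, "manifest.json")))
    stop("missing upstream artefacts: run stage '", stage, "' first")
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# rebuild the synthetic world deterministically from the config (rasters on
# disk are for external consumption; stages rebuild the stack from seed to
# avoid text-roundtrip noise)
config_world <- function(config) {
  make_environment(seed = config$seed,
                   extent_km = c(config$extent_km_x, config$extent_km_y),
                   cell_m = config$cell_m, roa_km = config$roa_km)
}

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow on the synthetic study system:
#' `simulate` (world, tracks, fishing), `preprocess` (fix filters +
#' rarefaction), `pseudoabs` (profiling + pseudo-absences for both schemes),
#' `fit` (collinearity screen, spatial-block folds, backward elimination,
#' population GLM, NEK selection, individual GLMM), `evaluate` (blocked CV,
#' LOIO CV, residual variogram), `predict` (suitability surfaces),
#' `combine` (bivariate classification) and `risk` (fishing KDE,
#' exposure-consequence risk, subregion statistics). `all` runs every stage
#' in order. Each stage writes CSV/ASCII-grid artefacts plus a manifest with
#' content hashes, the seed and the config echo; no stage mutates an
#' upstream artefact.
#'
#' @param stage one of simulate, preprocess, pseudoabs, fit, evaluate,
#'   predict, combine, risk, all.
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @param outdir artefact directory (one subdirectory per stage).
#' @param quiet suppress progress messages.
#' @return (invisibly) the outdir.
#' @export
run_pipeline <- function(stage = "all", config = default_config(),
                         outdir = tempfile("cpfrisk_run_"), quiet = FALSE) {
  stages <- c("simulate", "preprocess", "pseudoabs", "fit", "evaluate",
              "predict", "combine", "risk")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cpfrisk] ", ...)
  for (st in todo) {
    say("stage ", st)
    get(paste0("stage_", st), mode = "function")(config, outdir)
    write_manifest(stage_dir(outdir, st), st, config$seed, config)
  }
  invisible(outdir)
}

stage_simulate <- function(config, outdir) {
  d <- stage_dir(outdir, "simulate")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  sim <- simulate_tracks(w, n_individuals = config$n_individuals,
                         fixes_per_id = config$fixes_per_id,
                         a_true = config$a_true, d0_km = config$d0_km,
                         sigma_id = config$sigma_id,
                         bad_fix_rate = config$bad_fix_rate,
                         vmax = config$vmax, seed = config$seed + 1)
  fish <- simulate_fishing(w, n_industrial = config$n_industrial,
                           n_artisanal = config$n_artisanal,
                           nearshore_industrial_frac =
                             config$nearshore_industrial_frac,
                           nearshore_m = config$subregion_nm_m,
                           seed = config$seed + 2)
  write_csv(sim$fixes, file.path(d, "telemetry.csv"))
  write_csv(sim$truth, file.path(d, "corruption_truth.csv"))
  write_csv(data.frame(individual_id = names(sim$b_i), b_i = sim$b_i),
            file.path(d, "individual_intercepts_truth.csv"))
  write_csv(fish$industrial, file.path(d, "fishing_industrial.csv"))
  write_csv(fish$artisanal, file.path(d, "fishing_artisanal.csv"))
  for (nm in names(w$tstack$layers))
    write_ascii_grid(w$tstack$layers[[nm]],
                     file.path(d, paste0("covariate_", nm, ".asc")))
  write_ascii_grid(w$land_mask, file.path(d, "land_mask.asc"))
  write_ascii_grid(w$dist_shore, file.path(d, "dist_shore.asc"))
  write_ascii_grid(w$suitability, file.path(d, "true_suitability.asc"))
  write_csv(w$tstack$bounds, file.path(d, "rescale_bounds.csv"))
}

stage_preprocess <- function(config, outdir) {
  need_stage(outdir, "simulate")
  d <- stage_dir(outdir, "preprocess")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  fixes <- read_fixes_csv(file.path(outdir, "simulate", "telemetry.csv"))
  res <- filter_fixes(fixes, w$land_mask, w$dist_shore,
                      min_sats = config$min_sats,
                      max_residual = config$max_residual,
                      vmax = config$vmax,
                      max_dist_m = config$roa_km * 1000)
  write_csv(res$audit, file.path(d, "filter_audit.csv"))
  write_csv(res$fixes, file.path(d, "fixes_flagged.csv"))
  write_csv(res$retained, file.path(d, "fixes_retained.csv"))
  pres_pop <- grid_rarefy(res$retained, w$grid, "population")
  pres_ind <- grid_rarefy(res$retained, w$grid, "individual")
  write_csv(pres_pop, file.path(d, "presences_population.csv"))
  write_csv(pres_ind, file.path(d, "presences_individual.csv"))
}

pipeline_covariates <- function() {
  c("sst", "chl", "eke", "depth", "slope", "dist_rivers", "dist_shore",
    "dist_shelf")
}

stage_pseudoabs <- function(config, outdir) {
  need_stage(outdir, "preprocess")
  d <- stage_dir(outdir, "pseudoabs")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  covs <- pipeline_covariates()
  pres_pop <- utils::read.csv(file.path(outdir, "preprocess",
                                        "presences_population.csv"))
  pres_ind <- utils::read.csv(file.path(outdir, "preprocess",
                                        "presences_individual.csv"))
  env_pop <- extract_covariates(w$tstack, pres_pop$x, pres_pop$y)
  prof <- ocsvm_profile(env_pop, w$tstack, nu = config$ocsvm_nu)
  write_ascii_grid(prof$classification, file.path(d, "ocsvm_population.asc"))
  pa_pop <- sample_population_pa(prof$classification, pres_pop,
                                 buffer_m = config$buffer_population_m,
                                 seed = config$seed + 3)
  pa_ind <- sample_individual_pa(pres_ind, w$tstack,
                                 buffer_m = config$buffer_individual_m,
                                 nu = config$ocsvm_nu,
                                 seed = config$seed + 4)
  lab <- function(pres, pa, scheme) {
    rbind(data.frame(x = pres$x, y = pres$y, label = 1,
                     individual_id = pres$individual_id),
          data.frame(x = pa$x, y = pa$y, label = 0,
                     individual_id = pa$individual_id))
  }
  pop <- lab(pres_pop, pa_pop)
  ind <- lab(pres_ind, pa_ind)
  pop <- cbind(pop, extract_covariates(w$tstack, pop$x, pop$y))
  ind <- cbind(ind, extract_covariates(w$tstack, ind$x, ind$y))
  write_csv(pop, file.path(d, "samples_population.csv"))
  write_csv(ind, file.path(d, "samples_individual.csv"))
}

stage_fit <- function(config, outdir) {
  need_stage(outdir, "pseudoabs")
  d <- stage_dir(outdir, "fit")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  pop <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_population.csv"))
  ind <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_individual.csv"))
  covs <- pipeline_covariates()
  scr <- collinearity_screen(pop[covs])
  write_csv(data.frame(layer = scr$retained), file.path(d, "screen_retained.csv"))
  write_csv(scr$dropped, file.path(d, "screen_dropped.csv"))
  covs <- scr$retained
  # spatial block size from the median variogram range of the covariates
  block_side <- config$block_side_m
  if (is.na(block_side) || is.null(block_side)) {
    sub <- with_seed(config$seed + 7,
                     pop[sample.int(nrow(pop), min(800, nrow(pop))), ])
    rngs <- vapply(covs, function(v) {
      tryCatch(variogram_range(sub[[v]], sub$x, sub$y)$range,
               error = function(e) NA_real_)
    }, 0)
    block_side <- stats::median(rngs, na.rm = TRUE)
    write_csv(data.frame(layer = names(rngs), range_m = rngs),
              file.path(d, "variogram_ranges.csv"))
  }
  folds <- with_seed(config$seed + 5,
                     make_spatial_blocks(pop, block_side, k = config$cv_k,
                                         n_iter = config$cv_n_iter))
  write_csv(data.frame(fold = folds$fold), file.path(d, "folds_population.csv"))
  write_csv(folds$blocks, file.path(d, "blocks.csv"))
  elim <- backward_eliminate(pop, covs, folds$fold,
                             tol = config$elimination_tol)
  write_csv(elim$trace, file.path(d, "elimination_trace.csv"))
  glm_fit <- fit_glm(pop, elim$retained, on_separation = "warn")
  write_model_json(glm_fit, file.path(d, "model_glm.json"),
                   meta = list(seed = config$seed, block_side_m = block_side))
  write_csv(variable_importance(glm_fit), file.path(d, "glm_importance.csv"))
  # NEK selection and individual model on the screened covariates
  cand <- nek_candidates(config$nek_n_candidates, config$nek_lo,
                         config$nek_hi)
  sel <- select_nek_a(ind, covs, w$colony, candidates = cand,
                      d0_km = config$d0_km)
  write_csv(sel$scores, file.path(d, "nek_scores.csv"))
  ind$nek <- nek_at(ind$x, ind$y, w$colony, sel$a, config$d0_km)
  glmm_fit <- fit_glmm(ind, c(covs, "nek"))
  write_model_json(glmm_fit, file.path(d, "model_glmm.json"),
                   meta = list(seed = config$seed, nek_a = sel$a,
                               d0_km = config$d0_km))
}

stage_evaluate <- function(config, outdir) {
  need_stage(outdir, "fit")
  d <- stage_dir(outdir, "evaluate")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  pop <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_population.csv"))
  ind <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_individual.csv"))
  glm_meta <- jsonlite::read_json(file.path(outdir, "fit", "model_glm.json"))
  glmm_meta <- jsonlite::read_json(file.path(outdir, "fit", "model_glmm.json"))
  covs_glm <- unlist(glm_meta$covariates)
  folds <- utils::read.csv(file.path(outdir, "fit", "folds_population.csv"))$fold
  rep_glm <- run_blocked_cv(pop, covs_glm, folds)
  covs_glmm <- setdiff(unlist(glmm_meta$covariates), "nek")
  ind$nek <- nek_at(ind$x, ind$y, w$colony, glmm_meta$meta$nek_a,
                    glmm_meta$meta$d0_km)
  rep_glmm <- run_loio_cv(ind, c(covs_glmm, "nek"))
  write_csv(rep_glm$folds, file.path(d, "cv_population.csv"))
  write_csv(rep_glmm$folds, file.path(d, "cv_individual.csv"))
  summ <- rbind(
    data.frame(model = "glm_blocked", metric = names(rep_glm$mean),
               mean = as.numeric(rep_glm$mean), sd = as.numeric(rep_glm$sd)),
    data.frame(model = "glmm_loio", metric = names(rep_glmm$mean),
               mean = as.numeric(rep_glmm$mean), sd = as.numeric(rep_glmm$sd)))
  write_csv(summ, file.path(d, "metrics_summary.csv"))
  # residual variogram of the final population model
  glm_fit <- fit_glm(pop, covs_glm, on_separation = "warn")
  resid <- pop$label - predict_samples(glm_fit, pop)
  sub <- with_seed(config$seed + 6,
                   pop[sample.int(nrow(pop), min(800, nrow(pop))), ])
  resid_sub <- sub$label - predict_samples(glm_fit, sub)
  vg <- variogram_range(resid_sub, sub$x, sub$y)
  write_csv(data.frame(lag_m = vg$lag, gamma = vg$gamma, count = vg$counts,
                       range_m = vg$range, nugget = vg$nugget,
                       psill = vg$psill),
            file.path(d, "residual_variogram.csv"))
}

stage_predict <- function(config, outdir) {
  need_stage(outdir, "fit")
  d <- stage_dir(outdir, "predict")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  glm_meta <- jsonlite::read_json(file.path(outdir, "fit", "model_glm.json"))
  glmm_meta <- jsonlite::read_json(file.path(outdir, "fit", "model_glmm.json"))
  pop <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_population.csv"))
  ind <- utils::read.csv(file.path(outdir, "pseudoabs",
                                   "samples_individual.csv"))
  covs_glm <- unlist(glm_meta$covariates)
  glm_fit <- fit_glm(pop, covs_glm, on_separation = "warn")
  pred_pop <- predict_surface(glm_fit, w$tstack, mode = "marginal")
  write_ascii_grid(pred_pop, file.path(d, "prediction_population.asc"))
  covs_glmm <- unlist(glmm_meta$covariates)
  a <- glmm_meta$meta$nek_a
  ind$nek <- nek_at(ind$x, ind$y, w$colony, a, glmm_meta$meta$d0_km)
  glmm_fit <- fit_glmm(ind, covs_glmm)
  nek_layer <- nek_surface(w$grid, w$colony, a, glmm_meta$meta$d0_km)$raster
  stack2 <- covariate_stack(c(w$tstack$layers, list(nek = nek_layer)))
  conds <- lapply(names(glmm_fit$ranef), function(id)
    predict_surface(glmm_fit, stack2, mode = "conditional", id = id))
  names(conds) <- names(glmm_fit$ranef)
  for (id in names(conds))
    write_ascii_grid(conds[[id]],
                     file.path(d, paste0("prediction_conditional_", id, ".asc")))
  write_ascii_grid(predict_surface(glmm_fit, stack2, mode = "novel"),
                   file.path(d, "prediction_novel.asc"))
  write_ascii_grid(aggregate_individual(conds, "max"),
                   file.path(d, "prediction_individual_max.asc"))
  write_ascii_grid(aggregate_individual(conds, "mean"),
                   file.path(d, "prediction_individual_mean.asc"))
}

stage_combine <- function(config, outdir) {
  need_stage(outdir, "predict")
  d <- stage_dir(outdir, "combine")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  pop <- read_ascii_grid(file.path(outdir, "predict",
                                   "prediction_population.asc"))
  ind <- read_ascii_grid(file.path(outdir, "predict",
                                   "prediction_individual_max.asc"))
  bv <- bivariate_classify(pop, ind)
  write_ascii_grid(bv$pop_tercile, file.path(d, "tercile_population.asc"))
  write_ascii_grid(bv$ind_tercile, file.path(d, "tercile_individual.asc"))
  write_ascii_grid(bv$joint, file.path(d, "class_joint.asc"))
  write_ascii_grid(bv$overall, file.path(d, "class_overall.asc"))
  write_ascii_grid(distribution_reclass(bv),
                   file.path(d, "distribution_class.asc"))
  jsonlite::write_json(bv$breaks, file.path(d, "tercile_breaks.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_risk <- function(config, outdir) {
  need_stage(outdir, "combine")
  d <- stage_dir(outdir, "risk")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  w <- config_world(config)
  # 3 km analysis grid for the risk model
  fac <- config$kde_cell_m / w$grid$cell
  kgrid <- grid_template(floor(w$grid$n_rows / fac), floor(w$grid$n_cols / fac),
                         cell = config$kde_cell_m,
                         x0 = w$grid$x0, y0 = w$grid$y0 +
                           (w$grid$n_rows - floor(w$grid$n_rows / fac) * fac) *
                           w$grid$cell)
  dist_cls <- read_ascii_grid(file.path(outdir, "combine",
                                        "distribution_class.asc"))
  ax <- grid_axes(kgrid)
  co <- grid_coords(kgrid)
  dist_k <- grid_like(kgrid, matrix(grid_value_at(dist_cls, co$x, co$y),
                                    kgrid$n_rows, kgrid$n_cols))
  sub_k <- grid_like(kgrid, matrix(grid_value_at(w$dist_shore, co$x, co$y),
                                   kgrid$n_rows, kgrid$n_cols))
  land_k <- grid_value_at(w$land_mask, co$x, co$y)
  sub_k$values[!is.na(land_k) & land_k == 1] <- NA
  subreg <- subregion_raster(sub_k, boundary_m = config$subregion_nm_m,
                             max_m = config$roa_km * 1000)
  fleets <- list(
    industrial = utils::read.csv(file.path(outdir, "simulate",
                                           "fishing_industrial.csv")),
    artisanal = utils::read.csv(file.path(outdir, "simulate",
                                          "fishing_artisanal.csv")))
  risks <- list(); Es <- list(); Cs <- list()
  for (fl in names(fleets)) {
    pts <- fleets[[fl]]
    kde <- fishing_kde(pts$x, pts$y, kgrid, radius_m = config$kde_radius_m,
                       weights = pts$count)
    write_ascii_grid(kde, file.path(d, paste0("kde_", fl, ".asc")))
    intens <- quantile_reclass(kde)
    likel <- interaction_likelihood(intens, dist_k)
    overlap <- grid_like(kgrid,
                         as.numeric(!is.na(dist_k$values) &
                                      dist_k$values >= 2 &
                                      kde$values > 0))
    # subregion-specific criteria merged cell-wise along the 5 NM boundary
    E <- grid_like(kgrid, NA_real_); C <- grid_like(kgrid, NA_real_)
    for (sr in c("nearshore", "offshore")) {
      crit <- default_criteria_table(fl, sr)
      ec <- ec_scores(crit, spatial_layers = list(intensity = intens,
                                                  likelihood = likel),
                      template = kgrid)
      in_sr <- !is.na(subreg$values) & subreg$values == (if (sr == "nearshore") 1 else 2)
      E$values[in_sr] <- ec$E$values[in_sr]
      C$values[in_sr] <- ec$C$values[in_sr]
    }
    risks[[fl]] <- risk_surface(E, C, overlap)
    Es[[fl]] <- E; Cs[[fl]] <- C
    write_ascii_grid(risks[[fl]], file.path(d, paste0("risk_", fl, ".asc")))
    write_csv(rbind(default_criteria_table(fl, "nearshore"),
                    default_criteria_table(fl, "offshore")),
              file.path(d, paste0("criteria_", fl, ".csv")))
  }
  cum <- cumulative_and_stats(risks, subreg, Es, Cs,
                              subregion_names = list("1" = "nearshore",
                                                     "2" = "offshore"))
  write_ascii_grid(cum$cumulative, file.path(d, "risk_cumulative.asc"))
  write_csv(cum$stats, file.path(d, "risk_stats.csv"))
  write_csv(cum$ec_scatter, file.path(d, "ec_scatter.csv"))
  write_csv(uncertainty_table(), file.path(d, "uncertainty_stoplight.csv"))
  write_ascii_grid(subreg, file.path(d, "subregions.asc"))
}
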