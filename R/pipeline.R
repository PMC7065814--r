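# End-to-end orchestration: simulate (or load) samples, build the variable
# table, select and fit the PLS model, score it against the OLS and PCR
# baselines, and produce a classified GPC map. Every stage is seeded from
# the configuration, so a rerun with the same configuration is
# byte-identical; every artifact carries the configuration hash.

#' Pipeline configuration
#'
#' Validated bundle of every tunable of [run_pipeline()], with the
#' defaults of the reference analysis: four sensitive indices (NDVI, SIPI,
#' PSRI, EVI) as predictors, PRESS search up to 10 components, a 3:2
#' modeling/verification split, relative accuracy, the green-band EVI
#' variant, and GPC map classes cut at 11.3 / 11.8 / 12.5 %.
#'
#' @param n_samples Number of synthetic field samples.
#' @param predictors Predictor variable names (subset of
#'   [variable_names()]).
#' @param a_max Largest candidate component count for the PRESS search.
#' @param split_ratio Modeling-set proportion.
#' @param seed Master RNG seed; stage seeds are derived from it.
#' @param accuracy Accuracy definition, `"relative"` or `"mae"`
#'   (see [score()]).
#' @param evi_variant `"green"` or `"blue"` (see [compute_indices()]).
#' @param bin_edges GPC class boundaries (%) for the map.
#' @param lr_predictors `"selected"` fits the OLS baseline on the same
#'   predictors as PLS; `"all"` uses all 14 variables.
#' @param pcr_components Components retained by the PCR baseline.
#' @param scene_rows,scene_cols,wheat_fraction Synthetic scene geometry.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 255,
                            predictors = c("NDVI", "SIPI", "PSRI", "EVI"),
                            a_max = 10,
                            split_ratio = 0.6,
                            seed = 1L,
                            accuracy = c("relative", "mae"),
                            evi_variant = c("green", "blue"),
                            bin_edges = c(11.3, 11.8, 12.5),
                            lr_predictors = c("selected", "all"),
                            pcr_components = 5,
                            scene_rows = 48, scene_cols = 48,
                            wheat_fraction = 0.6,
                            out_dir = tempfile("wheatgpc_run_")) {
  accuracy <- match.arg(accuracy)
  evi_variant <- match.arg(evi_variant)
  lr_predictors <- match.arg(lr_predictors)
  if (!all(predictors %in% variable_names())) {
    stop(sprintf("unknown predictor(s): %s",
                 paste(setdiff(predictors, variable_names()),
                       collapse = ", ")), call. = FALSE)
  }
  if (a_max < 1) stop("`a_max` must be at least 1", call. = FALSE)
  # PLS1 on p predictors supports at most p components
  a_max <- min(a_max, length(predictors))
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         predictors = predictors,
         a_max = as.integer(a_max),
         split_ratio = split_ratio,
         seed = as.integer(seed),
         accuracy = accuracy,
         evi_variant = evi_variant,
         bin_edges = bin_edges,
         lr_predictors = lr_predictors,
         pcr_components = as.integer(pcr_components),
         scene_rows = as.integer(scene_rows),
         scene_cols = as.integer(scene_cols),
         wheat_fraction = wheat_fraction,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   re-validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Hash of a pipeline configuration
#'
#' FNV-1a hash of the canonical YAML rendering, excluding the output
#' directory (so the same analysis written elsewhere hashes identically).
#' Stamped on every pipeline artifact.
#'
#' @param config A [pipeline_config()].
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a_hash(yaml::as.yaml(cfg))
}

#' Run the full GPC pipeline
#'
#' Stages: simulate field samples, build the 14-variable table, split 3:2,
#' select the component count at the PRESS minimum and fit PLS on the
#' modeling set, fit the OLS and PCR baselines, score every model on both
#' sets, and produce a classified GPC map from a simulated scene. All
#' artifacts are written under `config$out_dir`:
#' `config.yaml`, `model.json` (PLS + PRESS curve), `model_ols.json`,
#' `model_pcr.json`, `press_curve.csv`, `samples.csv`,
#' `gpc_summary.json`, `correlations.csv`, `comparison.json`, and the map
#' layers of [export_map()] under `map/`.
#'
#' @param config A [pipeline_config()].
#' @param samples Optional data frame of field samples (columns `r_blue`,
#'   `r_green`, `r_red`, `r_nir`, `gpc`); when omitted, samples are
#'   simulated under `config$seed`.
#' @return Invisibly, a list with every intermediate object (`samples`,
#'   `table`, `split`, `press`, `model`, `baselines`, `reports`,
#'   `comparison`, `grid`, `hash`).
#' @export
run_pipeline <- function(config, samples = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(config$out_dir, "config.yaml"))

  # -- simulate ------------------------------------------------------------
  params <- scene_params(n_samples = config$n_samples, seed = config$seed)
  if (is.null(samples)) {
    samples <- generate_samples(params)
    message(sprintf("[simulate] generated %d samples", nrow(samples)))
  } else {
    message(sprintf("[simulate] using %d supplied samples", nrow(samples)))
  }
  utils::write.csv(samples, file.path(config$out_dir, "samples.csv"),
                   row.names = FALSE)

  # -- indices -------------------------------------------------------------
  vt <- build_variable_table(samples, evi_variant = config$evi_variant)
  message(sprintf("[indices] variable table: %d x %d", nrow(vt),
                  length(variable_names())))

  # -- split + summaries ---------------------------------------------------
  split <- split_samples(vt$gpc, ratio = config$split_ratio,
                         seed = config$seed + 1L)
  summaries <- rbind(
    summary_stats(vt$gpc[split$modeling_ids], "modeling"),
    summary_stats(vt$gpc[split$verification_ids], "verification")
  )
  jsonlite::write_json(list(config_hash = hash, sets = summaries),
                       file.path(config$out_dir, "gpc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  corr <- correlation_matrix(vt)
  utils::write.csv(round(corr$r, 4),
                   file.path(config$out_dir, "correlations.csv"))
  message(sprintf("[split] modeling %d / verification %d",
                  length(split$modeling_ids),
                  length(split$verification_ids)))

  # -- fit -----------------------------------------------------------------
  Xm <- vt[split$modeling_ids, config$predictors, drop = FALSE]
  ym <- vt$gpc[split$modeling_ids]
  Xv <- vt[split$verification_ids, config$predictors, drop = FALSE]
  yv <- vt$gpc[split$verification_ids]
  press <- press_curve(Xm, ym, a_max = config$a_max)
  a_opt <- select_components(press)
  model <- fit_pls(Xm, ym, a = a_opt)
  write_model(model, file.path(config$out_dir, "model.json"), press = press)
  pc <- data.frame(config_hash = hash, a = press$a_values,
                   press = press$press)
  utils::write.csv(pc, file.path(config$out_dir, "press_curve.csv"),
                   row.names = FALSE)
  message(sprintf("[fit] PRESS minimum at a = %d (PRESS = %.3f)",
                  a_opt, min(press$press)))

  # -- baselines -----------------------------------------------------------
  lr_vars <- if (config$lr_predictors == "selected") config$predictors
             else variable_names()
  ols <- fit_ols(vt[split$modeling_ids, lr_vars, drop = FALSE], ym)
  pcr <- fit_pcr(vt[split$modeling_ids, variable_names(), drop = FALSE],
                 ym, n_components = config$pcr_components)
  write_model(ols, file.path(config$out_dir, "model_ols.json"))
  write_model(pcr, file.path(config$out_dir, "model_pcr.json"))

  # -- evaluate ------------------------------------------------------------
  score_both <- function(m, Xmod, Xver) {
    list(
      modeling = score(ym, predict(m, Xmod), accuracy = config$accuracy,
                       label = "modeling"),
      verification = score(yv, predict(m, Xver),
                           accuracy = config$accuracy,
                           label = "verification")
    )
  }
  reports <- list(
    pls = score_both(model, Xm, Xv),
    lr = score_both(ols, vt[split$modeling_ids, lr_vars, drop = FALSE],
                    vt[split$verification_ids, lr_vars, drop = FALSE]),
    pcr = score_both(pcr,
                     vt[split$modeling_ids, variable_names(), drop = FALSE],
                     vt[split$verification_ids, variable_names(),
                        drop = FALSE])
  )
  comparison <- compare_models(reports)
  jsonlite::write_json(
    list(config_hash = hash, table = comparison$table,
         accuracy_deltas = lapply(comparison$accuracy_deltas, function(m) {
           as.data.frame(m)
         })),
    file.path(config$out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA)
  message(sprintf("[evaluate] verification RMSE: PLS %.3f | LR %.3f | PCR %.3f",
                  reports$pls$verification$rmse,
                  reports$lr$verification$rmse,
                  reports$pcr$verification$rmse))

  # -- map -----------------------------------------------------------------
  scene <- generate_scene(config$scene_rows, config$scene_cols,
                          config$wheat_fraction,
                          scene_params(n_samples = config$n_samples,
                                       seed = config$seed + 2L))
  grids <- compute_index_grids(scene$bands, scene$mask,
                               evi_variant = config$evi_variant)
  grid <- predict_grid(model, grids, scene$mask)
  grid <- classify_gpc(grid, bin_edges = config$bin_edges)
  export_map(grid, file.path(config$out_dir, "map"))
  message(sprintf("[map] %d x %d scene, %d wheat cells classified",
                  config$scene_rows, config$scene_cols,
                  sum(grid$mask, na.rm = TRUE)))

  invisible(list(samples = samples, table = vt, split = split,
                 press = press, model = model,
                 baselines = list(ols = ols, pcr = pcr),
                 reports = reports, comparison = comparison,
                 grid = grid, hash = hash))
}
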