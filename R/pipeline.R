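#' Pipeline configuration
#'
#' Defaults follow the classical optimized-MaxEnt protocol: 1-km spatial
#' thinning (30 arc-second buckets), contribution pre-screen then Pearson
#' |r| <= 0.85 collinearity filter, an 8 x 6 RM-by-FC AICc tuning grid
#' (RM 0.5-4.0 step 0.5; FC L, H, LQ, LQH, LQHP, LQHPT), 10,000 background
#' points, a 500-iteration ceiling, 10 bootstrap replicates with a 75/25
#' split, and fixed 0.1/0.3/0.5 suitability breaks.
#'
#' @param scene a [scene_config()] for a synthetic run, or `NULL` when
#'   `layer_paths`/`occurrence_path` point at files.
#' @param layer_paths named character vector of ESRI ASCII grid paths.
#' @param occurrence_path occurrence CSV path.
#' @param future_paths named list (scenario -> named vector of layer paths).
#' @param thin_cell_size thinning bucket edge in degrees.
#' @param min_year cleaning cutoff year (NULL to keep all).
#' @param min_contribution pre-screen threshold, percent.
#' @param cor_threshold collinearity threshold on |r|.
#' @param rms,fcs tuning grid.
#' @param n_background background sample size.
#' @param max_iterations fitting cycle ceiling.
#' @param replicates bootstrap replicates.
#' @param train_fraction training fraction.
#' @param breaks suitability class breaks.
#' @param n_hinge_knots,n_threshold_knots feature knot counts.
#' @param seed master seed; every stochastic stage derives a sub-seed.
#' @param output_dir artifact directory (NULL: no files written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, layer_paths = NULL,
                            occurrence_path = NULL, future_paths = NULL,
                            thin_cell_size = 1 / 120, min_year = 2000,
                            min_contribution = 1, cor_threshold = 0.85,
                            rms = seq(0.5, 4, by = 0.5),
                            fcs = c("L", "H", "LQ", "LQH", "LQHP", "LQHPT"),
                            n_background = 10000, max_iterations = 500,
                            replicates = 10, train_fraction = 0.75,
                            breaks = c(0.1, 0.3, 0.5),
                            n_hinge_knots = 50, n_threshold_knots = 20,
                            seed = 1L, output_dir = NULL) {
  if (is.null(scene) && (is.null(layer_paths) || is.null(occurrence_path)))
    stop("either a synthetic scene or layer_paths + occurrence_path is required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML with keys matching the [pipeline_config()] arguments; a `scene:`
#' block with `layers`, `niche` (`linear`/`quadratic`/`intercept` maps),
#' and the other [scene_config()] fields describes a synthetic run.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scene)) {
    s <- y$scene
    niche <- niche_spec(linear = unlist(s$niche$linear),
                        quadratic = unlist(s$niche$quadratic),
                        intercept = if (is.null(s$niche$intercept)) 0
                                    else s$niche$intercept)
    cm <- NULL
    if (!is.null(s$target_corr)) {
      cm <- do.call(rbind, s$target_corr)
    }
    y$scene <- scene_config(
      n_row = s$n_row, n_col = s$n_col,
      cell_size = if (is.null(s$cell_size)) 0.025 else s$cell_size,
      layer_names = unlist(s$layer_names),
      corr_length = if (is.null(s$corr_length)) 10 else s$corr_length,
      target_corr = cm, niche = niche,
      n_presence = if (is.null(s$n_presence)) 157 else s$n_presence,
      seed = if (is.null(s$seed)) 1L else s$seed,
      future_deltas = unlist(s$future_deltas))
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

write_csv_artifact <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full modeling pipeline
#'
#' Executes clean, thin, screen, tune, bootstrap fit/evaluate, predict
#' (current and each scenario), classify, area accounting, change mapping,
#' and centroid-shift analysis, writing all tables as CSV plus a JSON
#' report when `output_dir` is set. Identical config + seed gives
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- list(settings = list(seed = seed,
                                 cor_threshold = config$cor_threshold,
                                 n_background = config$n_background,
                                 replicates = config$replicates))

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$scene)) {
    scene <- make_scene(config$scene)
    stack <- scene$stack
    occ_raw <- scene$occurrences
    futures <- if (!is.null(scene$future)) list(future = scene$future) else list()
  } else {
    stack <- grid_stack(lapply(names(config$layer_paths), function(nm)
      read_grid(config$layer_paths[[nm]], name = nm)))
    occ_raw <- read_occurrences(config$occurrence_path, config$min_year)
    futures <- lapply(config$future_paths, function(paths)
      grid_stack(lapply(names(paths), function(nm) read_grid(paths[[nm]], name = nm))))
  }

  # -- occurrence prep ------------------------------------------------------
  occ <- thin_one_per_cell(occ_raw, config$thin_cell_size)
  report$occurrences <- list(raw = nrow(occ_raw), thinned = nrow(occ))

  background <- sample_background(stack, config$n_background,
                                  seed = stage_seed(seed, "background"))
  presence <- extract_at_points(stack, occ, "presence")

  # -- variable screening ---------------------------------------------------
  trial <- fit_maxent(presence, background, fc = "LQH", rm = 1,
                      max_iterations = config$max_iterations,
                      n_hinge_knots = config$n_hinge_knots,
                      n_threshold_knots = config$n_threshold_knots)
  contrib <- percent_contribution(trial)
  pre <- contribution_screen(contrib, config$min_contribution)
  corr <- pearson_matrix(rbind(presence$env, background$env))
  selected <- collinearity_filter(corr[pre, pre, drop = FALSE],
                                  contrib[contrib$variable %in% pre, ],
                                  config$cor_threshold)
  report$screening <- list(candidates = ncol(presence$env),
                           after_contribution = length(pre),
                           selected = selected)
  write_csv_artifact(contrib, dir, "contributions.csv")
  write_csv_artifact(as.data.frame(corr), dir, "correlations.csv")

  keep_stack <- grid_stack(stack[selected], selected)
  presence <- sample_matrix(presence$env[, selected, drop = FALSE],
                            presence$coords, presence$label)
  background <- sample_matrix(background$env[, selected, drop = FALSE],
                              background$coords, background$label)

  # -- tuning ---------------------------------------------------------------
  tuning <- tune_grid(occ, keep_stack, background, rms = config$rms,
                      fcs = config$fcs, seed = stage_seed(seed, "tuning"),
                      max_iterations = config$max_iterations,
                      n_hinge_knots = config$n_hinge_knots,
                      n_threshold_knots = config$n_threshold_knots)
  sel <- attr(tuning, "selected")
  report$tuning <- list(rm = sel$rm, fc = sel$fc, rows = nrow(tuning))
  write_csv_artifact(as.data.frame(tuning), dir, "tuning.csv")

  # -- bootstrap fit + evaluation ------------------------------------------
  ev <- bootstrap_evaluate(occ, keep_stack, background, fc = sel$fc,
                           rm = sel$rm, replicates = config$replicates,
                           train_fraction = config$train_fraction,
                           seed = stage_seed(seed, "bootstrap"),
                           max_iterations = config$max_iterations,
                           n_hinge_knots = config$n_hinge_knots,
                           n_threshold_knots = config$n_threshold_knots)
  report$evaluation <- list(auc_mean = ev$auc_mean, auc_sd = ev$auc_sd,
                            tss_mean = ev$tss_mean, tss_sd = ev$tss_sd)
  write_csv_artifact(ev$replicates, dir, "replicate_metrics.csv")

  final <- fit_maxent(presence, background, fc = sel$fc, rm = sel$rm,
                      max_iterations = config$max_iterations,
                      n_hinge_knots = config$n_hinge_knots,
                      n_threshold_knots = config$n_threshold_knots)
  imp <- permutation_importance(final, presence, background,
                                seed = stage_seed(seed, "importance"))
  report$importance <- stats::setNames(imp$importance, imp$variable)
  write_csv_artifact(imp, dir, "importance.csv")

  # -- projection, classification, areas ------------------------------------
  pred_now <- ev$mean_prediction
  if (!is.null(dir)) write_grid(pred_now, file.path(dir, "suitability_current.asc"))
  class_now <- classify(pred_now, config$breaks)
  at_now <- area_table(class_now)
  report$area <- list(current = as.data.frame(at_now))
  write_csv_artifact(as.data.frame(at_now), dir, "area_current.csv")

  scen_reports <- list()
  for (nm in names(futures)) {
    fstack <- grid_stack(futures[[nm]][selected], selected)
    preds <- lapply(ev$models, function(m) predict(m, fstack, type = "logistic"))
    vals <- Reduce(`+`, lapply(preds, `[[`, "values")) / length(preds)
    r <- fstack[[1L]]
    pred_f <- grid_raster(vals, r$origin_lon, r$origin_lat, r$cell_size,
                          name = paste0("suitability_", nm))
    if (!is.null(dir))
      write_grid(pred_f, file.path(dir, paste0("suitability_", nm, ".asc")))
    class_f <- classify(pred_f, config$breaks)
    at_f <- area_table(class_f)
    ch <- change_map(class_now, class_f)
    shift <- tryCatch({
      a <- class_centroid(class_now, "high")
      b <- class_centroid(class_f, "high")
      shift_vector(a, b)
    }, error = function(e) NULL)
    scen_reports[[nm]] <- list(
      area = as.data.frame(at_f),
      change = list(gain = ch$gain, loss = ch$loss,
                    stable_suitable = ch$stable_suitable,
                    stable_unsuitable = ch$stable_unsuitable,
                    gross_turnover = ch$gross_turnover,
                    net_change = ch$net_change),
      centroid_shift = if (!is.null(shift))
        list(from = shift$from, to = shift$to,
             distance_km = shift$distance_km,
             bearing = shift$bearing, direction = shift$direction))
    write_csv_artifact(as.data.frame(at_f), dir, paste0("area_", nm, ".csv"))
  }
  if (length(scen_reports)) report$scenarios <- scen_reports

  if (!is.null(dir))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
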