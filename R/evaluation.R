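#' Area under the ROC curve (presence vs background)
#'
#' Mann-Whitney formulation: the fraction of (presence, background) pairs
#' in which the presence scores higher, ties counting one half. Computed
#' from ranks, so it is exact and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximized true skill statistic
#'
#' Scans every distinct observed score as a threshold (prediction positive
#' when `score >= threshold`), maximizing
#' `TSS = sensitivity + specificity - 1`; ties are resolved toward the
#' lowest threshold.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  thresholds <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(thresholds, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(thresholds, function(t) mean(background_scores < t), 0)
  val <- sens + spec - 1
  best <- which.max(val)          # which.max returns the first (lowest) maximum
  list(tss = val[best], threshold = thresholds[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Single-split model evaluation
#'
#' @param model a fitted `maxent_model`.
#' @param test_presence,background [sample_matrix()] objects.
#' @return list with `auc`, `tss`, `tss_threshold`, `sensitivity`,
#'   `specificity`, `n_presence_test`, `n_background`.
#' @export
evaluate_model <- function(model, test_presence, background) {
  sp <- as.vector(predict(model, test_presence$env, type = "logistic"))
  sb <- as.vector(predict(model, background$env, type = "logistic"))
  ts <- tss(sp, sb)
  list(auc = auc(sp, sb), tss = ts$tss, tss_threshold = ts$threshold,
       sensitivity = ts$sensitivity, specificity = ts$specificity,
       n_presence_test = length(sp), n_background = length(sb))
}

#' Bootstrap-replicate fitting and evaluation
#'
#' Per replicate: resample the occurrences with replacement, split into
#' training and held-out fractions, fit, and evaluate against the
#' background sample; the cellwise mean of the replicate prediction
#' rasters is returned alongside the metric summary. Ten replicates with a
#' 75/25 split are the defaults.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [grid_stack()].
#' @param background a [sample_matrix()] of background points.
#' @param fc,rm engine settings.
#' @param replicates number of bootstrap replicates.
#' @param train_fraction training fraction per replicate.
#' @param seed integer seed (replicate sub-seeds derive from it).
#' @param ... further arguments to [fit_maxent()].
#' @return object of class `eval_summary`: per-replicate metrics, their
#'   mean/sd, the mean prediction raster, and the fitted replicate models.
#' @export
bootstrap_evaluate <- function(occ, stack, background, fc = "LQH", rm = 1,
                               replicates = 10, train_fraction = 0.75,
                               seed = 1L, ...) {
  n <- nrow(occ)
  if (n < 4L) stop("too few occurrences to split")
  metrics <- vector("list", replicates)
  models <- vector("list", replicates)
  mean_pred <- NULL
  for (b in seq_len(replicates)) {
    rep_seed <- stage_seed(seed, paste0("replicate", b))
    boot <- with_seed(rep_seed, occ[sample.int(n, n, replace = TRUE), ])
    boot <- boot[!duplicated(boot[c("lon", "lat")]), ]
    class(boot) <- c("occurrence_set", "data.frame")
    sp <- split_train_test(boot, train_fraction, seed = rep_seed)
    train_sm <- extract_at_points(stack, sp$train, "presence")
    test_sm <- extract_at_points(stack, sp$test, "presence")
    mod <- fit_maxent(train_sm, background, fc = fc, rm = rm, ...)
    metrics[[b]] <- as.data.frame(evaluate_model(mod, test_sm, background))
    models[[b]] <- mod
    pred <- predict(mod, stack, type = "logistic")
    mean_pred <- if (is.null(mean_pred)) pred$values else mean_pred + pred$values
  }
  metrics <- do.call(rbind, metrics)
  metrics$replicate <- seq_len(replicates)
  r <- stack[[1L]]
  mean_raster <- grid_raster(mean_pred / replicates, r$origin_lon,
                             r$origin_lat, r$cell_size, name = "mean_suitability")
  structure(list(replicates = metrics,
                 auc_mean = mean(metrics$auc), auc_sd = stats::sd(metrics$auc),
                 tss_mean = mean(metrics$tss), tss_sd = stats::sd(metrics$tss),
                 mean_prediction = mean_raster, models = models),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %d replicate(s): AUC %.3f +/- %.3f, TSS %.3f +/- %.3f\n",
              nrow(x$replicates), x$auc_mean,
              ifelse(is.na(x$auc_sd), 0, x$auc_sd),
              x$tss_mean, ifelse(is.na(x$tss_sd), 0, x$tss_sd)))
  invisible(x)
}
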