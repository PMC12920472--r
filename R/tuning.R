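#' Small-sample-corrected AIC of a fitted model on a landscape
#'
#' The raw prediction is renormalized to sum 1 over all valid landscape
#' cells; the log-likelihood is the sum of the log normalized density at
#' the occurrence cells; `k` is the number of non-zero coefficients; and
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1)` with `n` the occurrence
#' count. When `n - k - 1 <= 0` the correction is undefined and the result
#' carries `defined = FALSE` instead of a value.
#'
#' @param model a fitted `maxent_model`.
#' @param occ an [occurrence_set()] (all records, unsplit).
#' @param stack the [grid_stack()] landscape.
#' @return list with `aicc`, `k`, `loglik`, `n`, `defined`.
#' @export
aicc <- function(model, occ, stack) {
  raw <- predict(model, stack, type = "raw")
  v <- raw$values
  total <- sum(v, na.rm = TRUE)
  rc <- locate_cells(raw, occ$lon, occ$lat)
  ok <- !is.na(rc$row)
  p <- rep(NA_real_, nrow(rc))
  p[ok] <- v[cbind(rc$row[ok], rc$col[ok])] / total
  if (anyNA(p)) stop("occurrence(s) outside the landscape or on nodata cells")
  loglik <- sum(log(p))
  k <- sum(model$lambda != 0)
  n <- nrow(occ)
  val <- aicc_formula(k, n, loglik)
  list(aicc = val, k = k, loglik = loglik, n = n, defined = !is.na(val))
}

#' @rdname aicc
#' @param k number of non-zero coefficients.
#' @param n occurrence count.
#' @param loglik log-likelihood.
#' @export
aicc_formula <- function(k, n, loglik) {
  if (n - k - 1 <= 0) return(NA_real_)
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Tune regularization multiplier and feature classes by AICc
#'
#' Fits one model per (RM, FC) candidate on the full occurrence set (the
#' AICc-based selection convention: no split), scores each by [aicc()],
#' and reports Delta-AICc relative to the best defined row. An optional
#' held-out AUC per row is reported for reference only and never drives
#' selection.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [grid_stack()].
#' @param background a [sample_matrix()] reused across candidates.
#' @param rms regularization multipliers (default 0.5 to 4 by 0.5).
#' @param fcs feature-class strings (default the six classical combos).
#' @param seed integer seed for the reference train/test split.
#' @param eval_auc also report a 75/25 held-out AUC per row.
#' @param ... further arguments to [fit_maxent()].
#' @return object of class `tuning_result`: data.frame of rows plus the
#'   selected row as attributes.
#' @export
tune_grid <- function(occ, stack, background,
                      rms = seq(0.5, 4, by = 0.5),
                      fcs = c("L", "H", "LQ", "LQH", "LQHP", "LQHPT"),
                      seed = 1L, eval_auc = TRUE, ...) {
  grid <- expand.grid(rm = rms, fc = fcs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) < 1L) stop("empty tuning grid")
  presence_all <- extract_at_points(stack, occ, "presence")
  split_auc <- NULL
  if (eval_auc && nrow(occ) >= 4L) {
    sp <- split_train_test(occ, 0.75, seed = seed)
    split_auc <- list(train = extract_at_points(stack, sp$train, "presence"),
                      test = extract_at_points(stack, sp$test, "presence"))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mod <- fit_maxent(presence_all, background, fc = grid$fc[i],
                      rm = grid$rm[i], ...)
    ic <- aicc(mod, occ, stack)
    test_auc <- NA_real_
    if (!is.null(split_auc)) {
      mod_s <- fit_maxent(split_auc$train, background, fc = grid$fc[i],
                          rm = grid$rm[i], ...)
      test_auc <- evaluate_model(mod_s, split_auc$test, background)$auc
    }
    data.frame(rm = grid$rm[i], fc = grid$fc[i], k = ic$k,
               loglik = ic$loglik, aicc = ic$aicc, defined = ic$defined,
               test_auc = test_auc)
  })
  res <- do.call(rbind, rows)
  if (!any(res$defined)) {
    res$delta_aicc <- NA_real_
    res$support <- NA_character_
  } else {
    best_aicc <- min(res$aicc[res$defined])
    res$delta_aicc <- res$aicc - best_aicc
    res$support <- ifelse(!res$defined, NA_character_,
                          ifelse(res$delta_aicc < 2, "strong",
                                 ifelse(res$delta_aicc > 10, "negligible",
                                        "moderate")))
  }
  res <- structure(res, class = c("tuning_result", "data.frame"),
                   fc_order = fcs)
  sel <- tryCatch(select_best(res), error = function(e) NULL)
  attr(res, "selected") <- sel
  res
}

#' Select the best tuning row
#'
#' The row with Delta-AICc = 0; ties are broken by fewer non-zero
#' coefficients, then smaller RM, then feature-class list order. Rows with
#' undefined AICc never win.
#'
#' @param tuning a `tuning_result`.
#' @return list with `rm`, `fc`, and the winning `row`.
#' @export
select_best <- function(tuning) {
  cand <- tuning[which(tuning$defined & tuning$delta_aicc == 0), , drop = FALSE]
  if (!nrow(cand)) stop("no row has a defined AICc; selection impossible")
  fc_order <- attr(tuning, "fc_order")
  if (is.null(fc_order)) fc_order <- unique(tuning$fc)
  ord <- order(cand$k, cand$rm, match(cand$fc, fc_order))
  best <- cand[ord[1L], ]
  list(rm = best$rm, fc = best$fc, row = best)
}

#' @export
print.tuning_result <- function(x, ...) {
  sel <- attr(x, "selected")
  cat(sprintf("<tuning_result> %d candidate(s); selected RM=%g FC=%s\n",
              nrow(x), sel$rm, sel$fc))
  print(as.data.frame(x)[order(x$delta_aicc), ][seq_len(min(6L, nrow(x))), ])
  invisible(x)
}
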