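#' Pearson correlation matrix over sample values
#'
#' Computed on the presence + background sample values (the sample-based
#' convention of the screening tools common in SDM work), not on whole
#' rasters. Constant columns get r = 0 against everything, with a warning.
#'
#' @param samples a [sample_matrix()] (or plain numeric matrix).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(samples) {
  env <- if (inherits(samples, "sample_matrix")) samples$env else as.matrix(samples)
  if (nrow(env) < 3L) stop("need at least 3 rows for a correlation matrix")
  sds <- apply(env, 2L, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("constant column(s): ", paste(colnames(env)[const], collapse = ", "),
            "; correlations set to 0")
  cm <- suppressWarnings(stats::cor(env))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm
}

#' Drop layers with low model contribution
#'
#' @param contrib data.frame with `variable` and `contribution` (percent)
#'   columns, e.g. from [percent_contribution()].
#' @param min_contribution retention threshold in percent.
#' @return retained variable names, input order preserved.
#' @export
contribution_screen <- function(contrib, min_contribution = 1) {
  keep <- contrib$variable[contrib$contribution >= min_contribution]
  if (!length(keep))
    stop("no variable reaches the contribution threshold of ", min_contribution, "%")
  as.character(keep)
}

#' Greedy collinearity filter
#'
#' Variables are visited in order of descending contribution (ties broken
#' by name); a variable is accepted iff its absolute Pearson correlation
#' with every already-accepted variable is <= `threshold`. Guarantees that
#' no accepted pair exceeds the threshold, and gives priority to the more
#' informative member of each collinear group.
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param contrib data.frame with `variable` and `contribution`.
#' @param threshold collinearity threshold on |r| (default 0.85).
#' @return accepted variable names, in acceptance order.
#' @export
collinearity_filter <- function(corr, contrib, threshold = 0.85) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  vars <- as.character(contrib$variable)
  if (!all(vars %in% rownames(corr)))
    stop("contribution table and correlation matrix name different variables")
  ord <- vars[order(-contrib$contribution, vars)]
  accepted <- character()
  for (v in ord) {
    if (all(abs(corr[v, accepted]) <= threshold)) accepted <- c(accepted, v)
  }
  accepted
}
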