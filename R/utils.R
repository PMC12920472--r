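# internal helpers shared across modules

# run expr with a local RNG state; caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deterministic sub-seed for a named pipeline stage
#'
#' Derives a reproducible integer seed (< 2^31) from a master seed and a
#' stage label, so one master seed drives every stochastic stage of a run
#' without reusing the same stream.
#'
#' @param master integer master seed.
#' @param stage stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(master) * 1009L + h) %% .Machine$integer.max
}
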