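#' Smooth Gaussian random field
#'
#' White noise convolved (circularly, via FFT) with a Gaussian kernel of
#' standard deviation `corr_length` cells, then standardized to empirical
#' mean 0 and variance 1. `corr_length = 0` gives i.i.d. noise. Used to
#' emulate spatially autocorrelated environmental layers such as
#' bioclimatic surfaces.
#'
#' @param n_row,n_col grid dimensions.
#' @param corr_length autocorrelation length in cells (kernel sd); >= 0.
#' @param seed integer seed; the field is reproducible given the seed.
#' @param origin_lon,origin_lat,cell_size grid georeferencing.
#' @param name layer label.
#' @return a [grid_raster()].
#' @export
gaussian_field <- function(n_row, n_col, corr_length = 10, seed = 1L,
                           origin_lon = 100, origin_lat = 40,
                           cell_size = 0.025, name = "field") {
  if (corr_length < 0) stop("corr_length must be >= 0")
  if (n_row < 1L || n_col < 1L) stop("grid dimensions must be >= 1")
  noise <- with_seed(seed, matrix(stats::rnorm(n_row * n_col), n_row, n_col))
  if (corr_length > 0) {
    gr <- circular_gaussian(n_row, corr_length)
    gc <- circular_gaussian(n_col, corr_length)
    kernel <- outer(gr, gc)
    f <- Re(stats::fft(stats::fft(noise) * stats::fft(kernel), inverse = TRUE)) /
      (n_row * n_col)
  } else {
    f <- noise
  }
  f <- (f - mean(f)) / stats::sd(f)
  grid_raster(f, origin_lon, origin_lat, cell_size, name = name)
}

# Gaussian kernel on a circle of n cells, centered at index 1
circular_gaussian <- function(n, sigma) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / sigma)^2)
  k / sum(k)
}

#' Species-environment relationship with known truth
#'
#' A linear-quadratic predictor over named layers pushed through the
#' logistic function: `suitability = plogis(intercept + sum(b_i x_i) +
#' sum(a_i x_i^2))`. Quadratic coefficients must be <= 0 so responses to
#' driving layers are unimodal; the optimum of a driving layer is
#' `-b/(2a)`.
#'
#' @param linear named numeric vector of linear coefficients.
#' @param quadratic named numeric vector of quadratic coefficients (<= 0).
#' @param intercept scalar.
#' @return object of class `niche_spec`.
#' @export
niche_spec <- function(linear = numeric(), quadratic = numeric(), intercept = 0) {
  if (length(linear) && is.null(names(linear)))
    stop("linear coefficients must be named by layer")
  if (length(quadratic) && is.null(names(quadratic)))
    stop("quadratic coefficients must be named by layer")
  if (any(quadratic > 0))
    stop("quadratic coefficients must be <= 0 (unimodal responses)")
  if (all(c(linear, quadratic) == 0))
    stop("niche needs at least one non-zero coefficient")
  structure(list(linear = linear, quadratic = quadratic, intercept = intercept),
            class = "niche_spec")
}

#' Optima of the driving layers of a niche
#'
#' @param niche a [niche_spec()].
#' @return named vector `-b/(2a)` over layers with a non-zero quadratic term.
#' @export
niche_optimum <- function(niche) {
  a <- niche$quadratic[niche$quadratic != 0]
  if (!length(a)) return(stats::setNames(numeric(), character()))
  b <- ifelse(names(a) %in% names(niche$linear), niche$linear[names(a)], 0)
  stats::setNames(-b / (2 * a), names(a))
}

#' Synthetic scene configuration
#'
#' Bundles everything needed to generate a reproducible landscape with a
#' known species-environment truth: grid geometry, layer names, spatial
#' autocorrelation, a target cross-correlation structure, the niche, the
#' presence sample size, and additive per-layer shifts defining a "future"
#' scenario stack.
#'
#' @param n_row,n_col grid dimensions.
#' @param cell_size cell edge, decimal degrees.
#' @param layer_names unique layer labels.
#' @param corr_length autocorrelation length in cells (scalar or per layer).
#' @param target_corr symmetric unit-diagonal positive-semidefinite matrix of
#'   target pairwise correlations; default identity.
#' @param niche a [niche_spec()] over a subset of `layer_names`.
#' @param n_presence target number of presence records (>= 10).
#' @param seed master seed for the scene.
#' @param future_deltas named vector of additive layer shifts for the future
#'   stack (may be empty).
#' @param origin_lon,origin_lat top-left corner, decimal degrees.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(n_row = 200, n_col = 200, cell_size = 0.025,
                         layer_names, corr_length = 10, target_corr = NULL,
                         niche, n_presence = 157, seed = 1L,
                         future_deltas = numeric(),
                         origin_lon = 100, origin_lat = 40) {
  k <- length(layer_names)
  if (anyDuplicated(layer_names)) stop("layer names must be unique")
  if (is.null(target_corr)) target_corr <- diag(k)
  target_corr <- as.matrix(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr), tolerance = 1e-8)))
    stop("target correlation matrix must be symmetric")
  if (any(abs(diag(target_corr) - 1) > 1e-8))
    stop("target correlation matrix must have unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target correlation matrix must be positive semi-definite")
  if (n_presence < 10) stop("n_presence must be >= 10")
  if (!all(names(c(niche$linear, niche$quadratic)) %in% layer_names))
    stop("niche references layers not in the scene")
  if (length(future_deltas) && !all(names(future_deltas) %in% layer_names))
    stop("future_deltas references layers not in the scene")
  corr_length <- rep_len(corr_length, k)
  structure(list(n_row = n_row, n_col = n_col, cell_size = cell_size,
                 layer_names = layer_names, corr_length = corr_length,
                 target_corr = target_corr, niche = niche,
                 n_presence = n_presence, seed = as.integer(seed),
                 future_deltas = future_deltas,
                 origin_lon = origin_lon, origin_lat = origin_lat),
            class = "scene_config")
}

#' Generate the environmental stack of a scene
#'
#' Independent smooth fields are generated per layer, empirically whitened
#' (centered and orthonormalized across cells), and mixed through the
#' symmetric square root of the target correlation matrix, so the empirical
#' pairwise correlations of the output layers match the target to numerical
#' precision. Each output layer keeps empirical mean 0 and variance 1.
#'
#' @param config a [scene_config()].
#' @return a [grid_stack()].
#' @export
make_env_stack <- function(config) {
  k <- length(config$layer_names)
  fields <- lapply(seq_len(k), function(i)
    gaussian_field(config$n_row, config$n_col, config$corr_length[i],
                   seed = stage_seed(config$seed, paste0("field", i)),
                   origin_lon = config$origin_lon,
                   origin_lat = config$origin_lat,
                   cell_size = config$cell_size,
                   name = config$layer_names[i]))
  x <- vapply(fields, function(f) as.vector(f$values),
              numeric(config$n_row * config$n_col))
  x <- scale(x, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(x)) * sqrt(nrow(x) - 1)        # exactly uncorrelated, sd 1
  es <- eigen(config$target_corr, symmetric = TRUE)
  sq <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
  y <- q %*% sq
  layers <- lapply(seq_len(k), function(i)
    grid_raster(matrix(y[, i], config$n_row, config$n_col),
                config$origin_lon, config$origin_lat, config$cell_size,
                name = config$layer_names[i]))
  grid_stack(layers)
}

#' True suitability surface of a scene
#'
#' @param stack a [grid_stack()].
#' @param niche a [niche_spec()] whose layers all occur in the stack.
#' @return a [grid_raster()] of probabilities in (0, 1).
#' @export
true_suitability <- function(stack, niche) {
  vars <- union(names(niche$linear), names(niche$quadratic))
  missing <- setdiff(vars, names(stack))
  if (length(missing))
    stop("niche references layers not in the stack: ", paste(missing, collapse = ", "))
  r <- stack[[1L]]
  eta <- matrix(niche$intercept, nrow(r$values), ncol(r$values))
  for (v in names(niche$linear))
    eta <- eta + niche$linear[[v]] * stack[[v]]$values
  for (v in names(niche$quadratic))
    eta <- eta + niche$quadratic[[v]] * stack[[v]]$values^2
  grid_raster(stats::plogis(eta), r$origin_lon, r$origin_lat, r$cell_size,
              name = "suitability")
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability until `n_target` cells are drawn or the positive-suitability
#' cells are exhausted; one record is placed at each drawn cell's center
#' (one presence per cell, mirroring the spatial thinning applied to real
#' records downstream).
#'
#' @param suitability a [grid_raster()] with values in `[0, 1]`.
#' @param n_target number of records wanted.
#' @param seed integer seed.
#' @return an [occurrence_set()].
#' @export
sample_occurrences <- function(suitability, n_target, seed = 1L) {
  v <- suitability$values
  ok <- which(!is.na(v) & v > 0)
  if (!length(ok)) stop("suitability is zero or nodata everywhere")
  n <- min(n_target, length(ok))
  pick <- with_seed(seed, sample(ok, n, replace = FALSE, prob = v[ok]))
  rows <- ((pick - 1L) %% nrow(v)) + 1L
  cols <- ((pick - 1L) %/% nrow(v)) + 1L
  cc <- cell_center(suitability, rows, cols)
  occurrence_set(data.frame(lon = cc$lon, lat = cc$lat,
                            source = "synthetic", year = NA_integer_))
}

#' Apply scenario shifts to a stack
#'
#' Adds the named per-layer deltas; unnamed layers are copied unchanged and
#' nodata masks are preserved. Emulates a future-climate version of the
#' landscape.
#'
#' @param stack a [grid_stack()].
#' @param deltas named numeric vector of additive shifts.
#' @return a [grid_stack()].
#' @export
make_future <- function(stack, deltas) {
  missing <- setdiff(names(deltas), names(stack))
  if (length(missing))
    stop("deltas reference layers not in the stack: ", paste(missing, collapse = ", "))
  layers <- lapply(names(stack), function(nm) {
    r <- stack[[nm]]
    if (nm %in% names(deltas)) r$values <- r$values + deltas[[nm]]
    r
  })
  grid_stack(layers, names(stack))
}

#' Generate a full synthetic scene
#'
#' Convenience wrapper: environmental stack, true suitability, presence
#' records, and (when the config carries deltas) the future stack.
#'
#' @param config a [scene_config()].
#' @return list with `stack`, `suitability`, `occurrences`, and optionally
#'   `future`.
#' @export
make_scene <- function(config) {
  stack <- make_env_stack(config)
  suit <- true_suitability(stack, config$niche)
  occ <- sample_occurrences(suit, config$n_presence,
                            seed = stage_seed(config$seed, "occurrences"))
  out <- list(stack = stack, suitability = suit, occurrences = occ,
              config = config)
  if (length(config$future_deltas))
    out$future <- make_future(stack, config$future_deltas)
  out
}

#' Default synthetic study scene
#'
#' The packaged stand-in for the kind of landscape the pipeline is meant
#' for: ten spatially autocorrelated standardized layers named after common
#' SDM predictors, two strongly cross-correlated pairs (r = 0.9) to
#' exercise collinearity screening, a niche driven by four layers with
#' dry-month precipitation dominant, about 157 presences, and a future
#' scenario shifting the two main climate layers.
#'
#' @param seed master seed.
#' @param n_row,n_col grid dimensions (default 200 x 200).
#' @param n_presence presence target (default 157).
#' @return a [scene_config()].
#' @export
default_scene_config <- function(seed = 1L, n_row = 200, n_col = 200,
                                 n_presence = 157) {
  layers <- c("bio_03", "bio_04", "bio_14", "bio_15", "elev",
              "aspect", "slope", "srad_08", "srad_10", "awc")
  k <- length(layers)
  cm <- diag(k); dimnames(cm) <- list(layers, layers)
  cm["srad_08", "srad_10"] <- cm["srad_10", "srad_08"] <- 0.9
  cm["bio_14", "bio_15"] <- cm["bio_15", "bio_14"] <- 0.9
  cm["bio_03", "bio_04"] <- cm["bio_04", "bio_03"] <- 0.6
  # narrow unimodal responses with optima away from the layer means, so
  # presences concentrate in a restricted region and the fitted model
  # reaches the high-AUC regime typical of a well-determined SDM
  niche <- niche_spec(
    linear = c(bio_14 = 9, bio_04 = -3, elev = -2.4, srad_10 = 1.5),
    quadratic = c(bio_14 = -3, bio_04 = -2, elev = -1.6, srad_10 = -1.5),
    intercept = -6)
  scene_config(n_row = n_row, n_col = n_col, layer_names = layers,
               corr_length = 10, target_corr = cm, niche = niche,
               n_presence = n_presence, seed = seed,
               future_deltas = c(bio_04 = 0.5, bio_14 = -0.3))
}
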