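# shared fixtures: tiny rasters, scenes and independent oracles

toy_raster <- function(values, origin_lon = 0, origin_lat = 2,
                       cell_size = 1, name = "toy") {
  grid_raster(values, origin_lon, origin_lat, cell_size, name = name)
}

# small single-driver scene: narrow quadratic niche on layer "x" with
# optimum 1.5 (an uncommon value of the standardized field, so presences
# concentrate and the signal is strong, as in a well-determined SDM)
small_scene <- function(seed = 1, n = 60, n_presence = 120, n_layers = 3) {
  layers <- c("x", paste0("noise", seq_len(n_layers - 1)))
  niche <- niche_spec(linear = c(x = 15), quadratic = c(x = -5),
                      intercept = -10.25)
  cfg <- scene_config(n_row = n, n_col = n, layer_names = layers,
                      corr_length = 6, niche = niche,
                      n_presence = n_presence, seed = seed)
  make_scene(cfg)
}

# presence/background sample matrices from a scene
scene_samples <- function(scene, n_background = 800, seed = 1) {
  list(presence = extract_at_points(scene$stack, scene$occurrences, "presence"),
       background = sample_background(scene$stack, n_background, seed = seed))
}

# Generic convex-solver oracle for the penalized maxent objective:
# L-BFGS-B on the split lambda = lp - lm, lp/lm >= 0, with analytic
# gradients. Independent of the coordinate-descent trainer.
maxent_oracle_objective <- function(f_presence, f_background, beta,
                                    maxit = 2000L) {
  p <- ncol(f_background)
  pmean <- colMeans(f_presence)
  negj <- function(theta) {
    lam <- theta[1:p] - theta[(p + 1):(2 * p)]
    eta <- as.vector(f_background %*% lam)
    m <- max(eta)
    -(sum(lam * pmean) - (m + log(sum(exp(eta - m)))) -
        sum(beta * (theta[1:p] + theta[(p + 1):(2 * p)])))
  }
  grad <- function(theta) {
    lam <- theta[1:p] - theta[(p + 1):(2 * p)]
    eta <- as.vector(f_background %*% lam)
    w <- exp(eta - max(eta)); q <- w / sum(w)
    eq <- as.vector(t(f_background) %*% q)
    g <- pmean - eq
    c(-g + beta, g + beta)
  }
  fit <- stats::optim(rep(0, 2 * p), negj, grad, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = maxit, factr = 1e4))
  -fit$value
}

# exhaustive TSS oracle: try every distinct score as a ">= t" threshold
tss_oracle <- function(p, b) {
  ts <- sort(unique(c(p, b)))
  vals <- sapply(ts, function(t) mean(p >= t) + mean(b < t) - 1)
  list(tss = max(vals), threshold = ts[which.max(vals)])
}

# exhaustive pair-counting AUC oracle
auc_oracle <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# brute-force Fisher-Jenks oracle: enumerate all ordered partitions
jenks_oracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- NULL; best_cost <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (i in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, i], n)
    cost <- sum(sapply(seq_len(k), function(g)
      ssd(x[(bounds[g] + 1):bounds[g + 1]])))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- x[cuts[, i] + 1]   # lower bound of each upper class
    }
  }
  best
}
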