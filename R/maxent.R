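#' Feature expansion for the MaxEnt engine
#'
#' Derives model features from raw layers: linear (L), quadratic (Q),
#' pairwise product (P), hinge (H, forward and reverse ramps at evenly
#' spaced knots), and threshold (T, step indicators). Every feature is
#' scaled to `[0, 1]` by its minimum/maximum over the background rows, the
#' classical MaxEnt convention; hinge/threshold knots are placed strictly
#' inside each layer's background range. Constant layers contribute no
#' features (warning).
#'
#' @param samples a [sample_matrix()]; rows labelled `"background"` define
#'   the scaling statistics (all rows are used if there are none).
#' @param fc feature classes as a string over `L`, `Q`, `H`, `P`, `T`,
#'   e.g. `"LQH"`.
#' @param n_hinge_knots knots per hinge direction (>= 2 when H requested).
#' @param n_threshold_knots threshold knots (>= 2 when T requested).
#' @return object of class `feature_expansion`.
#' @export
build_features <- function(samples, fc = "LQH", n_hinge_knots = 50,
                           n_threshold_knots = 20) {
  fc <- toupper(fc)
  classes <- strsplit(fc, "")[[1]]
  if (!length(classes) || !all(classes %in% c("L", "Q", "H", "P", "T")))
    stop("fc must be a non-empty combination of L, Q, H, P, T")
  if ("H" %in% classes && n_hinge_knots < 2) stop("need >= 2 hinge knots")
  if ("T" %in% classes && n_threshold_knots < 2) stop("need >= 2 threshold knots")
  env <- samples$env
  bg <- env[samples$label == "background", , drop = FALSE]
  if (!nrow(bg)) bg <- env
  layers <- colnames(env)
  lmin <- apply(bg, 2L, min); lmax <- apply(bg, 2L, max)
  lmean <- colMeans(bg)
  const <- lmax - lmin <= 0
  if (any(const))
    warning("constant layer(s) dropped from features: ",
            paste(layers[const], collapse = ", "))
  active <- layers[!const]
  feats <- list()
  add <- function(type, var1, var2 = NA_character_, knot = NA_real_,
                  direction = NA_character_, fmin, fmax) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, var1 = var1, var2 = var2, knot = knot,
      direction = direction, fmin = fmin, fmax = fmax)
  }
  for (v in active) {
    if ("L" %in% classes) add("linear", v, fmin = lmin[[v]], fmax = lmax[[v]])
    if ("Q" %in% classes) {
      sq <- bg[, v]^2
      add("quadratic", v, fmin = min(sq), fmax = max(sq))
    }
    if ("H" %in% classes) {
      knots <- seq(lmin[[v]], lmax[[v]],
                   length.out = n_hinge_knots + 2L)[-c(1L, n_hinge_knots + 2L)]
      for (k in knots) {
        add("hinge", v, knot = k, direction = "forward",
            fmin = 0, fmax = lmax[[v]] - k)
        add("hinge", v, knot = k, direction = "reverse",
            fmin = 0, fmax = k - lmin[[v]])
      }
    }
    if ("T" %in% classes) {
      knots <- seq(lmin[[v]], lmax[[v]],
                   length.out = n_threshold_knots + 2L)[-c(1L, n_threshold_knots + 2L)]
      for (k in knots) add("threshold", v, knot = k, fmin = 0, fmax = 1)
    }
  }
  if ("P" %in% classes && length(active) >= 2L) {
    pairs <- utils::combn(active, 2L)
    for (i in seq_len(ncol(pairs))) {
      pr <- bg[, pairs[1L, i]] * bg[, pairs[2L, i]]
      add("product", pairs[1L, i], pairs[2L, i], fmin = min(pr), fmax = max(pr))
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(), var1 = character(), var2 = character(),
               knot = numeric(), direction = character(),
               fmin = numeric(), fmax = numeric())
  expansion <- structure(
    list(features = features, fc = fc,
         layer_stats = data.frame(layer = layers, min = lmin, max = lmax,
                                  mean = lmean, row.names = NULL)),
    class = "feature_expansion")
  # sd of each scaled feature over background, used by the default penalties
  fb <- feature_matrix(expansion, bg, clamp = FALSE)
  expansion$features$sd_bg <- apply(fb, 2L, stats::sd)
  expansion
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion> FC=%s: %d features over %d layers\n",
              x$fc, nrow(x$features), nrow(x$layer_stats)))
  print(table(x$features$type))
  invisible(x)
}

# evaluate scaled features on a raw env matrix; optionally clamp raw layer
# values to the background range and scaled features to [0,1]
feature_matrix <- function(expansion, env, clamp = TRUE, count_clamps = FALSE) {
  ft <- expansion$features
  ls <- expansion$layer_stats
  clamp_counts <- stats::setNames(integer(nrow(ls)), ls$layer)
  if (clamp) {
    for (i in seq_len(nrow(ls))) {
      v <- ls$layer[i]
      if (!v %in% colnames(env)) next
      out <- env[, v] < ls$min[i] | env[, v] > ls$max[i]
      clamp_counts[v] <- sum(out)
      env[, v] <- pmin(pmax(env[, v], ls$min[i]), ls$max[i])
    }
  }
  n <- nrow(env)
  f <- matrix(0, n, nrow(ft))
  for (j in seq_len(nrow(ft))) {
    x <- env[, ft$var1[j]]
    raw <- switch(ft$type[j],
      linear = x,
      quadratic = x^2,
      product = x * env[, ft$var2[j]],
      hinge = if (ft$direction[j] == "forward") pmax(0, x - ft$knot[j])
              else pmax(0, ft$knot[j] - x),
      threshold = as.numeric(x >= ft$knot[j]))
    rng <- ft$fmax[j] - ft$fmin[j]
    f[, j] <- if (rng > 0) (raw - ft$fmin[j]) / rng else raw
  }
  if (clamp) f <- pmin(pmax(f, 0), 1)
  if (count_clamps) attr(f, "clamp_counts") <- clamp_counts
  f
}

#' Default per-feature L1 penalties
#'
#' The published MaxEnt regularization schedule: a class-specific base
#' value interpolated in the presence sample size (linear/quadratic/
#' product: 1.0 at <= 10 presences, 0.2 at 30, 0.05 at >= 100,
#' piecewise-linear; hinge: 0.5 throughout; threshold: 2.0 at <= 10 to 1.0
#' at >= 100), scaled by the feature's background standard deviation and
#' the regularization multiplier:
#' `beta_j = rm * base(class, m) * sd_j / sqrt(m)`.
#'
#' @param expansion a [build_features()] result.
#' @param n_presence presence count m (>= 2).
#' @param rm regularization multiplier (> 0).
#' @return numeric vector of penalties, one per feature.
#' @export
default_regularization <- function(expansion, n_presence, rm = 1) {
  if (n_presence < 2) stop("n_presence must be >= 2")
  if (rm <= 0) stop("rm must be > 0")
  base_of <- function(type) {
    switch(type,
      linear = , quadratic = , product =
        stats::approx(c(10, 30, 100), c(1.0, 0.2, 0.05),
                      xout = n_presence, rule = 2)$y,
      hinge = 0.5,
      threshold = stats::approx(c(10, 100), c(2.0, 1.0),
                                xout = n_presence, rule = 2)$y)
  }
  ft <- expansion$features
  base <- vapply(ft$type, base_of, 0, USE.NAMES = FALSE)
  rm * base * ft$sd_bg / sqrt(n_presence)
}

#' Fit the L1-regularized maximum-entropy model
#'
#' Maximizes the penalized presence log-likelihood of the Gibbs density
#' over background cells,
#' `J(lambda) = mean_presence(eta) - log(sum_background(exp(eta))) -
#' sum_j beta_j |lambda_j|`,
#' by cyclic coordinate descent with soft-thresholding (one-dimensional
#' Newton step per feature, step-halved so the objective never decreases).
#' Iterations are full cycles over the features; fitting stops when a
#' cycle improves the objective by less than `tolerance` or the iteration
#' ceiling is reached.
#'
#' @param presence,background [sample_matrix()] objects on the same layers.
#' @param fc feature classes, e.g. `"LQHPT"`.
#' @param rm regularization multiplier.
#' @param max_iterations cycle ceiling (default 500).
#' @param tolerance objective-improvement stopping tolerance.
#' @param n_hinge_knots,n_threshold_knots knot counts for H/T features.
#' @param beta optional per-feature penalty vector overriding
#'   [default_regularization()] (e.g. all zero for an unpenalized fit).
#' @return object of class `maxent_model`.
#' @export
fit_maxent <- function(presence, background, fc = "LQH", rm = 1,
                       max_iterations = 500, tolerance = 1e-7,
                       n_hinge_knots = 50, n_threshold_knots = 20,
                       beta = NULL) {
  if (nrow(presence$env) < 2L) stop("need >= 2 presence rows")
  if (nrow(background$env) < 10L) stop("need >= 10 background rows")
  if (!identical(colnames(presence$env), colnames(background$env)))
    stop("presence and background layers differ")
  combined <- rbind_samples(
    sample_matrix(presence$env, presence$coords, rep("presence", nrow(presence$env))),
    sample_matrix(background$env, background$coords, rep("background", nrow(background$env))))
  expansion <- build_features(combined, fc, n_hinge_knots, n_threshold_knots)
  p <- nrow(expansion$features)
  n_bg <- nrow(background$env)
  m <- nrow(presence$env)
  if (is.null(beta)) {
    beta <- if (p) default_regularization(expansion, m, rm) else numeric()
  } else beta <- rep_len(beta, p)
  f_bg <- feature_matrix(expansion, background$env, clamp = FALSE)
  # presence rows can fall outside the background range of a layer; their
  # features are clamped to [0,1] exactly as at prediction time
  pmean <- if (p) unname(colMeans(feature_matrix(expansion, presence$env, clamp = TRUE)))
           else numeric()

  lambda <- numeric(p)
  eta <- rep(0, n_bg)
  gains <- numeric(p)
  objective <- function(lam, et)
    sum(lam * pmean) - log_sum_exp(et) - sum(beta * abs(lam))
  obj <- objective(lambda, eta)
  iterations <- 0L; converged <- FALSE
  while (iterations < max_iterations && p > 0L) {
    iterations <- iterations + 1L
    obj_cycle_start <- obj
    for (j in seq_len(p)) {
      fj <- f_bg[, j]
      w <- exp(eta - max(eta)); q <- w / sum(w)
      ej <- sum(q * fj)
      vj <- sum(q * fj * fj) - ej * ej
      if (vj < 1e-12) next
      g <- pmean[j] - ej
      z <- lambda[j] + g / vj
      lam_new <- sign(z) * max(0, abs(z) - beta[j] / vj)
      d <- lam_new - lambda[j]
      if (d == 0) next
      # step-halving keeps the objective monotone despite the quadratic
      # approximation of the log-partition term
      for (h in 1:30) {
        cand_lam <- lambda[j] + d
        cand_eta <- eta + d * fj
        cand_obj <- obj + d * pmean[j] -
          (log_sum_exp(cand_eta) - log_sum_exp(eta)) -
          beta[j] * (abs(lambda[j] + d) - abs(lambda[j]))
        if (cand_obj >= obj - 1e-12) break
        d <- d / 2
      }
      if (cand_obj >= obj - 1e-12 && cand_obj > obj) {
        gains[j] <- gains[j] + (cand_obj - obj)
        lambda[j] <- cand_lam
        eta <- cand_eta
        obj <- cand_obj
      }
    }
    if (obj - obj_cycle_start < tolerance) { converged <- TRUE; break }
  }
  if (!converged && p > 0L)
    message("fit_maxent: iteration ceiling of ", max_iterations, " reached")
  logz <- log_sum_exp(eta)
  q <- exp(eta - logz)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(
    list(expansion = expansion, lambda = lambda, beta = beta,
         pmean = pmean, logZ = logz, entropy = entropy,
         rm = rm, fc = expansion$fc, n_presence = m, n_background = n_bg,
         iterations = iterations, converged = converged,
         objective = obj, feature_gains = gains),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> FC=%s RM=%g: %d/%d non-zero features, ",
                     "%d presences vs %d background\n",
                     "  objective %.6f after %d iteration(s)%s; H = %.4f\n"),
              x$fc, x$rm, sum(x$lambda != 0), length(x$lambda),
              x$n_presence, x$n_background, x$objective, x$iterations,
              if (x$converged) "" else " (ceiling)", x$entropy))
  invisible(x)
}

# linear predictor eta for a raw env matrix, with clamping
model_eta <- function(model, env, count_clamps = FALSE) {
  f <- feature_matrix(model$expansion, env, clamp = TRUE,
                      count_clamps = count_clamps)
  eta <- as.vector(f %*% model$lambda)
  if (count_clamps) attr(eta, "clamp_counts") <- attr(f, "clamp_counts")
  eta
}

#' Predict from a fitted MaxEnt model
#'
#' `raw` is the normalized Gibbs density `exp(eta - logZ)` (sums to 1 over
#' the training background); `logistic` is
#' `plogis(H + eta - logZ)` with `H` the entropy of the fitted background
#' distribution (0.5 where the model has no information); `cloglog` is
#' `1 - exp(-exp(H + eta - logZ))`. Inputs outside the training range are
#' clamped to it, with per-layer clamp counts attached as an attribute.
#'
#' @param object a `maxent_model`.
#' @param newdata a [grid_stack()] (returns a [grid_raster()]) or a
#'   [sample_matrix()] / numeric matrix (returns a vector).
#' @param type `"logistic"` (default), `"raw"`, or `"cloglog"`.
#' @param ... unused.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "cloglog"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "grid_stack")) {
    tab <- stack_cell_table(newdata)
    v <- predict(object, tab$env, type = type)
    r <- newdata[[1L]]
    m <- matrix(NA_real_, nrow(r$values), ncol(r$values))
    m[cbind(tab$rows, tab$cols)] <- v
    out <- grid_raster(m, r$origin_lon, r$origin_lat, r$cell_size,
                       name = paste0("suitability_", type))
    attr(out, "clamp_counts") <- attr(v, "clamp_counts")
    return(out)
  }
  env <- if (inherits(newdata, "sample_matrix")) newdata$env else as.matrix(newdata)
  missing <- setdiff(object$expansion$layer_stats$layer, colnames(env))
  if (length(missing))
    stop("newdata lacks model layers: ", paste(missing, collapse = ", "))
  eta <- model_eta(object, env, count_clamps = TRUE)
  cc <- attr(eta, "clamp_counts")
  s <- object$entropy + as.vector(eta) - object$logZ
  out <- switch(type,
    raw = exp(as.vector(eta) - object$logZ),
    logistic = stats::plogis(s),
    cloglog = 1 - exp(-exp(s)))
  attr(out, "clamp_counts") <- cc
  out
}

#' Percent contribution of each variable
#'
#' Attributes the positive objective gains accumulated during coordinate
#' descent to the parent variable of the updated feature (product-feature
#' gains split evenly between the two parents) and normalizes to 100.
#'
#' @param model a fitted `maxent_model`.
#' @return data.frame with `variable` and `contribution` (percent), in
#'   layer order.
#' @export
percent_contribution <- function(model) {
  ft <- model$expansion$features
  layers <- model$expansion$layer_stats$layer
  g <- stats::setNames(numeric(length(layers)), layers)
  for (j in seq_len(nrow(ft))) {
    if (model$feature_gains[j] == 0) next
    if (ft$type[j] == "product") {
      g[ft$var1[j]] <- g[ft$var1[j]] + model$feature_gains[j] / 2
      g[ft$var2[j]] <- g[ft$var2[j]] + model$feature_gains[j] / 2
    } else {
      g[ft$var1[j]] <- g[ft$var1[j]] + model$feature_gains[j]
    }
  }
  total <- sum(g)
  contribution <- if (total > 0) 100 * g / total else g * 0
  data.frame(variable = layers, contribution = as.numeric(contribution))
}

#' Permutation importance of each variable
#'
#' Permutes each variable's values across the combined presence +
#' background rows, recomputes the training AUC, and reports the AUC drop
#' (floored at zero) normalized to sum 100. Variables carrying no model
#' feature score 0.
#'
#' @param model a fitted `maxent_model`.
#' @param presence,background the training [sample_matrix()] objects.
#' @param seed integer seed for the permutations.
#' @return data.frame with `variable` and `importance` (percent).
#' @export
permutation_importance <- function(model, presence, background, seed = 1L) {
  layers <- model$expansion$layer_stats$layer
  env_all <- rbind(presence$env, background$env)
  is_pres <- c(rep(TRUE, nrow(presence$env)), rep(FALSE, nrow(background$env)))
  score <- function(env) {
    s <- predict(model, env, type = "raw")
    auc(s[is_pres], s[!is_pres])
  }
  auc0 <- score(env_all)
  used <- unique(c(model$expansion$features$var1,
                   stats::na.omit(model$expansion$features$var2)))
  drops <- with_seed(seed, vapply(layers, function(v) {
    if (!v %in% used) return(0)
    env_p <- env_all
    env_p[, v] <- env_p[sample.int(nrow(env_p)), v]
    max(0, auc0 - score(env_p))
  }, 0))
  total <- sum(drops)
  importance <- if (total > 0) 100 * drops / total else drops * 0
  data.frame(variable = layers, importance = as.numeric(importance))
}

#' Jackknife gains per variable
#'
#' Refits the model with each variable alone and with each variable
#' omitted, reporting the regularized training gain (objective minus the
#' uniform-model objective `-log(n_background)`) and the training AUC for
#' every refit, plus the full model's values as attributes.
#'
#' @param presence,background training [sample_matrix()] objects.
#' @param fc,rm engine settings passed to [fit_maxent()].
#' @param ... further arguments to [fit_maxent()] (knot counts, ceilings).
#' @return data.frame with `variable`, `gain_only`, `gain_without`,
#'   `auc_only`, `auc_without`; attributes `gain_full`, `auc_full`.
#' @export
jackknife_gains <- function(presence, background, fc = "LQH", rm = 1, ...) {
  layers <- colnames(presence$env)
  if (length(layers) < 2L) stop("jackknife needs >= 2 variables")
  sub <- function(s, keep) sample_matrix(s$env[, keep, drop = FALSE], s$coords, s$label)
  gain_auc <- function(p, b) {
    mod <- fit_maxent(p, b, fc = fc, rm = rm, ...)
    sp <- predict(mod, p$env, type = "raw")
    sb <- predict(mod, b$env, type = "raw")
    c(gain = mod$objective + log(nrow(b$env)), auc = auc(sp, sb))
  }
  full <- gain_auc(presence, background)
  res <- t(vapply(layers, function(v) {
    only <- gain_auc(sub(presence, v), sub(background, v))
    rest <- setdiff(layers, v)
    wout <- gain_auc(sub(presence, rest), sub(background, rest))
    c(gain_only = only[["gain"]], gain_without = wout[["gain"]],
      auc_only = only[["auc"]], auc_without = wout[["auc"]])
  }, numeric(4)))
  out <- data.frame(variable = layers, res, row.names = NULL)
  attr(out, "gain_full") <- full[["gain"]]
  attr(out, "auc_full") <- full[["auc"]]
  out
}

#' Univariate response curve
#'
#' Marginal response: the chosen variable sweeps its background range on an
#' even grid while every other variable is held at its background mean;
#' logistic predictions are returned together with the >= 0.5 super-level
#' set as a union of closed intervals (the "suitable range" convention).
#'
#' @param model a fitted `maxent_model`.
#' @param variable layer name.
#' @param n_points grid resolution.
#' @return object of class `response_curve`: list with `variable`, `grid`,
#'   `prediction`, `suitable_intervals` (data.frame `from`/`to`).
#' @export
response_curve <- function(model, variable, n_points = 100) {
  ls <- model$expansion$layer_stats
  if (!variable %in% ls$layer) stop("unknown variable: ", variable)
  i <- match(variable, ls$layer)
  grid <- seq(ls$min[i], ls$max[i], length.out = n_points)
  env <- matrix(rep(ls$mean, each = n_points), nrow = n_points,
                dimnames = list(NULL, ls$layer))
  env[, variable] <- grid
  pred <- as.vector(predict(model, env, type = "logistic"))
  above <- pred >= 0.5
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(from = grid[starts[runs$values]],
                   to = grid[ends[runs$values]])
  structure(list(variable = variable, grid = grid, prediction = pred,
                 suitable_intervals = iv),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %s over [%g, %g]; suitable (>= 0.5): %s\n",
              x$variable, min(x$grid), max(x$grid),
              if (nrow(x$suitable_intervals))
                paste(sprintf("[%.4g, %.4g]", x$suitable_intervals$from,
                              x$suitable_intervals$to), collapse = " U ")
              else "empty"))
  invisible(x)
}

#' Serialize / restore a fitted model as plain text
#'
#' One line per feature (`type var1 var2 knot direction fmin fmax sd_bg
#' lambda beta`) after a header carrying the normalizer, entropy and
#' training metadata.
#'
#' @param model a `maxent_model`.
#' @param path output file.
#' @export
write_maxent <- function(model, path) {
  hdr <- sprintf("# maxent_model fc=%s rm=%.17g logZ=%.17g H=%.17g n_presence=%d n_background=%d",
                 model$fc, model$rm, model$logZ, model$entropy,
                 model$n_presence, model$n_background)
  ls <- model$expansion$layer_stats
  stat_lines <- sprintf("layer %s %.17g %.17g %.17g", ls$layer, ls$min, ls$max, ls$mean)
  ft <- model$expansion$features
  feat_lines <- sprintf("feature %s %s %s %.17g %s %.17g %.17g %.17g %.17g %.17g",
                        ft$type, ft$var1, ifelse(is.na(ft$var2), ".", ft$var2),
                        ifelse(is.na(ft$knot), 0, ft$knot),
                        ifelse(is.na(ft$direction), ".", ft$direction),
                        ft$fmin, ft$fmax, ft$sd_bg, model$lambda, model$beta)
  writeLines(c(hdr, stat_lines, feat_lines), path)
  invisible(path)
}

#' @rdname write_maxent
#' @param path file written by [write_maxent()].
#' @export
read_maxent <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  get_num <- function(key) as.numeric(sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr))
  fc <- sub(".*fc=([^ ]+).*", "\\1", hdr)
  sl <- lines[startsWith(lines, "layer ")]
  st <- do.call(rbind, strsplit(sl, " "))
  layer_stats <- data.frame(layer = st[, 2L], min = as.numeric(st[, 3L]),
                            max = as.numeric(st[, 4L]), mean = as.numeric(st[, 5L]))
  fl <- lines[startsWith(lines, "feature ")]
  fm <- do.call(rbind, strsplit(fl, " "))
  features <- data.frame(
    type = fm[, 2L], var1 = fm[, 3L],
    var2 = ifelse(fm[, 4L] == ".", NA_character_, fm[, 4L]),
    knot = as.numeric(fm[, 5L]),
    direction = ifelse(fm[, 6L] == ".", NA_character_, fm[, 6L]),
    fmin = as.numeric(fm[, 7L]), fmax = as.numeric(fm[, 8L]),
    sd_bg = as.numeric(fm[, 9L]))
  features$knot[features$type %in% c("linear", "quadratic", "product")] <- NA_real_
  expansion <- structure(list(features = features, fc = fc,
                              layer_stats = layer_stats),
                         class = "feature_expansion")
  structure(
    list(expansion = expansion, lambda = as.numeric(fm[, 10L]),
         beta = as.numeric(fm[, 11L]), pmean = NULL,
         logZ = get_num("logZ"), entropy = get_num("H"),
         rm = get_num("rm"), fc = fc,
         n_presence = as.integer(get_num("n_presence")),
         n_background = as.integer(get_num("n_background")),
         iterations = NA_integer_, converged = NA,
         objective = NA_real_, feature_gains = rep(NA_real_, nrow(features))),
    class = "maxent_model")
}
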