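# helper: 1-D sample matrices from explicit vectors
sm1d <- function(x, label, name = "x") {
  sample_matrix(matrix(x, ncol = 1, dimnames = list(NULL, name)),
                data.frame(lon = seq_along(x), lat = 0), rep(label, length(x)))
}

test_that("feature counts follow the class definitions", {
  set.seed(1)
  env <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  sm <- sample_matrix(env, data.frame(lon = 1:20, lat = 1:20),
                      rep("background", 20))
  expect_equal(nrow(build_features(sm, "L")$features), 3L)
  expect_equal(nrow(build_features(sm, "LQP")$features), 9L)  # 3 + 3 + C(3,2)
  fe <- build_features(sm, "LQHPT", n_hinge_knots = 4, n_threshold_knots = 3)
  expect_equal(as.vector(table(fe$features$type)[c("hinge", "threshold")]),
               c(3L * 8L, 3L * 3L))
})

test_that("hinge features scale a printed toy column to [0, 1]", {
  x <- c(0, 2, 4, 6, 8, 10)
  sm <- sm1d(x, "background")
  fe <- build_features(sm, "H", n_hinge_knots = 5)
  expect_equal(nrow(fe$features), 10L)     # 5 forward + 5 reverse
  f <- entsdm:::feature_matrix(fe, sm$env)
  expect_true(all(f >= 0 & f <= 1))
  # knots evenly spaced strictly inside (0, 10): 10/6 * (1..5)
  knots <- fe$features$knot[fe$features$direction == "forward"]
  expect_equal(knots, 10 / 6 * (1:5))
  # forward hinge at the first knot, evaluated at x = 4: (4 - 5/3) / (10 - 5/3)
  expect_equal(f[3, 1], (4 - 10 / 6) / (10 - 10 / 6))
  # reverse hinge at that knot, x = 0: (5/3 - 0) / (5/3 - 0) = 1
  expect_equal(f[1, 2], 1)
})

test_that("constant layers are dropped from the expansion with a warning", {
  env <- cbind(a = runif(15), flat = rep(2, 15))
  sm <- sample_matrix(env, data.frame(lon = 1:15, lat = 1:15),
                      rep("background", 15))
  expect_warning(fe <- build_features(sm, "LQ"), "constant")
  expect_false("flat" %in% fe$features$var1)
  expect_equal(nrow(fe$features), 2L)
})

test_that("the default regularization schedule interpolates in sample size", {
  sm <- sm1d(runif(50), "background")
  fe <- build_features(sm, "L")
  sd1 <- fe$features$sd_bg[1]
  expect_equal(default_regularization(fe, 100, 1), 0.05 * sd1 / 10)
  expect_equal(default_regularization(fe, 20, 1), 0.6 * sd1 / sqrt(20))
  expect_equal(default_regularization(fe, 100, 2),
               2 * default_regularization(fe, 100, 1))
  feh <- build_features(sm, "H", n_hinge_knots = 3)
  expect_equal(default_regularization(feh, 50, 1),
               0.5 * feh$features$sd_bg / sqrt(50))
  fet <- build_features(sm, "T", n_threshold_knots = 3)
  expect_equal(default_regularization(fet, 10, 1),
               2 * fet$features$sd_bg / sqrt(10))
})

test_that("an unpenalized 1-D fit matches the moment condition", {
  set.seed(4)
  bg <- sm1d(runif(150), "background")
  pres <- sm1d(runif(40, 0.5, 1), "presence")    # presences at high values
  mod <- fit_maxent(pres, bg, fc = "L", beta = 0, tolerance = 1e-12)
  f_bg <- entsdm:::feature_matrix(mod$expansion, bg$env)
  raw <- predict(mod, bg$env, type = "raw")
  f_pres <- entsdm:::feature_matrix(mod$expansion, pres$env)
  expect_equal(sum(raw * f_bg[, 1]), mean(f_pres[, 1]), tolerance = 1e-4)
})

test_that("every fit yields a normalized density with bounded entropy", {
  for (fc in c("L", "LQ", "LQH")) {
    scene <- small_scene(seed = 3, n = 30, n_presence = 40)
    s <- scene_samples(scene, n_background = 250, seed = 2)
    mod <- fit_maxent(s$presence, s$background, fc = fc, n_hinge_knots = 5)
    raw <- predict(mod, s$background$env, type = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-6)
    expect_gte(mod$entropy, 0)
    expect_lte(mod$entropy, log(nrow(s$background$env)) + 1e-9)
  }
})

test_that("the trainer matches a generic convex-solver oracle", {
  # small problems: <= 5 features, <= 200 background cells
  cases <- list(list(fc = "L", rm = 1), list(fc = "LQ", rm = 0.5),
                list(fc = "LQ", rm = 2))
  for (seed in 1:3) {
    scene <- small_scene(seed = seed, n = 25, n_presence = 30, n_layers = 2)
    s <- scene_samples(scene, n_background = 180, seed = seed)
    for (cs in cases) {
      mod <- fit_maxent(s$presence, s$background, fc = cs$fc, rm = cs$rm,
                        tolerance = 1e-10, max_iterations = 2000)
      f_bg <- entsdm:::feature_matrix(mod$expansion, s$background$env)
      f_p <- entsdm:::feature_matrix(mod$expansion, s$presence$env)
      oracle <- maxent_oracle_objective(f_p, f_bg, mod$beta)
      expect_equal(mod$objective, oracle, tolerance = 1e-4)
    }
  }
})

test_that("stronger regularization never adds non-zero coefficients", {
  scene <- small_scene(seed = 7, n = 30, n_presence = 50)
  s <- scene_samples(scene, n_background = 300, seed = 1)
  nnz <- sapply(c(0.5, 1, 2, 4), function(rm)
    sum(fit_maxent(s$presence, s$background, fc = "LQ", rm = rm)$lambda != 0))
  expect_true(all(diff(nnz) <= 0))
})

test_that("predictions follow the logistic/raw/cloglog forms", {
  set.seed(2)
  bg <- sm1d(runif(100), "background")
  pres <- sm1d(runif(20), "presence")
  # all-zero model via an overwhelming penalty: logistic = 0.5 everywhere
  mod0 <- fit_maxent(pres, bg, fc = "L", beta = 1e6)
  expect_equal(as.vector(predict(mod0, bg$env, type = "logistic")),
               rep(0.5, 100))
  # single positive linear feature: logistic monotone in the feature
  pres2 <- sm1d(runif(30, 0.6, 1), "presence")
  mod <- fit_maxent(pres2, bg, fc = "L")
  expect_gt(mod$lambda[1], 0)
  x <- matrix(seq(0.05, 0.95, length.out = 50), ncol = 1,
              dimnames = list(NULL, "x"))
  p <- predict(mod, x, type = "logistic")
  expect_true(all(diff(p) >= 0))
  cl <- predict(mod, x, type = "cloglog")
  expect_true(all(cl > 0 & cl < 1))
  raw <- as.vector(predict(mod, bg$env, type = "raw"))
  s <- mod$entropy + log(raw)
  expect_equal(as.vector(predict(mod, bg$env, type = "logistic")),
               plogis(s), tolerance = 1e-12)
})

test_that("out-of-range inputs are clamped and counted", {
  set.seed(6)
  bg <- sm1d(runif(100), "background")
  pres <- sm1d(runif(30, 0.5, 1), "presence")
  mod <- fit_maxent(pres, bg, fc = "LQ")
  inside <- matrix(c(0.5, max(bg$env)), ncol = 1, dimnames = list(NULL, "x"))
  outside <- matrix(c(0.5, 2), ncol = 1, dimnames = list(NULL, "x"))
  pi <- predict(mod, inside, type = "logistic")
  po <- predict(mod, outside, type = "logistic")
  expect_equal(attr(po, "clamp_counts")[["x"]], 1L)
  expect_equal(po[2], pi[2])      # clamped to the background max
  expect_equal(attr(pi, "clamp_counts")[["x"]], 0L)
})

test_that("percent contributions sum to 100 and credit the signal variable", {
  scene <- small_scene(seed = 5, n = 40, n_presence = 80)
  s <- scene_samples(scene, n_background = 400, seed = 3)
  mod <- fit_maxent(s$presence, s$background, fc = "LQ")
  contrib <- percent_contribution(mod)
  expect_equal(sum(contrib$contribution), 100, tolerance = 0.01)
  expect_true(all(contrib$contribution >= 0))
  expect_equal(contrib$variable[which.max(contrib$contribution)], "x")
})

test_that("two equally informative variables split the contribution evenly", {
  devs <- sapply(1:5, function(seed) {
    niche <- niche_spec(linear = c(a = 1.5, b = 1.5),
                        quadratic = c(a = -1.5, b = -1.5), intercept = 0)
    cfg <- scene_config(n_row = 50, n_col = 50, layer_names = c("a", "b"),
                        corr_length = 5, niche = niche, n_presence = 120,
                        seed = seed)
    scene <- make_scene(cfg)
    s <- scene_samples(scene, n_background = 500, seed = seed)
    contrib <- percent_contribution(
      fit_maxent(s$presence, s$background, fc = "LQ"))
    contrib$contribution[contrib$variable == "a"]
  })
  expect_true(mean(abs(devs - 50) <= 10) >= 0.8)
})

test_that("permutation importance ranks the driver first and ignores absent layers", {
  scene <- small_scene(seed = 9, n = 40, n_presence = 100)
  s <- scene_samples(scene, n_background = 400, seed = 4)
  # add a constant layer: dropped from features, importance must be 0
  add_flat <- function(m) {
    sample_matrix(cbind(m$env, flat = 1), m$coords, m$label)
  }
  pres <- add_flat(s$presence); bg <- add_flat(s$background)
  mod <- suppressWarnings(fit_maxent(pres, bg, fc = "LQ"))
  imp <- permutation_importance(mod, pres, bg, seed = 1)
  expect_equal(imp$importance[imp$variable == "flat"], 0)
  expect_equal(imp$variable[which.max(imp$importance)], "x")
  expect_equal(sum(imp$importance), 100, tolerance = 1e-9)
  imp2 <- permutation_importance(mod, pres, bg, seed = 1)
  expect_identical(imp, imp2)
})

test_that("jackknife gains respect redundancy and noise", {
  set.seed(11)
  scene <- small_scene(seed = 11, n = 40, n_presence = 80, n_layers = 2)
  s <- scene_samples(scene, n_background = 300, seed = 5)
  # duplicate the driver: removing one copy leaves the "without" gain unchanged
  dup <- function(m) sample_matrix(cbind(m$env, x2 = m$env[, "x"] + rnorm(nrow(m$env), sd = 1e-9)),
                                   m$coords, m$label)
  jk <- jackknife_gains(dup(s$presence), dup(s$background), fc = "L")
  full <- attr(jk, "gain_full")
  expect_true(all(c(jk$gain_only, jk$gain_without) >= -1e-9))
  without_x <- jk$gain_without[jk$variable == "x"]
  expect_lt(abs(without_x - full) / max(full, 1e-9), 0.02)
  # a pure-noise variable carries almost no gain on its own
  noise_only <- jk$gain_only[jk$variable == "noise1"]
  expect_lt(noise_only, 0.05)
})

test_that("response curves recover shape, intervals, and the true optimum", {
  set.seed(12)
  bg <- sm1d(runif(200), "background")
  # uniform model: flat 0.5 curve, suitable over the whole range
  pres0 <- sm1d(runif(30), "presence")
  mod0 <- fit_maxent(pres0, bg, fc = "L", beta = 1e6)
  rc0 <- response_curve(mod0, "x", n_points = 21)
  expect_equal(rc0$prediction, rep(0.5, 21), tolerance = 1e-12)
  expect_equal(nrow(rc0$suitable_intervals), 1L)
  expect_equal(rc0$suitable_intervals$from[1], min(rc0$grid))
  expect_equal(rc0$suitable_intervals$to[1], max(rc0$grid))
  # positive linear model: one right-anchored interval
  pres1 <- sm1d(runif(60, 0.7, 1), "presence")
  mod1 <- fit_maxent(pres1, bg, fc = "L")
  rc1 <- response_curve(mod1, "x")
  expect_equal(nrow(rc1$suitable_intervals), 1L)
  expect_equal(rc1$suitable_intervals$to[1], max(rc1$grid))
  # quadratic niche: the suitable interval contains the true optimum
  scene <- small_scene(seed = 13, n = 50, n_presence = 150)
  s <- scene_samples(scene, n_background = 500, seed = 6)
  mod2 <- fit_maxent(s$presence, s$background, fc = "LQ")
  rc2 <- response_curve(mod2, "x")
  opt <- niche_optimum(scene$config$niche)[["x"]]
  expect_true(any(rc2$suitable_intervals$from <= opt &
                  rc2$suitable_intervals$to >= opt))
  expect_error(response_curve(mod2, "nope"), "unknown variable")
})

test_that("model serialization round-trips predictions", {
  scene <- small_scene(seed = 15, n = 30, n_presence = 40)
  s <- scene_samples(scene, n_background = 200, seed = 7)
  mod <- fit_maxent(s$presence, s$background, fc = "LQH", n_hinge_knots = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxent(mod, path)
  back <- read_maxent(path)
  newx <- s$background$env[1:25, , drop = FALSE]
  expect_equal(predict(back, newx, type = "logistic"),
               predict(mod, newx, type = "logistic"), tolerance = 1e-12)
  expect_equal(back$logZ, mod$logZ)
  expect_equal(back$entropy, mod$entropy)
})
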