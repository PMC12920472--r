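lag1_autocor <- function(m) {
  stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
}

test_that("gaussian fields are standardized, seeded, and autocorrelated as asked", {
  f0 <- gaussian_field(200, 200, corr_length = 0, seed = 5)
  expect_equal(mean(f0$values), 0, tolerance = 1e-12)
  expect_equal(sd(f0$values), 1, tolerance = 1e-12)
  expect_lt(abs(lag1_autocor(f0$values)), 0.05)       # white-noise limit

  f20 <- gaussian_field(200, 200, corr_length = 20, seed = 5)
  expect_gt(lag1_autocor(f20$values), 0.8)

  expect_identical(gaussian_field(50, 50, 5, seed = 9)$values,
                   gaussian_field(50, 50, 5, seed = 9)$values)
  expect_false(identical(gaussian_field(50, 50, 5, seed = 9)$values,
                         gaussian_field(50, 50, 5, seed = 10)$values))
})

test_that("environmental stacks hit the target correlation structure", {
  niche <- niche_spec(linear = c(a = 1))
  # identity target: near-zero empirical correlations
  cfg <- scene_config(n_row = 100, n_col = 100, layer_names = c("a", "b", "c"),
                      corr_length = 8, niche = niche, n_presence = 50, seed = 2)
  st <- make_env_stack(cfg)
  cm <- cor(sapply(st, function(r) as.vector(r$values)))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  for (seed in 1:3) {                                  # r = 0.9 pair
    tc <- diag(3); tc[1, 2] <- tc[2, 1] <- 0.9
    cfg <- scene_config(n_row = 100, n_col = 100, layer_names = c("a", "b", "c"),
                        corr_length = 8, target_corr = tc, niche = niche,
                        n_presence = 50, seed = seed)
    st <- make_env_stack(cfg)
    r_ab <- cor(as.vector(st[["a"]]$values), as.vector(st[["b"]]$values))
    expect_gt(r_ab, 0.85); expect_lt(r_ab, 0.95)
  }

  tc <- diag(2); tc[1, 2] <- tc[2, 1] <- 1             # degenerate pair
  cfg <- scene_config(n_row = 60, n_col = 60, layer_names = c("a", "b"),
                      corr_length = 5, target_corr = tc, niche = niche,
                      n_presence = 50, seed = 4)
  st <- make_env_stack(cfg)
  expect_equal(st[["a"]]$values, st[["b"]]$values, tolerance = 1e-8)

  tc[1, 2] <- tc[2, 1] <- 1.5
  expect_error(scene_config(layer_names = c("a", "b"), target_corr = tc,
                            niche = niche), "semi-definite")
})

test_that("true suitability is the logistic of the linear-quadratic predictor", {
  x <- toy_raster(matrix(seq(-2, 2, length.out = 25), 5, 5), name = "x")
  st <- grid_stack(list(x))
  niche <- niche_spec(linear = c(x = 2), quadratic = c(x = -1), intercept = 0)
  suit <- true_suitability(st, niche)
  # eta = -(x - 1)^2 + 1; argmax over cells is the cell with x closest to 1
  expect_equal(which.max(suit$values),
               which.min(abs(x$values - 1)))
  expect_equal(suit$values[1, 1],
               plogis(2 * x$values[1, 1] - x$values[1, 1]^2))
  expect_true(all(suit$values > 0 & suit$values < 1))
  expect_error(true_suitability(st, niche_spec(linear = c(missing = 1))),
               "not in the stack")
})

test_that("suitability of exactly m cells yields exactly those records", {
  v <- matrix(0, 4, 4); v[c(2, 7, 11)] <- 1
  suit <- toy_raster(v)
  occ <- sample_occurrences(suit, 10, seed = 1)
  expect_equal(nrow(occ), 3L)
  picked <- locate_cells(suit, occ$lon, occ$lat)
  expect_setequal(picked$row + (picked$col - 1L) * 4L, c(2L, 7L, 11L))
  expect_identical(sample_occurrences(suit, 2, seed = 3)$lon,
                   sample_occurrences(suit, 2, seed = 3)$lon)
  expect_error(sample_occurrences(toy_raster(matrix(0, 2, 2)), 5), "zero")
})

test_that("uniform suitability samples cells uniformly", {
  suit <- toy_raster(matrix(0.5, 4, 4))
  counts <- integer(16)
  for (s in 1:500) {
    occ <- sample_occurrences(suit, 1, seed = s)
    rc <- locate_cells(suit, occ$lon, occ$lat)
    i <- rc$row + (rc$col - 1L) * 4L
    counts[i] <- counts[i] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("future stacks shift only the named layers", {
  cfg <- scene_config(n_row = 20, n_col = 20, layer_names = c("a", "b"),
                      corr_length = 3, niche = niche_spec(linear = c(a = 1)),
                      n_presence = 20, seed = 3)
  st <- make_env_stack(cfg)
  fut <- make_future(st, c(a = 2))
  expect_equal(fut[["a"]]$values, st[["a"]]$values + 2)
  expect_identical(fut[["b"]]$values, st[["b"]]$values)
  same <- make_future(st, c(a = 0, b = 0))
  expect_equal(same[["a"]]$values, st[["a"]]$values)
  expect_error(make_future(st, c(zz = 1)), "not in the stack")
})

test_that("niche optimum is -b/(2a) and quadratic terms must be concave", {
  n <- niche_spec(linear = c(x = 2, y = 1), quadratic = c(x = -2), intercept = 0)
  expect_equal(niche_optimum(n), c(x = 0.5))
  expect_error(niche_spec(quadratic = c(x = 1)), "unimodal")
  expect_error(niche_spec(), "non-zero")
})
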