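test_that("DMS conversion handles signs and the 60-second carry", {
  expect_equal(dms_to_decimal(111, 22, 41, "E"), 111.378056, tolerance = 1e-6)
  expect_equal(dms_to_decimal(112, 0, 60, "E"), 112.016667, tolerance = 1e-6)
  expect_equal(dms_to_decimal(30, 30, 51, "S"), -30.514167, tolerance = 1e-6)
  expect_error(dms_to_decimal(10, -5, 0), ">= 0")
})

test_that("classification follows the half-open break convention", {
  suit <- toy_raster(matrix(c(0.05, 0.1, 0.3, 0.5, 0.99, NA), 2, 3))
  cl <- classify(suit)
  expect_equal(as.vector(cl$values)[1:5], c(0, 1, 2, 3, 3))
  expect_true(is.na(cl$values[2, 3]))
  zeros <- classify(toy_raster(matrix(0, 2, 2)))
  expect_true(all(zeros$values == 0))
  expect_error(classify(suit, breaks = c(0.5, 0.3, 0.1)), "increasing")
})

test_that("jenks breaks split at the obvious gap and match brute force", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), 10)
  for (seed in 1:8) {
    set.seed(seed)
    x <- round(runif(sample(6:12, 1), 0, 100), 1)
    if (length(unique(x)) < 4) next
    for (k in 2:3)
      expect_equal(jenks_breaks(x, k), jenks_oracle(x, k))
  }
  expect_error(jenks_breaks(rep(7, 10), 3), "distinct")
})

test_that("classify with jenks breaks assigns values to their interval", {
  set.seed(2)
  vals <- c(rbeta(200, 1, 6), rbeta(200, 8, 2))    # bimodal in [0,1]
  br <- jenks_breaks(vals, 4)
  suit <- toy_raster(matrix(vals[1:400], 20, 20))
  cl <- classify(suit, breaks = br)
  want <- findInterval(vals[1:400], br)
  expect_equal(as.vector(cl$values), want)
})

test_that("spherical cell areas follow the closed form and cosine scaling", {
  a_eq <- cell_area_km2(0, 2.5 / 60)
  expect_equal(a_eq, 21.47, tolerance = 1e-3)
  a_60 <- cell_area_km2(60, 2.5 / 60)
  expect_equal(a_60 / a_eq, 0.5, tolerance = 0.01)
  expect_gt(cell_area_km2(89.99, 2.5 / 60), 0)
  expect_error(cell_area_km2(95, 1), "latitude")
})

test_that("area tables match a brute-force per-cell oracle and partition the area", {
  set.seed(5)
  suit <- grid_raster(matrix(runif(20 * 15), 20, 15), 110, 35, 0.25)
  suit$values[sample(300, 10)] <- NA
  cl <- classify(suit)
  at <- area_table(cl)
  # brute force: loop over every cell
  brute <- numeric(4)
  for (r in 1:20) for (c in 1:15) {
    v <- cl$values[r, c]
    if (is.na(v)) next
    lat <- 35 - (r - 0.5) * 0.25
    brute[v + 1] <- brute[v + 1] + cell_area_km2(lat, 0.25)
  }
  expect_equal(at$area_1e4_km2 * 1e4, brute, tolerance = 1e-9)
  expect_equal(sum(at$area_1e4_km2), attr(at, "total_valid"), tolerance = 1e-12)
  expect_equal(sum(at$percent_of_suitable[2:4]), 100, tolerance = 1e-9)
  expect_equal(attr(at, "total_suitable"), sum(at$area_1e4_km2[2:4]))
})

test_that("published-style class areas give back the printed percentages", {
  res <- area_percentages(91.32, 148.89, 88.20)
  expect_equal(round(unname(res$percent), 2), c(27.81, 45.34, 26.86))
  expect_equal(res$total, 328.41, tolerance = 1e-9)
  one <- area_percentages(0, 0, 50)
  expect_equal(unname(one$percent), c(0, 0, 100))
  expect_error(area_percentages(0, 0, 0), "positive")
})

test_that("change maps account for gains, losses, and stability", {
  now <- classify(toy_raster(matrix(c(0.6, 0.6, 0.05, 0.05), 2, 2)))
  same <- change_map(now, now)
  expect_equal(same$gain, 0); expect_equal(same$loss, 0)
  expect_equal(same$gross_turnover, 0)
  comp <- classify(toy_raster(matrix(c(0.05, 0.05, 0.6, 0.6), 2, 2)))
  flip <- change_map(now, comp)
  expect_equal(flip$stable_suitable + flip$stable_unsuitable, 0)
  expect_equal(flip$gross_turnover,
               sum(cell_area_km2(c(1.5, 1.5, 0.5, 0.5), 1)) / 1e4,
               tolerance = 1e-9)
})

test_that("a hand-built 3x3 change map sums the right cell areas", {
  v_now <- matrix(c(0.6, 0.0, 0.0,
                    0.0, 0.6, 0.0,
                    0.0, 0.0, 0.0), 3, 3, byrow = TRUE)
  v_fut <- matrix(c(0.0, 0.6, 0.0,
                    0.0, 0.6, 0.6,
                    0.0, 0.0, 0.0), 3, 3, byrow = TRUE)
  now <- classify(toy_raster(v_now, origin_lat = 31, cell_size = 1))
  fut <- classify(toy_raster(v_fut, origin_lat = 31, cell_size = 1))
  ch <- change_map(now, fut)
  # gains at (1,2) lat 30.5 and (2,3) lat 29.5; loss at (1,1) lat 30.5
  gain <- (cell_area_km2(30.5, 1) + cell_area_km2(29.5, 1)) / 1e4
  loss <- cell_area_km2(30.5, 1) / 1e4
  expect_equal(ch$gain, gain, tolerance = 1e-12)
  expect_equal(ch$loss, loss, tolerance = 1e-12)
  expect_equal(ch$net_change, gain - loss, tolerance = 1e-12)
  expect_equal(ch$gross_turnover, gain + loss, tolerance = 1e-12)
})

test_that("class centroids are area-weighted cell-center means", {
  one <- classify(toy_raster(matrix(c(0.6, 0, 0, 0), 2, 2), origin_lat = 40))
  cen <- class_centroid(one, "high")
  expect_equal(cen$lon, 0.5); expect_equal(cen$lat, 39.5)
  # two cells at the same latitude: midpoint longitude
  two <- classify(toy_raster(matrix(c(0.6, 0, 0.6, 0), 2, 2), origin_lat = 40))
  cen2 <- class_centroid(two, "high")
  expect_equal(cen2$lon, 1); expect_equal(cen2$lat, 39.5)
  # vertical 2x1 block: centroid pulled toward the equatorward (larger) cell
  block <- classify(toy_raster(matrix(c(0.6, 0.6), 2, 1), origin_lat = 40))
  cen3 <- class_centroid(block, "high")
  w <- cell_area_km2(c(39.5, 38.5), 1)
  expect_equal(cen3$lat, sum(w * c(39.5, 38.5)) / sum(w))
  expect_lt(cen3$lat, 39)
  expect_error(class_centroid(one, "low"), "empty")
})

test_that("geodesic distances are metric-like and match the equatorial arc", {
  expect_equal(geodesic_km(c(0, 0), c(1, 0)), 111.32, tolerance = 1e-4)
  expect_equal(geodesic_km(c(5, 5), c(5, 5)), 0)
  set.seed(8)
  for (i in 1:5) {
    p <- cbind(runif(3, -30, 30), runif(3, -30, 30))
    d12 <- geodesic_km(p[1, ], p[2, ]); d21 <- geodesic_km(p[2, ], p[1, ])
    expect_equal(d12, d21, tolerance = 1e-9)
    expect_lte(d12, geodesic_km(p[1, ], p[3, ]) +
                    geodesic_km(p[3, ], p[2, ]) + 1e-9)
    hv <- geodesic_km(p[1, ], p[2, ], method = "haversine")
    if (d12 > 1) expect_lt(abs(hv - d12) / d12, 0.005)
  }
})

test_that("shift vectors carry distance, bearing, and compass label", {
  north <- shift_vector(c(111, 30), c(111, 31))
  expect_equal(north$bearing, 0, tolerance = 1e-6)
  expect_equal(north$direction, "N")
  ab <- shift_vector(c(111, 30), c(112, 31))
  ba <- shift_vector(c(112, 31), c(111, 30))
  expect_equal(ab$distance_km, ba$distance_km, tolerance = 1e-9)
  expect_equal(ab$direction, "NE")
  expect_true(ab$bearing >= 0 && ab$bearing < 360)
})
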