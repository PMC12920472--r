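#' Degrees-minutes-seconds to decimal degrees
#'
#' Values of 60 or more in the minutes or seconds place carry into the
#' next unit (so 0' 60" is 1'). Southern and western hemispheres give
#' negative values.
#'
#' @param degrees,minutes,seconds non-negative components.
#' @param hemisphere one of `"N"`, `"S"`, `"E"`, `"W"`.
#' @return decimal degrees, signed.
#' @export
dms_to_decimal <- function(degrees, minutes = 0, seconds = 0, hemisphere = "N") {
  if (any(minutes < 0) || any(seconds < 0))
    stop("minutes and seconds must be >= 0")
  dec <- degrees + minutes / 60 + seconds / 3600
  sign <- ifelse(toupper(hemisphere) %in% c("S", "W"), -1, 1)
  sign * dec
}

suitability_classes <- c("unsuitable", "low", "moderate", "high")

#' Classify a suitability raster
#'
#' Half-open classes on three breaks `(b1, b2, b3)`: unsuitable
#' `[0, b1)`, low `[b1, b2)`, moderate `[b2, b3)`, high `[b3, 1]`. The
#' default breaks 0.1/0.3/0.5 are the classical suitability bands; pass
#' [jenks_breaks()] output for a data-driven alternative.
#'
#' @param suitability a [grid_raster()] with values in `[0, 1]`.
#' @param breaks increasing vector of three interior breaks in (0, 1).
#' @return object of class `class_raster`: a [grid_raster()] with integer
#'   codes 0-3 plus a `classes`/`breaks` attribute.
#' @export
classify <- function(suitability, breaks = c(0.1, 0.3, 0.5)) {
  if (length(breaks) != 3L || is.unsorted(breaks, strictly = TRUE) ||
      breaks[1] <= 0 || breaks[3] >= 1)
    stop("breaks must be three increasing values strictly inside (0, 1)")
  v <- suitability$values
  cl <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cl[ok] <- findInterval(v[ok], breaks)      # 0..3, right-open at each break
  out <- grid_raster(cl, suitability$origin_lon, suitability$origin_lat,
                     suitability$cell_size, name = "suitability_class")
  attr(out, "breaks") <- breaks
  attr(out, "classes") <- suitability_classes
  class(out) <- c("class_raster", class(out))
  out
}

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D partition of the values into `n_classes` groups minimizing
#' the total within-class sum of squared deviations, by dynamic
#' programming over the sorted values (exact, not the heuristic k-means
#' variant). Returns the lower bound of each upper class, i.e. the break
#' values usable directly in [classify()]'s half-open convention.
#'
#' @param values numeric vector (NAs dropped); needs at least `n_classes`
#'   distinct values.
#' @param n_classes number of classes (>= 2).
#' @param max_values inputs longer than this are thinned to an evenly
#'   spaced subsample of the sorted values before the quadratic-cost DP
#'   (the breaks are order statistics, so this changes them negligibly).
#' @return increasing vector of `n_classes - 1` break values.
#' @export
jenks_breaks <- function(values, n_classes = 4, max_values = 2000) {
  x <- sort(values[!is.na(values)])
  if (length(x) > max_values)
    x <- x[unique(round(seq(1, length(x), length.out = max_values)))]
  n <- length(x)
  k <- as.integer(n_classes)
  if (k < 2L) stop("n_classes must be >= 2")
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, k, n)       # cost[c, j]: best ssd of x[1..j] in c groups
  back <- matrix(0L, k, n)        # start index of the last group
  for (j in 1:n) { cost[1L, j] <- ssd(1L, j); back[1L, j] <- 1L }
  for (c in 2:k) {
    for (j in c:n) {
      for (i in c:j) {
        val <- cost[c - 1L, i - 1L] + ssd(i, j)
        if (val < cost[c, j]) { cost[c, j] <- val; back[c, j] <- i }
      }
    }
  }
  starts <- integer(k); j <- n
  for (c in k:1) { starts[c] <- back[c, j]; j <- starts[c] - 1L }
  x[starts[-1L]]
}

#' Area of a geographic grid cell
#'
#' Spherical-zone formula `R^2 * dlambda * (sin(lat_top) - sin(lat_bottom))`
#' with the authalic Earth radius R = 6371.0088 km; exact on the sphere
#' for square-degree cells and accurate to well under a percent against
#' the ellipsoid.
#'
#' @param lat_center cell-center latitude, decimal degrees (vectorized).
#' @param cell_size cell edge, decimal degrees.
#' @return area in km^2.
#' @export
cell_area_km2 <- function(lat_center, cell_size) {
  if (any(abs(lat_center) > 90)) stop("latitude outside [-90, 90]")
  R <- 6371.0088
  half <- cell_size / 2
  top <- pmin(90, lat_center + half) * pi / 180
  bottom <- pmax(-90, lat_center - half) * pi / 180
  R^2 * (cell_size * pi / 180) * (sin(top) - sin(bottom))
}

# per-valid-cell areas of a raster, as a vector aligned with which(!is.na)
raster_cell_areas <- function(r) {
  idx <- which(!is.na(r$values))
  rows <- ((idx - 1L) %% nrow(r$values)) + 1L
  lat <- r$origin_lat - (rows - 0.5) * r$cell_size
  cell_area_km2(lat, r$cell_size)
}

#' Class area table
#'
#' Latitude-corrected areas per suitability class, reported in
#' 10^4 km^2, with each suitable class (low/moderate/high) as a
#' percentage of the total suitable area. Rounding to two decimals only
#' affects the printed columns, not the stored exact areas.
#'
#' @param class_raster a [classify()] result.
#' @return object of class `area_table`: data.frame with `class`,
#'   `area_1e4_km2`, `percent_of_suitable`; attributes `total_suitable`
#'   and `total_valid`.
#' @export
area_table <- function(class_raster) {
  idx <- which(!is.na(class_raster$values))
  cl <- class_raster$values[idx]
  areas_km2 <- raster_cell_areas(class_raster)
  per_class <- vapply(0:3, function(c) sum(areas_km2[cl == c]), 0) / 1e4
  suitable <- sum(per_class[2:4])
  pct <- c(NA_real_, if (suitable > 0) 100 * per_class[2:4] / suitable
           else rep(NA_real_, 3L))
  if (suitable == 0) warning("no suitable area; percentages undefined")
  out <- data.frame(class = suitability_classes,
                    area_1e4_km2 = per_class,
                    percent_of_suitable = pct)
  structure(out, class = c("area_table", "data.frame"),
            total_suitable = suitable, total_valid = sum(per_class))
}

#' Suitable-class percentages from published area figures
#'
#' Recomputes what an [area_table()] derives on a raster, but from given
#' class areas (e.g. a published table): percentage of each suitable
#' class and the total suitable area.
#'
#' @param low,moderate,high class areas (any common unit).
#' @return list with `percent` (named length-3 vector) and `total`.
#' @export
area_percentages <- function(low, moderate, high) {
  total <- low + moderate + high
  if (total <= 0) stop("total suitable area must be positive")
  list(percent = c(low = 100 * low / total, moderate = 100 * moderate / total,
                   high = 100 * high / total),
       total = total)
}

#' Gain/loss/stable change accounting between two class maps
#'
#' Both maps are binarized at suitable = {low, moderate, high}; each valid
#' cell is labelled gain, loss, stable-suitable, or stable-unsuitable, and
#' latitude-corrected areas are accumulated. Both the gross turnover
#' (gain + loss) and the signed net change (gain - loss) are reported,
#' labelled explicitly.
#'
#' @param class_now,class_future [classify()] results on the same grid.
#' @return object of class `change_summary`: list with the transition
#'   raster (codes 0 stable-unsuitable, 1 gain, 2 loss, 3 stable-suitable)
#'   and areas in 10^4 km^2.
#' @export
change_map <- function(class_now, class_future) {
  if (!same_grid(class_now, class_future))
    stop("class maps are not on the same grid")
  a <- class_now$values >= 1; b <- class_future$values >= 1
  code <- matrix(NA_real_, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  code[ok] <- ifelse(!a[ok] & b[ok], 1,
                     ifelse(a[ok] & !b[ok], 2,
                            ifelse(a[ok] & b[ok], 3, 0)))
  trans <- grid_raster(code, class_now$origin_lon, class_now$origin_lat,
                       class_now$cell_size, name = "change")
  areas_km2 <- raster_cell_areas(trans)
  cl <- trans$values[!is.na(trans$values)]
  area_of <- function(c) sum(areas_km2[cl == c]) / 1e4
  gain <- area_of(1); loss <- area_of(2)
  structure(list(transitions = trans, gain = gain, loss = loss,
                 stable_suitable = area_of(3), stable_unsuitable = area_of(0),
                 gross_turnover = gain + loss, net_change = gain - loss),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(paste0("<change_summary> (10^4 km^2) gain %.2f, loss %.2f, ",
                     "stable suitable %.2f, stable unsuitable %.2f\n",
                     "  gross turnover (gain+loss) %.2f; net change (gain-loss) %+.2f\n"),
              x$gain, x$loss, x$stable_suitable, x$stable_unsuitable,
              x$gross_turnover, x$net_change))
  invisible(x)
}

#' Centroid of a suitability class
#'
#' Area-weighted mean of the cell-center coordinates over the cells of the
#' target class (weights = spherical cell areas). Computed on the binary
#' class mask; set `weight_by` to a suitability raster for a
#' suitability-weighted variant.
#'
#' @param class_raster a [classify()] result.
#' @param target_class class name (default `"high"`) or code 0-3.
#' @param weight_by optional [grid_raster()] of additional per-cell weights.
#' @return list with `lon`, `lat`.
#' @export
class_centroid <- function(class_raster, target_class = "high", weight_by = NULL) {
  code <- if (is.character(target_class))
    match(target_class, suitability_classes) - 1L else as.integer(target_class)
  if (is.na(code) || code < 0L || code > 3L) stop("unknown class: ", target_class)
  idx <- which(!is.na(class_raster$values) & class_raster$values == code)
  if (!length(idx)) stop("class '", target_class, "' is empty")
  rows <- ((idx - 1L) %% nrow(class_raster$values)) + 1L
  cols <- ((idx - 1L) %/% nrow(class_raster$values)) + 1L
  cc <- cell_center(class_raster, rows, cols)
  w <- cell_area_km2(cc$lat, class_raster$cell_size)
  if (!is.null(weight_by)) w <- w * weight_by$values[cbind(rows, cols)]
  list(lon = sum(w * cc$lon) / sum(w), lat = sum(w * cc$lat) / sum(w))
}

#' Geodesic distance between two points
#'
#' WGS84 ellipsoidal inverse geodesic (the default, via
#' \pkg{geosphere}), or the spherical haversine with R = 6371 km as a
#' documented fallback (agrees within about 0.5%).
#'
#' @param a,b points as `list(lon =, lat =)` or length-2 lon/lat vectors.
#' @param method `"wgs84"` or `"haversine"`.
#' @return distance in km.
#' @export
geodesic_km <- function(a, b, method = c("wgs84", "haversine")) {
  method <- match.arg(method)
  pa <- as_lonlat(a); pb <- as_lonlat(b)
  if (method == "wgs84") return(geosphere::distGeo(pa, pb) / 1000)
  geosphere::distHaversine(pa, pb, r = 6371000) / 1000
}

as_lonlat <- function(p) {
  if (is.list(p)) c(p$lon, p$lat) else c(p[1L], p[2L])
}

#' Centroid shift vector
#'
#' Geodesic distance, initial bearing (degrees clockwise from north, in
#' `[0, 360)`), and the cardinal-quadrant label of the displacement from
#' `a` to `b`: a shift with both a northward and a westward component is
#' "NW"; pure-axis shifts get the single cardinal letter.
#'
#' @param a,b points as in [geodesic_km()].
#' @return object of class `shift_vector`: list with `from`, `to`,
#'   `distance_km`, `bearing`, `direction`.
#' @export
shift_vector <- function(a, b) {
  pa <- as_lonlat(a); pb <- as_lonlat(b)
  d <- geodesic_km(a, b)
  brg <- if (d == 0) 0 else (geosphere::bearing(pa, pb) %% 360)
  eps <- 1e-9
  lab <- if (abs(brg) < eps || abs(brg - 360) < eps) "N"
    else if (abs(brg - 90) < eps) "E"
    else if (abs(brg - 180) < eps) "S"
    else if (abs(brg - 270) < eps) "W"
    else if (brg < 90) "NE" else if (brg < 180) "SE"
    else if (brg < 270) "SW" else "NW"
  structure(list(from = list(lon = pa[1L], lat = pa[2L]),
                 to = list(lon = pb[1L], lat = pb[2L]),
                 distance_km = d, bearing = brg, direction = lab),
            class = "shift_vector")
}

#' @export
print.shift_vector <- function(x, ...) {
  cat(sprintf("<shift_vector> (%.4f, %.4f) -> (%.4f, %.4f): %.2f km %s (bearing %.1f deg)\n",
              x$from$lon, x$from$lat, x$to$lon, x$to$lat,
              x$distance_km, x$direction, x$bearing))
  invisible(x)
}
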