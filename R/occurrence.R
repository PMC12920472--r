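#' Occurrence record set
#'
#' Cleaned presence records in decimal-degree lon/lat. Stored as a
#' data.frame with columns `id`, `lon`, `lat`, `source`, `year`;
#' coordinates must be valid and (lon, lat) pairs unique.
#'
#' @param records data.frame with at least `lon` and `lat`; optional
#'   `source` and `year`.
#' @return object of class `occurrence_set` (a data.frame).
#' @export
occurrence_set <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("lon", "lat") %in% names(records)))
    stop("records need lon and lat columns")
  if (!nrow(records)) stop("occurrence set is empty")
  if (any(records$lon < -180 | records$lon > 180 |
          records$lat < -90 | records$lat > 90, na.rm = TRUE))
    stop("coordinates outside [-180, 180] x [-90, 90]")
  if (anyNA(records$lon) || anyNA(records$lat))
    stop("occurrence set must not contain missing coordinates")
  if (anyDuplicated(records[c("lon", "lat")]))
    stop("duplicate (lon, lat) pairs; clean_records() collapses these")
  out <- data.frame(id = seq_len(nrow(records)),
                    lon = records$lon, lat = records$lat,
                    source = if ("source" %in% names(records))
                      as.character(records$source) else NA_character_,
                    year = if ("year" %in% names(records))
                      suppressWarnings(as.integer(records$year)) else NA_integer_)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Clean raw occurrence records
#'
#' Drops rows with missing or unparseable coordinates, collapses exact
#' (lon, lat) duplicates to the first occurrence in input order, and, when
#' `min_year` is given, drops rows whose recorded year predates it (rows
#' with no year are retained). Removal counts are reported via `message()`.
#'
#' @param raw data.frame with `lon`/`lat` (or `longitude`/`latitude`)
#'   columns, optionally `source` and `year`.
#' @param min_year optional cutoff year.
#' @return an [occurrence_set()].
#' @export
clean_records <- function(raw, min_year = NULL) {
  raw <- as.data.frame(raw)
  names(raw)[names(raw) == "longitude"] <- "lon"
  names(raw)[names(raw) == "latitude"] <- "lat"
  if (!all(c("lon", "lat") %in% names(raw)))
    stop("raw table needs lon/lat (or longitude/latitude) columns")
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad_coord <- is.na(lon) | is.na(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  keep <- !bad_coord
  n_coord <- sum(bad_coord)
  n_year <- 0L
  if (!is.null(min_year) && "year" %in% names(raw)) {
    yr <- suppressWarnings(as.integer(raw$year))
    old <- !is.na(yr) & yr < min_year
    n_year <- sum(old & keep)
    keep <- keep & !old
  }
  df <- data.frame(lon = lon, lat = lat,
                   source = if ("source" %in% names(raw))
                     as.character(raw$source) else NA_character_,
                   year = if ("year" %in% names(raw))
                     suppressWarnings(as.integer(raw$year)) else NA_integer_)[keep, ]
  dup <- duplicated(df[c("lon", "lat")])
  n_dup <- sum(dup)
  df <- df[!dup, ]
  message(sprintf("clean_records: dropped %d bad-coordinate, %d pre-%s, %d duplicate row(s); %d kept",
                  n_coord, n_year, if (is.null(min_year)) "-" else min_year,
                  n_dup, nrow(df)))
  if (!nrow(df)) stop("no records survive cleaning")
  occurrence_set(df)
}

#' Spatially thin to one record per grid cell
#'
#' Records are bucketed on a regular lon/lat grid of the given cell size
#' anchored at (-180, 90); the first record in input order is kept per
#' occupied bucket. The default 30-arc-second cell (0.0083333 degrees)
#' approximates a 1 km filter. Thinning is deterministic and idempotent.
#'
#' @param occ an [occurrence_set()].
#' @param cell_size bucket edge in decimal degrees.
#' @return a thinned [occurrence_set()].
#' @export
thin_one_per_cell <- function(occ, cell_size = 1 / 120) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  bx <- floor((occ$lon - (-180)) / cell_size)
  by <- floor((90 - occ$lat) / cell_size)
  keep <- !duplicated(paste(bx, by))
  out <- occ[keep, ]
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Random train/test split of occurrences
#'
#' @param occ an [occurrence_set()].
#' @param train_fraction fraction in (0, 1); train size is
#'   `round(n * train_fraction)`.
#' @param seed integer seed.
#' @return list with `train` and `test` occurrence sets (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(occ, train_fraction = 0.75, seed = 1L) {
  n <- nrow(occ)
  if (n < 4L) stop("need at least 4 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  train <- occ[sort(idx), ]
  test <- occ[setdiff(seq_len(n), idx), ]
  class(train) <- class(test) <- c("occurrence_set", "data.frame")
  list(train = train, test = test)
}

#' Read / write occurrence CSV
#'
#' The CSV layout is `species,longitude,latitude[,source,year]`; `species`
#' is optional on read and written as `species` when present.
#'
#' @param path file path.
#' @param min_year optional cleaning cutoff passed to [clean_records()].
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path, min_year = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  clean_records(df, min_year = min_year)
}

#' @rdname read_occurrences
#' @param occ an [occurrence_set()].
#' @param species species label written in the first column.
#' @export
write_occurrences <- function(occ, path, species = "species") {
  utils::write.csv(data.frame(species = species, longitude = occ$lon,
                              latitude = occ$lat, source = occ$source,
                              year = occ$year),
                   path, row.names = FALSE)
  invisible(path)
}
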