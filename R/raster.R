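#' Geographic grid raster
#'
#' A minimal north-up, square-cell raster on a geographic (WGS84 lon/lat)
#' grid. Values are stored as a numeric matrix in row-major map order: row 1
#' is the northernmost row, column 1 the westernmost column. Missing cells
#' are `NA` in memory and written out as the `nodata` sentinel.
#'
#' Cell (r, c) (1-based here; the underlying convention is 0-based) has its
#' center at `lon = origin_lon + (c - 0.5) * cell_size`,
#' `lat = origin_lat - (r - 0.5) * cell_size`, where (`origin_lon`,
#' `origin_lat`) is the top-left corner of the grid. Cells are half-open
#' intervals `[edge, edge + cell_size)` in longitude and `(edge - cell_size,
#' edge]`-complementary in latitude, so a point on a boundary belongs to the
#' cell to its east/south.
#'
#' @param values numeric matrix (rows = north to south), `NA` for nodata.
#' @param origin_lon,origin_lat decimal degrees of the top-left corner.
#' @param cell_size cell edge in decimal degrees (square cells).
#' @param name layer label.
#' @param nodata sentinel used on disk; `NA` internally.
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin_lon, origin_lat, cell_size,
                        name = "layer", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("raster must have >= 1 row and column")
  if (any(!is.na(values) & !is.finite(values)))
    stop("raster values must be finite or NA")
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, name = name, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %s: %d x %d cells of %g deg, origin (%g, %g), %d nodata\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_lon, x$origin_lat, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  list(lon_min = r$origin_lon,
       lon_max = r$origin_lon + ncol(r$values) * r$cell_size,
       lat_min = r$origin_lat - nrow(r$values) * r$cell_size,
       lat_max = r$origin_lat)
}

#' Cell centers of a raster
#'
#' @param r a `grid_raster`.
#' @param rows,cols 1-based indices (vectors, recycled together).
#' @return data.frame with `lon`, `lat`.
#' @export
cell_center <- function(r, rows, cols) {
  data.frame(lon = r$origin_lon + (cols - 0.5) * r$cell_size,
             lat = r$origin_lat - (rows - 0.5) * r$cell_size)
}

#' Locate points on the grid
#'
#' Maps lon/lat to 1-based (row, col); points on a cell edge fall in the
#' half-open interval `[edge, edge + cell_size)` going east and south.
#' Points outside the extent get `NA` indices.
#'
#' @param r a `grid_raster`.
#' @param lon,lat coordinate vectors, decimal degrees.
#' @return data.frame with `row`, `col`.
#' @export
locate_cells <- function(r, lon, lat) {
  col <- floor((lon - r$origin_lon) / r$cell_size) + 1L
  row <- floor((r$origin_lat - lat) / r$cell_size) + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read a gridded layer
#'
#' Reads an ESRI ASCII grid (`.asc`), the text raster format classical
#' MaxEnt tooling consumes. Both `xllcorner/yllcorner` and
#' `xllcenter/yllcenter` headers are accepted. GeoTIFF is not supported:
#' no installed reader preserves the geotransform, and a silently
#' georeference-free import would be worse than an error.
#'
#' @param path file path.
#' @param format `"ascii_grid"` (default) or `"geotiff"` (errors).
#' @param name layer label; defaults to the file stem.
#' @return a [grid_raster()].
#' @export
read_grid <- function(path, format = c("ascii_grid", "geotiff"), name = NULL) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF input is not supported; convert to ESRI ASCII grid")
  if (!file.exists(path)) stop("cannot read grid: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ", paste(setdiff(need, names(hdr)), collapse = ", "), "): ", path)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("unsupported grid: non-square cells")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has ", length(vals), " values, expected ", hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid_raster(m, origin_lon = xll,
              origin_lat = yll + hdr$nrows * hdr$cellsize,
              cell_size = hdr$cellsize, name = name, nodata = nodata)
}

#' Write a gridded layer
#'
#' Writes an ESRI ASCII grid. Values are printed with 17 significant
#' digits so a write/read round trip reproduces IEEE doubles exactly.
#'
#' @param r a [grid_raster()].
#' @param path output file path.
#' @param format only `"ascii_grid"` is supported.
#' @return `path`, invisibly.
#' @export
write_grid <- function(r, path, format = "ascii_grid") {
  if (format != "ascii_grid")
    stop("only ascii_grid output is supported")
  ext <- raster_extent(r)
  m <- r$values
  m[is.na(m)] <- r$nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.17g", ext$lon_min),
           sprintf("yllcorner %.17g", ext$lat_min),
           sprintf("cellsize %.17g", r$cell_size),
           sprintf("NODATA_value %.17g", r$nodata))
  body <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Bundle aligned layers into a stack
#'
#' All layers must share dims, origin and cell size; the union of their
#' nodata masks is applied to every layer so the stack has one common mask.
#' Use [align_stack()] first when grids differ.
#'
#' @param rasters list of [grid_raster()].
#' @param names unique layer labels; default taken from the rasters.
#' @return object of class `grid_stack`: a named list of `grid_raster`.
#' @export
grid_stack <- function(rasters, names = NULL) {
  if (length(rasters) < 1L) stop("need at least one raster")
  if (is.null(names)) names <- vapply(rasters, `[[`, "", "name")
  if (anyDuplicated(names) || any(!nzchar(names)))
    stop("layer names must be unique and non-empty")
  ref <- rasters[[1L]]
  for (r in rasters[-1L])
    if (!same_grid(ref, r)) stop("layers are not on the same grid; use align_stack()")
  mask <- Reduce(`|`, lapply(rasters, function(r) is.na(r$values)))
  rasters <- lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    r$values[mask] <- NA_real_
    r$name <- names[i]
    r
  })
  names(rasters) <- names
  structure(rasters, class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  r <- x[[1L]]
  cat(sprintf("<grid_stack> %d layers (%s), %d x %d cells of %g deg\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(r$values), ncol(r$values), r$cell_size))
  invisible(x)
}

stack_valid_mask <- function(stack) !is.na(stack[[1L]]$values)

# n_valid_cells x k matrix of layer values at all valid cells, plus coords
stack_cell_table <- function(stack) {
  mask <- stack_valid_mask(stack)
  idx <- which(mask)                       # column-major cell index
  r <- stack[[1L]]
  rows <- ((idx - 1L) %% nrow(r$values)) + 1L
  cols <- ((idx - 1L) %/% nrow(r$values)) + 1L
  env <- vapply(stack, function(l) l$values[idx], numeric(length(idx)))
  env <- matrix(env, nrow = length(idx),
                dimnames = list(NULL, names(stack)))
  list(env = env, rows = rows, cols = cols, coords = cell_center(r, rows, cols))
}

#' Align rasters onto a common grid
#'
#' Crops every layer to the intersection of the extents and resamples to the
#' coarsest cell size by nearest neighbor (each output cell takes the value
#' of the input cell containing the output cell center). The union of the
#' nodata masks is applied to all layers.
#'
#' @param rasters list of [grid_raster()].
#' @param names optional layer labels.
#' @return a [grid_stack()].
#' @export
align_stack <- function(rasters, names = NULL) {
  if (length(rasters) < 1L) stop("need at least one raster")
  exts <- lapply(rasters, raster_extent)
  lon_min <- max(vapply(exts, `[[`, 0, "lon_min"))
  lon_max <- min(vapply(exts, `[[`, 0, "lon_max"))
  lat_min <- max(vapply(exts, `[[`, 0, "lat_min"))
  lat_max <- min(vapply(exts, `[[`, 0, "lat_max"))
  if (lon_min >= lon_max || lat_min >= lat_max)
    stop("rasters have no overlapping extent")
  sizes <- vapply(rasters, `[[`, 0, "cell_size")
  ref <- rasters[[which.max(sizes)]]
  cs <- ref$cell_size
  # snap the output window to the reference layer's grid lines
  c0 <- ceiling((lon_min - ref$origin_lon) / cs - 1e-9)
  c1 <- floor((lon_max - ref$origin_lon) / cs + 1e-9)
  r0 <- ceiling((ref$origin_lat - lat_max) / cs - 1e-9)
  r1 <- floor((ref$origin_lat - lat_min) / cs + 1e-9)
  if (c1 <= c0 || r1 <= r0) stop("rasters have no overlapping extent")
  out_origin_lon <- ref$origin_lon + c0 * cs
  out_origin_lat <- ref$origin_lat - r0 * cs
  n_row <- r1 - r0; n_col <- c1 - c0
  centers <- expand.grid(row = seq_len(n_row), col = seq_len(n_col))
  tmpl <- grid_raster(matrix(0, n_row, n_col), out_origin_lon, out_origin_lat, cs)
  cc <- cell_center(tmpl, centers$row, centers$col)
  layers <- lapply(rasters, function(r) {
    rc <- locate_cells(r, cc$lon, cc$lat)
    v <- rep(NA_real_, nrow(rc))
    ok <- !is.na(rc$row)
    v[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
    m <- matrix(NA_real_, n_row, n_col)
    m[cbind(centers$row, centers$col)] <- v
    grid_raster(m, out_origin_lon, out_origin_lat, cs, name = r$name,
                nodata = r$nodata)
  })
  grid_stack(layers, names)
}

#' Sample matrix of environmental values
#'
#' The design matrix consumed by the fitting engine: one row per presence or
#' background point, one column per stack layer, with coordinates and a
#' presence/background label carried alongside. Rows never contain missing
#' values.
#'
#' @param env numeric matrix, columns named by layer.
#' @param coords data.frame with `lon`, `lat` per row.
#' @param label character vector, `"presence"` or `"background"` per row.
#' @return object of class `sample_matrix`.
#' @export
sample_matrix <- function(env, coords, label) {
  env <- as.matrix(env)
  if (anyNA(env)) stop("sample matrix must not contain missing values")
  if (nrow(env) != nrow(coords) || nrow(env) != length(label))
    stop("env, coords and label must have matching lengths")
  structure(list(env = env, coords = as.data.frame(coords),
                 label = as.character(label)),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %d rows (%d presence, %d background) x %d layers\n",
              nrow(x$env), sum(x$label == "presence"),
              sum(x$label == "background"), ncol(x$env)))
  invisible(x)
}

rbind_samples <- function(a, b) {
  sample_matrix(rbind(a$env, b$env), rbind(a$coords, b$coords),
                c(a$label, b$label))
}

#' Extract layer values at points
#'
#' Each point is mapped to the cell containing it; points falling outside
#' the extent or on nodata cells are dropped with a message giving the
#' count.
#'
#' @param stack a [grid_stack()].
#' @param points an occurrence set or any data.frame with `lon`, `lat`.
#' @param label row label, `"presence"` or `"background"`.
#' @return a [sample_matrix()].
#' @export
extract_at_points <- function(stack, points, label = "presence") {
  lon <- points$lon; lat <- points$lat
  r <- stack[[1L]]
  rc <- locate_cells(r, lon, lat)
  ok <- !is.na(rc$row)
  if (any(ok)) {
    idx <- cbind(rc$row[ok], rc$col[ok])
    ok[ok] <- !is.na(r$values[idx])
  }
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    message(n_drop, " point(s) outside the extent or on nodata cells dropped")
  if (!any(ok)) stop("no points fall on valid cells")
  rc <- rc[ok, , drop = FALSE]
  env <- vapply(stack, function(l) l$values[cbind(rc$row, rc$col)],
                numeric(nrow(rc)))
  env <- matrix(env, nrow = nrow(rc), dimnames = list(NULL, names(stack)))
  sample_matrix(env, data.frame(lon = lon[ok], lat = lat[ok]),
                rep(label, nrow(rc)))
}

#' Draw background points
#'
#' Samples cells uniformly at random without replacement from the valid
#' (non-nodata) cells — at most one background point per cell, the
#' convention of presence-only MaxEnt. Asking for more points than there
#' are valid cells returns every valid cell once, with a warning.
#'
#' @param stack a [grid_stack()].
#' @param n number of background points.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a [sample_matrix()] with label `"background"`.
#' @export
sample_background <- function(stack, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  tab <- stack_cell_table(stack)
  n_valid <- nrow(tab$env)
  if (n_valid == 0L) stop("stack has no valid cells")
  if (n > n_valid) {
    warning("requested ", n, " background points but only ", n_valid,
            " valid cells; using all of them")
    n <- n_valid
  }
  pick <- with_seed(seed, sample.int(n_valid, n))
  sample_matrix(tab$env[pick, , drop = FALSE], tab$coords[pick, ],
                rep("background", n))
}
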