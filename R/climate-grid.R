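# Georeferenced single-band climate rasters (ESRI ASCII grid contract) and
# point extraction. Coordinates and grids are assumed to share WGS84; no
# reprojection is performed.

#' Construct a climate grid
#'
#' A `climate_grid` is a single-variable georeferenced raster: a numeric
#' matrix in map orientation (row 1 = northernmost row), a lower-left corner,
#' a square cell size in decimal degrees, and a nodata sentinel. Missing
#' cells are stored as `NA` internally.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param x_ll,y_ll longitude/latitude of the lower-left corner of the
#'   lower-left cell (degrees, WGS84).
#' @param cell_size cell edge in decimal degrees (> 0).
#' @param variable `"PDQ"` (precipitation of the driest quarter, mm) or
#'   `"MTCM"` (minimum temperature of the coldest month, degrees C).
#' @param nodata_value sentinel written to file for missing cells.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(values, x_ll, y_ll, cell_size,
                         variable = c("PDQ", "MTCM"), nodata_value = -9999) {
  variable <- match.arg(variable)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty grid", call. = FALSE)
  assert_number(x_ll, "x_ll")
  assert_number(y_ll, "y_ll")
  assert_number(cell_size, "cell_size")
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  structure(
    list(variable = variable, values = values,
         n_rows = nrow(values), n_cols = ncol(values),
         x_ll = x_ll, y_ll = y_ll, cell_size = cell_size,
         nodata_value = nodata_value),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid [%s]: %d x %d cells of %g deg, origin (%g, %g), %d nodata\n",
              x$variable, x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll,
              sum(is.na(x$values))))
  invisible(x)
}

# Cell-centre latitudes, north to south (matching matrix row order).
#' @noRd
grid_lat_centers <- function(grid) {
  grid$y_ll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
}

# Cell-centre longitudes, west to east.
#' @noRd
grid_lon_centers <- function(grid) {
  grid$x_ll + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by `nrows` rows of values,
#' top (north) row first. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path path to the `.asc` file.
#' @param variable variable label to attach, `"PDQ"` or `"MTCM"`.
#' @return a [climate_grid].
#' @export
read_ascii_grid <- function(path, variable = c("PDQ", "MTCM")) {
  variable <- match.arg(variable)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing_keys <- setdiff(req, names(hdr))
  if (length(missing_keys) > 0L) {
    stop("malformed ASCII grid header, missing: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  body <- lines[i:length(lines)]
  if (length(body) != n_rows) {
    stop(sprintf("expected %d data rows, found %d", n_rows, length(body)),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = n_rows, ncol = n_cols)
  for (r in seq_len(n_rows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != n_cols || anyNA(row)) {
      stop(sprintf("row %d: expected %d numeric values", r, n_cols),
           call. = FALSE)
    }
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  climate_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
               variable = variable, nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written at full double precision so that write-then-read
#' round-trips the grid exactly; `NA` cells are written as the grid's
#' nodata sentinel.
#'
#' @param grid a [climate_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %s", format_full(grid$x_ll)),
    sprintf("yllcorner %s", format_full(grid$y_ll)),
    sprintf("cellsize %s", format_full(grid$cell_size)),
    sprintf("NODATA_value %s", format_full(grid$nodata_value)))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata_value
  body <- apply(vals, 1L, function(r) paste(format_full(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Extract grid values at points
#'
#' Containing-cell lookup (no interpolation). Cells are half-open:
#' `[k * cell, (k + 1) * cell)` in both axes, so a point on a shared edge
#' belongs to the higher-index (east/north) cell. Points outside the extent
#' or on nodata cells yield `NA`.
#'
#' @param grid a [climate_grid].
#' @param lat,lon numeric vectors of point coordinates (degrees, WGS84).
#' @return numeric vector of cell values (`NA` = missing).
#' @export
extract_at_points <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "climate_grid"))
  validate_coords(lat, lon)
  col <- floor((lon - grid$x_ll) / grid$cell_size) + 1
  row_from_bottom <- floor((lat - grid$y_ll) / grid$cell_size) + 1
  row <- grid$n_rows - row_from_bottom + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_real_, length(lat))
  if (any(ok)) {
    out[ok] <- grid$values[cbind(row[ok], col[ok])]
  }
  out
}

#' Link occurrence records to climate values
#'
#' Extracts PDQ and MTCM at each record; records with either value missing
#' (outside extent or on a nodata cell) are dropped and counted.
#'
#' @param records data frame with columns `species`, `lat`, `lon`.
#' @param pdq_grid [climate_grid] carrying variable `"PDQ"`.
#' @param mtcm_grid [climate_grid] carrying variable `"MTCM"`.
#' @return list with `data` (data frame: species, lat, lon, pdq_mm, mtcm_c)
#'   and `n_dropped`.
#' @export
link_climate <- function(records, pdq_grid, mtcm_grid) {
  stopifnot(is.data.frame(records),
            all(c("species", "lat", "lon") %in% names(records)))
  stopifnot(inherits(pdq_grid, "climate_grid"), inherits(mtcm_grid, "climate_grid"))
  if (pdq_grid$variable != "PDQ" || mtcm_grid$variable != "MTCM") {
    stop("grid variable labels do not match arguments (expect PDQ, MTCM)",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(list(data = data.frame(species = character(), lat = numeric(),
                                  lon = numeric(), pdq_mm = numeric(),
                                  mtcm_c = numeric()),
                n_dropped = 0L))
  }
  pdq <- extract_at_points(pdq_grid, records$lat, records$lon)
  mtcm <- extract_at_points(mtcm_grid, records$lat, records$lon)
  keep <- !is.na(pdq) & !is.na(mtcm)
  out <- data.frame(species = records$species[keep],
                    lat = records$lat[keep], lon = records$lon[keep],
                    pdq_mm = pdq[keep], mtcm_c = mtcm[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(data = out, n_dropped = sum(!keep))
}
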