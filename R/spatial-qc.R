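# Grid-based spatial thinning, minimum-specimen filtering and Moran's I
# spatial-autocorrelation diagnostics.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over paired points.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * r * asin(sqrt(a))
}

# Half-open grid-cell key: cell index k = floor(coord / cell_deg), cells are
# [k*cell_deg, (k+1)*cell_deg); a boundary point belongs to the higher-index
# cell.
#' @noRd
grid_cell_key <- function(lat, lon, cell_deg) {
  paste(floor(lon / cell_deg), floor(lat / cell_deg), sep = ":")
}

#' Thin occurrences to one record per grid cell per species
#'
#' Within each species, at most one record is retained per `cell_deg` grid
#' cell, chosen uniformly at random among the records in that cell. Each
#' species draws from its own derived random stream, so thinning is
#' deterministic given the seed and independent across species. Output
#' preserves the input row order. Thinning an already-thinned set returns
#' it unchanged (every occupied cell holds a single record).
#'
#' @param records data frame with columns `species`, `lat`, `lon`.
#' @param cell_deg grid cell size in decimal degrees (default 0.1).
#' @param seed integer seed.
#' @return data frame of retained records.
#' @export
thin_to_grid <- function(records, cell_deg = 0.1, seed = 1L) {
  stopifnot(is.data.frame(records),
            all(c("species", "lat", "lon") %in% names(records)))
  if (!is.numeric(cell_deg) || length(cell_deg) != 1L || cell_deg <= 0) {
    stop("cell_deg must be a positive number", call. = FALSE)
  }
  if (nrow(records) == 0L) return(records)
  keep <- logical(nrow(records))
  for (sp in sort(unique(records$species))) {
    idx <- which(records$species == sp)
    keys <- grid_cell_key(records$lat[idx], records$lon[idx], cell_deg)
    withr::with_seed(derive_seed(seed, paste0("thin_", sp)), {
      for (k in sort(unique(keys))) {
        members <- idx[keys == k]
        keep[members[sample.int(length(members), 1L)]] <- TRUE
      }
    })
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude species with too few records
#'
#' Applied after thinning and climate linking: species whose remaining
#' record count is below `min_n` are excluded and reported.
#'
#' @param records data frame with a `species` column.
#' @param min_n minimum record count per species (default 10).
#' @return list with `kept` (records of retained species) and `excluded`
#'   (data frame: `species`, `n`).
#' @export
filter_min_specimens <- function(records, min_n = 10) {
  stopifnot(is.data.frame(records), "species" %in% names(records), min_n >= 1)
  if (nrow(records) == 0L) {
    return(list(kept = records,
                excluded = data.frame(species = character(), n = integer(),
                                      stringsAsFactors = FALSE)))
  }
  counts <- table(records$species)
  bad <- names(counts)[counts < min_n]
  kept <- records[!(records$species %in% bad), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       excluded = data.frame(species = bad,
                             n = as.integer(counts[bad]),
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Moran's I with distance-band weights
#'
#' Computes `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with binary weights `w_ij = 1` iff
#' `0 < d_ij <= lag_km` (great-circle distance), `W = sum w_ij`. No row
#' standardisation by default. Expectation is `-1/(n-1)`; the variance is
#' taken under the normality assumption and the two-sided p-value from the
#' normal approximation.
#'
#' @param values numeric vector of the variable observed at each point.
#' @param lat,lon matching point coordinates (degrees, WGS84).
#' @param lag_km distance-band upper bound in km.
#' @param weight_type `"binary"` (default) or `"inverse_distance"`
#'   (`1/d_ij` within the band).
#' @param row_standardize divide each row of the weight matrix by its sum
#'   (the convention of some spatial packages); default `FALSE`.
#' @return list of class `moran_result`: `I`, `expected_I`, `variance_I`,
#'   `p_value`, `n`, `lag_km`, `W`.
#' @export
morans_i <- function(values, lat, lon, lag_km,
                     weight_type = c("binary", "inverse_distance"),
                     row_standardize = FALSE) {
  weight_type <- match.arg(weight_type)
  validate_coords(lat, lon)
  n <- length(values)
  if (n < 3L || length(lat) != n) {
    stop("need at least 3 points with matching coordinates", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("zero variance in values: Moran's I undefined", call. = FALSE)
  }
  d <- haversine_km(rep(lat, times = n), rep(lon, times = n),
                    rep(lat, each = n), rep(lon, each = n))
  d <- matrix(d, n, n)
  w <- matrix(0, n, n)
  band <- d > 0 & d <= lag_km
  w[band] <- if (weight_type == "binary") 1 else 1 / d[band]
  if (sum(w) == 0) {
    stop(sprintf("no pairs within lag %g km", lag_km), call. = FALSE)
  }
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  s0 <- sum(w)
  z <- values - mean(values)
  i_stat <- (n / s0) * sum(w * tcrossprod(z)) / sum(z^2)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - e_i^2
  var_i <- max(var_i, 0)
  p <- if (var_i == 0) NA_real_ else
    2 * stats::pnorm(-abs((i_stat - e_i) / sqrt(var_i)))
  structure(list(I = i_stat, expected_I = e_i, variance_I = var_i,
                 p_value = p, n = n, lag_km = lag_km, W = s0),
            class = "moran_result")
}

#' Per-species Moran's I QC table
#'
#' Runs [morans_i] on the extracted PDQ and MTCM values of every species at
#' each lag distance. Moran's I needs a variable, not just coordinates;
#' computing it on the climate values at the occurrence points is this
#' package's (deliberately flagged) interpretation. Species/lag
#' combinations where the statistic is undefined (no pairs within the lag,
#' or constant values) are reported with `NA` and a note rather than
#' failing the run.
#'
#' @param specimens data frame with columns `species`, `lat`, `lon`,
#'   `pdq_mm`, `mtcm_c` (the output of [link_climate]).
#' @param lags_km numeric vector of lag distances (default 10, 20, 50 km).
#' @return data frame: `species`, `variable`, `lag_km`, `n`, `I`,
#'   `expected_I`, `variance_I`, `p_value`, `note`.
#' @export
moran_qc <- function(specimens, lags_km = c(10, 20, 50)) {
  stopifnot(is.data.frame(specimens),
            all(c("species", "lat", "lon", "pdq_mm", "mtcm_c") %in%
                  names(specimens)))
  rows <- list()
  for (sp in sort(unique(specimens$species))) {
    sub <- specimens[specimens$species == sp, , drop = FALSE]
    for (variable in c("PDQ", "MTCM")) {
      x <- if (variable == "PDQ") sub$pdq_mm else sub$mtcm_c
      for (lag in lags_km) {
        res <- tryCatch(morans_i(x, sub$lat, sub$lon, lag),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, variable = variable, lag_km = lag,
            n = nrow(sub), I = NA_real_, expected_I = NA_real_,
            variance_I = NA_real_, p_value = NA_real_, note = res,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, variable = variable, lag_km = lag,
            n = res$n, I = res$I, expected_I = res$expected_I,
            variance_I = res$variance_I, p_value = res$p_value, note = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
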