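# Virtual climate surfaces and virtual species with known (planted)
# tolerance structure. The generators are pure functions of (config, seed),
# so every downstream stage is testable without any data download.

#' Configure a synthetic climate landscape
#'
#' Defines a pair of spatially smooth climate surfaces with latitudinal
#' gradients over a rectangular WGS84 extent. Defaults emulate a subtropical
#' study region: the PDQ trend falls from ~135 mm in the south to ~45 mm in
#' the north and MTCM from ~11 to ~ -4 degrees C. The default PDQ noise
#' amplitude (30 mm) is comparable to the gradient span, so dry patches
#' occur at many latitudes and the two variables stay only weakly coupled
#' at the specimen level — a drought niche and a cold niche are then
#' distinct targets rather than the same corner of the map, and the planted
#' tolerance structure is a well-defined ground truth.
#'
#' Each surface is `base + gradient * latitude + noise`, where the noise is
#' white noise smoothed by a Gaussian kernel of `noise_range` cells and then
#' scaled to `noise_amplitude` (standard deviation, in variable units).
#'
#' @param lat_min,lat_max,lon_min,lon_max extent in decimal degrees.
#' @param cell_size cell edge in decimal degrees.
#' @param pdq,mtcm per-variable lists with elements `base`, `gradient`
#'   (units per degree latitude) and `noise_amplitude` (sd, variable units).
#' @param noise_range Gaussian smoothing length of the noise field, in cells.
#' @param nodata_fraction fraction of cells set to nodata (in `[0, 1]`).
#' @param seed integer master seed.
#' @return an object of class `surface_config`.
#' @export
surface_config <- function(lat_min = 22, lat_max = 34,
                           lon_min = 100, lon_max = 115,
                           cell_size = 0.25,
                           pdq = list(base = 300, gradient = -7.5,
                                      noise_amplitude = 30),
                           mtcm = list(base = 37, gradient = -1.2,
                                       noise_amplitude = 1.2),
                           noise_range = 3,
                           nodata_fraction = 0.02,
                           seed = 1L) {
  if (lat_max <= lat_min || lon_max <= lon_min) {
    stop("degenerate extent", call. = FALSE)
  }
  assert_number(cell_size, "cell_size")
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  assert_number(nodata_fraction, "nodata_fraction", 0, 1)
  for (v in list(pdq, mtcm)) {
    stopifnot(is.list(v), all(c("base", "gradient", "noise_amplitude") %in% names(v)))
  }
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 cell_size = cell_size, pdq = pdq, mtcm = mtcm,
                 noise_range = noise_range,
                 nodata_fraction = nodata_fraction,
                 seed = as.integer(seed)),
            class = "surface_config")
}

# Separable Gaussian smoothing of a matrix (reflected edges).
#' @noRd
smooth_field <- function(m, range_cells) {
  if (range_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  pad_smooth <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
    stats::filter(xp, k, sides = 2)[half + seq_len(n)]
  }
  m <- apply(m, 2L, pad_smooth)
  t(apply(m, 1L, pad_smooth))
}

#' Generate a synthetic climate grid
#'
#' Deterministic given the config seed (each variable draws from its own
#' derived stream). With `noise_amplitude = 0` every cell equals
#' `base + gradient * (cell-centre latitude)` exactly.
#'
#' @param config a [surface_config].
#' @param variable `"PDQ"` or `"MTCM"`.
#' @return a [climate_grid].
#' @export
gen_climate_grid <- function(config, variable = c("PDQ", "MTCM")) {
  stopifnot(inherits(config, "surface_config"))
  variable <- match.arg(variable)
  par <- if (variable == "PDQ") config$pdq else config$mtcm
  n_rows <- max(1L, round((config$lat_max - config$lat_min) / config$cell_size))
  n_cols <- max(1L, round((config$lon_max - config$lon_min) / config$cell_size))
  lat_c <- config$lat_min + (n_rows - seq_len(n_rows) + 0.5) * config$cell_size
  vals <- matrix(rep(par$base + par$gradient * lat_c, times = n_cols),
                 nrow = n_rows, ncol = n_cols)
  withr::with_seed(derive_seed(config$seed, paste0("grid_", variable)), {
    if (par$noise_amplitude > 0) {
      noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
      noise <- smooth_field(noise, config$noise_range)
      noise <- noise / stats::sd(noise)
      vals <- vals + par$noise_amplitude * noise
    }
    if (config$nodata_fraction > 0) {
      n_na <- floor(config$nodata_fraction * n_rows * n_cols)
      if (n_na > 0) vals[sample.int(n_rows * n_cols, n_na)] <- NA_real_
    }
  })
  climate_grid(vals, x_ll = config$lon_min, y_ll = config$lat_min,
               cell_size = config$cell_size, variable = variable)
}

# Landscape values over cells valid in both grids.
#' @noRd
landscape_values <- function(grids) {
  stopifnot(is.list(grids), inherits(grids$pdq, "climate_grid"),
            inherits(grids$mtcm, "climate_grid"))
  ok <- !is.na(grids$pdq$values) & !is.na(grids$mtcm$values)
  if (!any(ok)) stop("grids share no valid-data cells", call. = FALSE)
  list(pdq = grids$pdq$values[ok], mtcm = grids$mtcm$values[ok])
}

#' Generate a pool of virtual species
#'
#' Species have bivariate Gaussian climatic niches. "Planted" tolerant
#' species get a niche centre drawn strictly below the landscape 25th
#' percentile of the matching variable — uniform on the 5th-20th percentile
#' band, leaving a margin below the 25th percentile so that the planted
#' label is a well-defined ground truth rather than a coin flip at the band
#' boundary; all other centres are drawn from the landscape interquartile
#' range. Drought- and cold-planted subsets are sampled independently, so a
#' species can be planted for both, as real candidates can be.
#'
#' @param n_species pool size.
#' @param n_planted_drought,n_planted_cold planted counts (each
#'   `<= n_species`).
#' @param grids list with elements `pdq` and `mtcm` ([climate_grid]s).
#' @param seed integer seed.
#' @param n_occurrences per-species record count (scalar or length
#'   `n_species`); uneven sampling intensity is expressed through this.
#' @param sigma_pdq,sigma_mtcm niche breadths (sd, mm / degrees C).
#' @return data frame with one row per species: `name`, `mu_pdq`,
#'   `mu_mtcm`, `sigma_pdq`, `sigma_mtcm`, `planted_drought`,
#'   `planted_cold`, `n_occurrences`.
#' @export
gen_species_pool <- function(n_species = 35, n_planted_drought = 9,
                             n_planted_cold = 9, grids, seed = 1L,
                             n_occurrences = 30,
                             sigma_pdq = 8, sigma_mtcm = 1.0) {
  stopifnot(n_species >= 1)
  if (n_planted_drought > n_species || n_planted_cold > n_species) {
    stop("planted counts exceed pool size", call. = FALSE)
  }
  stopifnot(sigma_pdq > 0, sigma_mtcm > 0)
  land <- landscape_values(grids)
  q_pdq <- stats::quantile(land$pdq, c(0.05, 0.20, 0.25, 0.75),
                           names = FALSE, type = 7)
  q_mtcm <- stats::quantile(land$mtcm, c(0.05, 0.20, 0.25, 0.75),
                            names = FALSE, type = 7)
  n_occ <- rep_len(n_occurrences, n_species)
  stopifnot(all(n_occ >= 0))
  withr::with_seed(derive_seed(seed, "species_pool"), {
    planted_d <- seq_len(n_species) %in% sample.int(n_species, n_planted_drought)
    planted_c <- seq_len(n_species) %in% sample.int(n_species, n_planted_cold)
    # q = (Q05, Q20, Q25, Q75): planted centres on [Q05, Q20], others on
    # the interquartile range; every planted centre is strictly < Q25
    draw <- function(planted, q) {
      mu <- numeric(length(planted))
      mu[planted] <- stats::runif(sum(planted), q[1], q[2])
      mu[!planted] <- stats::runif(sum(!planted), q[3], q[4])
      stopifnot(all(mu[planted] < q[3]))
      mu
    }
    mu_pdq <- draw(planted_d, q_pdq)
    mu_mtcm <- draw(planted_c, q_mtcm)
  })
  data.frame(name = sprintf("species_%02d", seq_len(n_species)),
             mu_pdq = mu_pdq, mu_mtcm = mu_mtcm,
             sigma_pdq = sigma_pdq, sigma_mtcm = sigma_mtcm,
             planted_drought = planted_d, planted_cold = planted_c,
             n_occurrences = as.integer(n_occ),
             stringsAsFactors = FALSE)
}

#' Generate occurrence records for virtual species
#'
#' Cells valid in both grids are sampled with replacement with probability
#' proportional to the bivariate Gaussian suitability
#' `exp(-(vP - muP)^2 / (2 sigmaP^2) - (vT - muT)^2 / (2 sigmaT^2))`;
#' each record is then placed uniformly inside its chosen cell. Each
#' species draws from its own derived stream, so pools are reproducible
#' record-for-record and independent across species.
#'
#' @param species one or more rows of a [gen_species_pool] data frame.
#' @param grids list with elements `pdq` and `mtcm`.
#' @param seed integer seed.
#' @return data frame of records: `species`, `lat`, `lon`.
#' @export
gen_occurrences <- function(species, grids, seed = 1L) {
  stopifnot(is.data.frame(species), nrow(species) >= 1)
  land_ok <- !is.na(grids$pdq$values) & !is.na(grids$mtcm$values)
  if (!any(land_ok)) stop("grids share no valid-data cells", call. = FALSE)
  idx_ok <- which(land_ok)
  vP <- grids$pdq$values[idx_ok]
  vT <- grids$mtcm$values[idx_ok]
  g <- grids$pdq
  row_of <- (idx_ok - 1L) %% g$n_rows + 1L
  col_of <- (idx_ok - 1L) %/% g$n_rows + 1L
  lat_c <- grid_lat_centers(g)[row_of]
  lon_c <- grid_lon_centers(g)[col_of]
  half <- g$cell_size / 2
  out <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    sp <- species[i, ]
    n <- sp$n_occurrences
    if (n == 0L) {
      out[[i]] <- data.frame(species = character(), lat = numeric(),
                             lon = numeric(), stringsAsFactors = FALSE)
      next
    }
    w <- exp(-(vP - sp$mu_pdq)^2 / (2 * sp$sigma_pdq^2)
             - (vT - sp$mu_mtcm)^2 / (2 * sp$sigma_mtcm^2))
    if (sum(w) == 0) {
      stop(sprintf("total suitability is zero for %s: niche outside the landscape range",
                   sp$name), call. = FALSE)
    }
    withr::with_seed(derive_seed(seed, paste0("occ_", sp$name)), {
      cells <- sample.int(length(w), n, replace = TRUE, prob = w)
      # uniform jitter stays strictly inside the half-open cell
      lat <- lat_c[cells] + stats::runif(n, -half, half)
      lon <- lon_c[cells] + stats::runif(n, -half, half)
    })
    out[[i]] <- data.frame(species = sp$name, lat = lat, lon = lon,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact occurrence-climate distribution for one virtual species
#'
#' Enumerates the suitability-weighted discrete distribution over valid
#' cells — the distribution [gen_occurrences] samples from. Useful as an
#' analytic oracle for the generator.
#'
#' @inheritParams gen_occurrences
#' @return data frame: `pdq`, `mtcm`, `prob` per valid cell.
#' @export
occurrence_cell_distribution <- function(species, grids) {
  stopifnot(is.data.frame(species), nrow(species) == 1)
  land <- landscape_values(grids)
  w <- exp(-(land$pdq - species$mu_pdq)^2 / (2 * species$sigma_pdq^2)
           - (land$mtcm - species$mu_mtcm)^2 / (2 * species$sigma_mtcm^2))
  if (sum(w) == 0) stop("total suitability is zero", call. = FALSE)
  data.frame(pdq = land$pdq, mtcm = land$mtcm, prob = w / sum(w))
}

#' Write a synthetic study fixture to disk
#'
#' Materialises a full synthetic study: the two climate rasters as ESRI
#' ASCII grids, the pooled occurrence table as CSV (Darwin-Core-style
#' columns), and a JSON manifest of the true niche parameters for recovery
#' tests.
#'
#' @param config a [surface_config].
#' @param out_dir output directory (created if needed).
#' @param n_species,n_planted_drought,n_planted_cold,n_occurrences passed to
#'   [gen_species_pool].
#' @param seed integer seed for pool and occurrences.
#' @return invisibly, a list with the generated `grids`, `pool`, `records`
#'   and the written file paths.
#' @export
simulate_study <- function(config = surface_config(), out_dir,
                           n_species = 35, n_planted_drought = 9,
                           n_planted_cold = 9, n_occurrences = 30,
                           seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- list(pdq = gen_climate_grid(config, "PDQ"),
                mtcm = gen_climate_grid(config, "MTCM"))
  pool <- gen_species_pool(n_species, n_planted_drought, n_planted_cold,
                           grids, seed = seed, n_occurrences = n_occurrences)
  records <- gen_occurrences(pool, grids, seed = seed)
  paths <- list(pdq = file.path(out_dir, "pdq.asc"),
                mtcm = file.path(out_dir, "mtcm.asc"),
                occurrences = file.path(out_dir, "occurrences.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_ascii_grid(grids$pdq, paths$pdq)
  write_ascii_grid(grids$mtcm, paths$mtcm)
  write_occurrences(records, paths$occurrences)
  jsonlite::write_json(
    list(seed = seed, n_species = n_species, species = pool),
    paths$manifest, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(grids = grids, pool = pool, records = records, paths = paths))
}
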