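# Orchestration: configuration, the full screening run, and report/output
# writing. Defaults reproduce the study settings (0.1 degree thinning, >= 10
# specimens, 10/20/50 km Moran lags, 25th-percentile reference threshold
# with 5-35th sensitivity scenarios, >= 5-of-7 core rule, 5 clusters).

#' Build a run configuration
#'
#' All defaults equal the study settings, so an empty override reproduces
#' the standard procedure on any input.
#'
#' @param occurrences path to the occurrence CSV/TSV.
#' @param pdq_raster,mtcm_raster paths to the PDQ and MTCM ESRI ASCII grids.
#' @param column_map named vector mapping `species`, `lat`, `lon` to source
#'   column names.
#' @param delim occurrence-table field delimiter.
#' @param cell_deg thinning grid cell in degrees (default 0.1).
#' @param min_specimens minimum records per species after linking
#'   (default 10).
#' @param moran_lags_km Moran's I lag distances (default 10, 20, 50 km).
#' @param reference_percentile reference threshold percentile (default 0.25).
#' @param sensitivity_percentiles additional scenarios (default 0.05-0.35
#'   by 0.05 minus the reference).
#' @param core_min core-candidate rule: tolerant in at least this many
#'   scenarios (default 5 of the 7).
#' @param cluster_k number of clusters (default 5).
#' @param standardize z-score axes before clustering (default TRUE).
#' @param quantile_type quantile rule (default 7, linear interpolation).
#' @param seed master seed driving all stochastic stages (default 1).
#' @param out_dir optional output directory; when set, [run_pipeline]
#'   writes the CSV/JSON artefacts there.
#' @return list of class `run_config`.
#' @export
screen_config <- function(occurrences, pdq_raster, mtcm_raster,
                          column_map = c(species = "species",
                                         lat = "decimalLatitude",
                                         lon = "decimalLongitude"),
                          delim = ",",
                          cell_deg = 0.1, min_specimens = 10,
                          moran_lags_km = c(10, 20, 50),
                          reference_percentile = 0.25,
                          sensitivity_percentiles = c(0.05, 0.10, 0.15,
                                                      0.20, 0.30, 0.35),
                          core_min = 5, cluster_k = 5, standardize = TRUE,
                          quantile_type = 7, seed = 1L, out_dir = NULL) {
  cfg <- list(occurrences = occurrences, pdq_raster = pdq_raster,
              mtcm_raster = mtcm_raster, column_map = column_map,
              delim = delim, cell_deg = cell_deg,
              min_specimens = min_specimens, moran_lags_km = moran_lags_km,
              reference_percentile = reference_percentile,
              sensitivity_percentiles = sensitivity_percentiles,
              core_min = core_min, cluster_k = cluster_k,
              standardize = standardize, quantile_type = quantile_type,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat key-value file
#'
#' The file is in DCF format (R's native flat `Key: value` text format),
#' e.g. `occurrences: occ.csv`. Vector fields are comma-separated. Any key
#' not present keeps its [screen_config] default.
#'
#' @param path config file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- as.list(read.dcf(path)[1, ])
  num_vec <- function(x) as.numeric(strsplit(x, ",")[[1]])
  args <- list()
  for (key in names(raw)) {
    val <- trimws(raw[[key]])
    args[[key]] <- switch(key,
      occurrences = , pdq_raster = , mtcm_raster = , delim = ,
      out_dir = val,
      column_map = {
        parts <- strsplit(strsplit(val, ",")[[1]], "=")
        stats::setNames(trimws(vapply(parts, `[`, "", 2)),
                        trimws(vapply(parts, `[`, "", 1)))
      },
      moran_lags_km = , sensitivity_percentiles = num_vec(val),
      standardize = as.logical(val),
      seed = , min_specimens = , core_min = , cluster_k = ,
      quantile_type = as.integer(val),
      as.numeric(val))
  }
  do.call(screen_config, args)
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes read -> clean -> thin -> extract/link -> minimum-specimen
#' filter -> Moran QC -> Shapiro-Wilk + Kruskal-Wallis + linear R^2 ->
#' profiles -> clustering -> thresholds -> classification -> sensitivity ->
#' Mann-Whitney validation, and returns (and optionally writes) the full
#' report. The run is reproducible bit-for-bit given the config and seed.
#'
#' Record conservation holds at every stage: the tallies satisfy
#' `input = output + dropped`. The pooled Shapiro-Wilk test is limited to
#' 5000 values; larger pools are subsampled reproducibly (noted in the
#' report).
#'
#' @param config a `run_config` from [screen_config] or [read_run_config].
#' @return list of class `run_report`: `tallies`, `tests`, `moran`,
#'   `profiles`, `clusters`, `thresholds`, `screening`, `validation`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (field in c("occurrences", "pdq_raster", "mtcm_raster")) {
    if (is.null(config[[field]]) || !file.exists(config[[field]])) {
      stop(sprintf("configuration error: '%s' missing or not a file (%s)",
                   field, config[[field]]), call. = FALSE)
    }
  }

  occ <- stage("read_occurrences",
               read_occurrences(config$occurrences, config$column_map,
                                delim = config$delim))
  thinned <- stage("thin_to_grid",
                   thin_to_grid(occ$records, config$cell_deg, config$seed))
  pdq_grid <- stage("read_pdq_raster",
                    read_ascii_grid(config$pdq_raster, "PDQ"))
  mtcm_grid <- stage("read_mtcm_raster",
                     read_ascii_grid(config$mtcm_raster, "MTCM"))
  linked <- stage("link_climate", link_climate(thinned, pdq_grid, mtcm_grid))
  filtered <- stage("filter_min_specimens",
                    filter_min_specimens(linked$data, config$min_specimens))
  specimens <- filtered$kept
  if (nrow(specimens) == 0L) {
    stop("stage 'filter_min_specimens' failed: no species passes the minimum-specimen filter",
         call. = FALSE)
  }

  tallies <- list(
    rows_read = nrow(occ$records) + occ$dropped,
    invalid_dropped = occ$dropped,
    thinned_away = nrow(occ$records) - nrow(thinned),
    climate_dropped = linked$n_dropped,
    below_min_n = nrow(linked$data) - nrow(specimens),
    specimens_retained = nrow(specimens),
    species_retained = length(unique(specimens$species)),
    species_excluded = nrow(filtered$excluded))

  moran <- stage("moran_qc", moran_qc(specimens, config$moran_lags_km))

  sw_note <- ""
  sw_pool <- function(x) {
    if (length(x) > 5000L) {
      sw_note <<- "pooled sample subsampled to 5000 for Shapiro-Wilk"
      withr::with_seed(derive_seed(config$seed, "shapiro"),
                       x <- sample(x, 5000L))
    }
    shapiro_wilk(x)
  }
  groups_pdq <- split(specimens$pdq_mm, specimens$species)
  groups_mtcm <- split(specimens$mtcm_c, specimens$species)
  tests <- stage("stats", list(
    shapiro_pdq = sw_pool(specimens$pdq_mm),
    shapiro_mtcm = sw_pool(specimens$mtcm_c),
    kruskal_pdq = kruskal_wallis(groups_pdq),
    kruskal_mtcm = kruskal_wallis(groups_mtcm),
    linear_fit = linear_fit_r2(specimens$pdq_mm, specimens$mtcm_c),
    shapiro_note = sw_note))

  profiles <- stage("build_profiles", build_profiles(specimens))
  clusters <- stage("cluster_species",
                    cluster_species(profiles, k = min(config$cluster_k,
                                                      nrow(profiles)),
                                    standardize = config$standardize))

  all_pct <- sort(unique(c(config$reference_percentile,
                           config$sensitivity_percentiles)))
  thresholds <- stage("derive_thresholds",
                      lapply(all_pct, derive_thresholds, profiles = profiles))
  screening <- stage("sensitivity_analysis",
                     sensitivity_analysis(profiles, percentiles = all_pct,
                                          reference = config$reference_percentile,
                                          core_min = config$core_min))
  ref_scenario <- thresholds[[which(all_pct == config$reference_percentile)]]
  ref_cls <- classify_species(profiles, ref_scenario)
  validation <- stage("validate_separation", list(
    drought = if (nrow(ref_cls$drought) > 0 &&
                  nrow(ref_cls$drought) < nrow(profiles))
      validate_separation(specimens, ref_cls$drought$species, "drought") else NULL,
    cold = if (nrow(ref_cls$cold) > 0 &&
               nrow(ref_cls$cold) < nrow(profiles))
      validate_separation(specimens, ref_cls$cold$species, "cold") else NULL))

  report <- structure(list(
    tallies = tallies, tests = tests, moran = moran,
    specimens = specimens, profiles = profiles, clusters = clusters,
    thresholds = thresholds, classification = ref_cls,
    screening = screening, validation = validation,
    config = config,
    fingerprint = list(package = "climscreen",
                       version = as.character(utils::packageVersion("climscreen")),
                       r_version = as.character(getRversion()),
                       seed = config$seed)),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the pipeline report artefacts
#'
#' Writes the linked specimen table, profiles with cluster labels, Newick
#' dendrogram, per-scenario thresholds, screening summary, Moran QC table,
#' and a JSON run report into `out_dir`.
#'
#' @param report a `run_report` from [run_pipeline].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(linked = file.path(out_dir, "occurrences.linked.csv"),
         profiles = file.path(out_dir, "profiles.csv"),
         clusters = file.path(out_dir, "clusters.csv"),
         dendrogram = file.path(out_dir, "dendrogram.nwk"),
         thresholds = file.path(out_dir, "thresholds.csv"),
         screening = file.path(out_dir, "screening.csv"),
         moran = file.path(out_dir, "moran_qc.csv"),
         report = file.path(out_dir, "report.json"))
  utils::write.csv(report$specimens, p[["linked"]], row.names = FALSE)
  prof <- report$profiles
  prof$cluster <- report$clusters$assignment[prof$species]
  utils::write.csv(prof, p[["profiles"]], row.names = FALSE)
  utils::write.csv(data.frame(species = names(report$clusters$assignment),
                              cluster = unname(report$clusters$assignment)),
                   p[["clusters"]], row.names = FALSE)
  cluster_newick(report$clusters, p[["dendrogram"]])
  thr <- do.call(rbind, lapply(report$thresholds, function(s) {
    data.frame(percentile = s$percentile, pdq_threshold_mm = s$pdq_threshold,
               mtcm_threshold_c = s$mtcm_threshold)
  }))
  utils::write.csv(thr, p[["thresholds"]], row.names = FALSE)
  utils::write.csv(report$screening, p[["screening"]], row.names = FALSE)
  utils::write.csv(report$moran, p[["moran"]], row.names = FALSE)
  tst <- lapply(report$tests, function(t) {
    if (inherits(t, "envelope_test")) unclass(t) else t
  })
  val <- lapply(report$validation, function(t) {
    if (inherits(t, "envelope_test")) unclass(t) else t
  })
  jsonlite::write_json(
    list(tallies = report$tallies, tests = tst, validation = val,
         thresholds = thr, fingerprint = report$fingerprint),
    p[["report"]], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(p)
}

#' @export
print.run_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("climscreen run: %d specimens of %d species retained\n",
              t$specimens_retained, t$species_retained))
  cat(sprintf("  read %d rows; dropped %d invalid, %d thinned, %d without climate, %d below min-n\n",
              t$rows_read, t$invalid_dropped, t$thinned_away,
              t$climate_dropped, t$below_min_n))
  ref <- x$thresholds[[which(vapply(x$thresholds, `[[`, 0, "percentile") ==
                               x$config$reference_percentile)]]
  cat(sprintf("  reference thresholds (p%g): PDQ < %.3f mm, MTCM < %.3f degC\n",
              100 * ref$percentile, ref$pdq_threshold, ref$mtcm_threshold))
  cat(sprintf("  candidates: %d drought-tolerant, %d cold-tolerant; %d clusters\n",
              nrow(x$classification$drought), nrow(x$classification$cold),
              x$clusters$k))
  invisible(x)
}
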