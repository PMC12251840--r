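# Percentile-threshold tolerance classification, multi-percentile
# sensitivity/consistency analysis, and Mann-Whitney validation of the
# separation between tolerant and nontolerant species.

#' Derive tolerance thresholds from species profiles
#'
#' Thresholds are the given percentile of the species-level median values
#' — one threshold per variable — computed with the linear-interpolation
#' quantile rule of [climate_quantile]. "Across all species" is read as
#' across the species-level indicator values, not the pooled specimens;
#' pooled-specimen thresholds can be computed by passing a pooled table
#' through the same quantile explicitly.
#'
#' @param profiles output of [build_profiles] (>= 2 species).
#' @param percentile fraction in `[0, 1]` (default 0.25, the reference
#'   scenario).
#' @return list of class `threshold_scenario`: `percentile`,
#'   `pdq_threshold` (mm), `mtcm_threshold` (degrees C).
#' @export
derive_thresholds <- function(profiles, percentile = 0.25) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) < 2L) stop("need at least 2 species profiles", call. = FALSE)
  assert_number(percentile, "percentile", 0, 1)
  structure(list(percentile = percentile,
                 pdq_threshold = climate_quantile(profiles$median_pdq, percentile),
                 mtcm_threshold = climate_quantile(profiles$median_mtcm, percentile)),
            class = "threshold_scenario")
}

#' Classify and rank candidate tolerant species
#'
#' A species is drought-tolerant iff its median PDQ is strictly below the
#' PDQ threshold, and cold-tolerant iff its median MTCM is strictly below
#' the MTCM threshold; a median exactly at the threshold is nontolerant.
#' Each candidate list is ranked strongest to weakest by ascending median
#' (drier/colder = stronger), ties broken by species label.
#'
#' @param profiles output of [build_profiles].
#' @param scenario a `threshold_scenario` from [derive_thresholds].
#' @return list with `drought` and `cold` data frames
#'   (`species`, `median`, `rank`).
#' @export
classify_species <- function(profiles, scenario) {
  stopifnot(is.data.frame(profiles), inherits(scenario, "threshold_scenario"))
  rank_list <- function(medians, threshold) {
    sel <- which(medians < threshold)
    df <- data.frame(species = profiles$species[sel],
                     median = medians[sel], stringsAsFactors = FALSE)
    df <- df[order(df$median, df$species), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  }
  list(drought = rank_list(profiles$median_pdq, scenario$pdq_threshold),
       cold = rank_list(profiles$median_mtcm, scenario$mtcm_threshold))
}

#' Multi-percentile sensitivity and consistency analysis
#'
#' Repeats threshold derivation and classification at each percentile and
#' summarises, per species and variable, the set of scenarios in which the
#' species is tolerant, the consistency score (how many of the scenarios),
#' and the core flag (score at least `core_min` of the scenarios, default
#' 5 of the 7). The rank is reported at the reference percentile only and
#' is `NA` for species not tolerant there.
#'
#' Because the tolerant set at a lower percentile is nested inside the set
#' at a higher percentile, the consistency score equals the number of
#' scenarios from the species' first qualifying percentile upward.
#'
#' @param profiles output of [build_profiles].
#' @param percentiles distinct fractions; default the study scenarios
#'   `c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35)`.
#' @param reference reference percentile, must be among `percentiles`
#'   (default 0.25).
#' @param core_min minimum consistency score for the core flag (default 5).
#' @return data frame: `species`, `variable` (`"drought"`/`"cold"`),
#'   `tolerant_at` (comma-joined percentiles), `consistency_score`,
#'   `core`, `rank`.
#' @export
sensitivity_analysis <- function(profiles,
                                 percentiles = c(0.05, 0.10, 0.15, 0.20,
                                                 0.25, 0.30, 0.35),
                                 reference = 0.25, core_min = 5) {
  if (length(percentiles) == 0L) stop("empty percentile list", call. = FALSE)
  if (anyDuplicated(percentiles)) stop("duplicate percentiles", call. = FALSE)
  if (!reference %in% percentiles) {
    stop("reference percentile must be among the scenarios", call. = FALSE)
  }
  percentiles <- sort(percentiles)
  scenarios <- lapply(percentiles, derive_thresholds, profiles = profiles)
  cls <- lapply(scenarios, classify_species, profiles = profiles)
  ref_cls <- cls[[which(percentiles == reference)]]
  rows <- list()
  for (variable in c("drought", "cold")) {
    tol_sets <- lapply(cls, function(cl) cl[[variable]]$species)
    ref_tab <- ref_cls[[variable]]
    for (sp in profiles$species) {
      at <- percentiles[vapply(tol_sets, function(s) sp %in% s, logical(1))]
      score <- length(at)
      rk <- if (sp %in% ref_tab$species) ref_tab$rank[ref_tab$species == sp] else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = variable,
        tolerant_at = paste(at, collapse = ","),
        consistency_score = score,
        core = score >= core_min,
        rank = rk, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate tolerant/nontolerant separation with the Mann-Whitney U test
#'
#' Compares specimen-level values of the relevant variable between the
#' specimens of the tolerant species and all other specimens, delegating to
#' [mann_whitney_u].
#'
#' @param specimens data frame with columns `species`, `pdq_mm`, `mtcm_c`.
#' @param tolerant character vector of tolerant species labels.
#' @param variable `"drought"` (compares PDQ) or `"cold"` (compares MTCM).
#' @return an `envelope_test` (see [mann_whitney_u]).
#' @export
validate_separation <- function(specimens, tolerant,
                                variable = c("drought", "cold")) {
  variable <- match.arg(variable)
  stopifnot(is.data.frame(specimens),
            all(c("species", "pdq_mm", "mtcm_c") %in% names(specimens)))
  vals <- if (variable == "drought") specimens$pdq_mm else specimens$mtcm_c
  in_tol <- specimens$species %in% tolerant
  if (!any(in_tol) || all(in_tol)) {
    stop("both tolerant and nontolerant groups must be non-empty",
         call. = FALSE)
  }
  mann_whitney_u(vals[in_tol], vals[!in_tol])
}
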