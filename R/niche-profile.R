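# Per-species climate profiles (medians, extrema, niche widths) and
# hierarchical clustering of species in median-climate space.

#' Build per-species climate profiles
#'
#' Aggregates specimen-level PDQ/MTCM values into one row per species: the
#' record count, the median of each variable (mid-rank median for even n),
#' the extrema, and the niche width computed as the range
#' (maximum - minimum) of each variable across the species' records.
#'
#' @param specimens data frame with columns `species`, `pdq_mm`, `mtcm_c`
#'   (the output of [link_climate]).
#' @return data frame sorted by species label: `species`, `n`,
#'   `median_pdq`, `median_mtcm`, `min_pdq`, `max_pdq`, `min_mtcm`,
#'   `max_mtcm`, `niche_width_pdq`, `niche_width_mtcm`.
#' @export
build_profiles <- function(specimens) {
  stopifnot(is.data.frame(specimens),
            all(c("species", "pdq_mm", "mtcm_c") %in% names(specimens)))
  if (nrow(specimens) == 0L) stop("no specimens", call. = FALSE)
  sp <- sort(unique(specimens$species))
  prof <- lapply(sp, function(s) {
    sub <- specimens[specimens$species == s, ]
    data.frame(species = s, n = nrow(sub),
               median_pdq = stats::median(sub$pdq_mm),
               median_mtcm = stats::median(sub$mtcm_c),
               min_pdq = min(sub$pdq_mm), max_pdq = max(sub$pdq_mm),
               min_mtcm = min(sub$mtcm_c), max_mtcm = max(sub$mtcm_c),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, prof)
  out$niche_width_pdq <- out$max_pdq - out$min_pdq
  out$niche_width_mtcm <- out$max_mtcm - out$min_mtcm
  rownames(out) <- NULL
  out
}

#' Cluster species in median-climate space
#'
#' Agglomerative hierarchical clustering of species on
#' `(median_pdq, median_mtcm)` using squared Euclidean distance, cut into
#' `k` clusters. With `standardize = TRUE` (default) both axes are z-scored
#' before distances, since millimetres and degrees Celsius are
#' incommensurable; raw-scale clustering can differ and is available with
#' `standardize = FALSE`. Default linkage is between-groups average; Ward
#' is available. Profiles are sorted by species label before clustering so
#' the result does not depend on input order; remaining ties at equal merge
#' heights are resolved by that label order.
#'
#' @param profiles output of [build_profiles] (or any data frame with
#'   `species`, `median_pdq`, `median_mtcm`).
#' @param k number of clusters, `1 <= k <=` number of species.
#' @param standardize z-score the two axes before computing distances?
#' @param linkage `"average"` (default) or `"ward"`.
#' @return list of class `cluster_result`: `k`, `assignment` (named
#'   integer vector, species -> cluster), `hclust` (the merge history with
#'   heights), `standardize`, `linkage`.
#' @export
cluster_species <- function(profiles, k = 5, standardize = TRUE,
                            linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.data.frame(profiles),
            all(c("species", "median_pdq", "median_mtcm") %in% names(profiles)))
  n <- nrow(profiles)
  if (k < 1 || k > n) stop("k must be between 1 and the number of species",
                           call. = FALSE)
  if (any(!is.finite(profiles$median_pdq)) ||
      any(!is.finite(profiles$median_mtcm))) {
    stop("non-finite medians", call. = FALSE)
  }
  profiles <- profiles[order(profiles$species), , drop = FALSE]
  x <- cbind(pdq = profiles$median_pdq, mtcm = profiles$median_mtcm)
  rownames(x) <- profiles$species
  if (standardize) {
    x <- apply(x, 2L, function(col) {
      s <- stats::sd(col)
      if (s == 0) col - mean(col) else (col - mean(col)) / s
    })
    rownames(x) <- profiles$species
  }
  d2 <- stats::dist(x)^2
  hc <- stats::hclust(d2, method = if (linkage == "ward") "ward.D" else "average")
  assignment <- stats::cutree(hc, k = k)
  structure(list(k = k, assignment = assignment, hclust = hc,
                 standardize = standardize, linkage = linkage),
            class = "cluster_result")
}

#' Export a clustering merge history as a Newick dendrogram
#'
#' @param clusters a `cluster_result` from [cluster_species].
#' @param path optional output file; when omitted the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to file).
#' @export
cluster_newick <- function(clusters, path = NULL) {
  stopifnot(inherits(clusters, "cluster_result"))
  phy <- ape::as.phylo(clusters$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
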