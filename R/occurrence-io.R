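# Reading, validating and writing occurrence record tables
# (Darwin-Core-style CSV/TSV).

#' Default Darwin-Core-style column mapping
#' @noRd
default_column_map <- function() {
  c(species = "species", lat = "decimalLatitude", lon = "decimalLongitude")
}

#' Read and clean an occurrence table
#'
#' Reads a delimited text file (RFC-4180 CSV by default; GBIF exports are
#' tab-separated, set `delim = "\t"`), maps the species/latitude/longitude
#' columns, and drops rows with a blank species label or a missing,
#' unparseable or out-of-range coordinate. Row order is preserved.
#' Coordinates exactly (0, 0) are valid by default; `drop_zero_zero = TRUE`
#' enables a strict mode that drops them.
#'
#' Exact duplicate records survive reading; downstream grid thinning
#' resolves them.
#'
#' @param path input file.
#' @param column_map named character vector with entries `species`, `lat`,
#'   `lon` giving the source column names.
#' @param delim field delimiter.
#' @param drop_zero_zero drop records at exactly (0, 0)?
#' @return list with `records` (data frame: `species`, `lat`, `lon`) and
#'   `dropped` (count of removed data rows).
#' @export
read_occurrences <- function(path, column_map = default_column_map(),
                             delim = ",", drop_zero_zero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(all(c("species", "lat", "lon") %in% names(column_map)))
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  absent <- setdiff(unname(column_map[c("species", "lat", "lon")]), names(raw))
  if (length(absent) > 0L) {
    stop("mapped columns absent from header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(list(records = data.frame(species = character(), lat = numeric(),
                                     lon = numeric(), stringsAsFactors = FALSE),
                dropped = 0L))
  }
  species <- trimws(raw[[column_map[["species"]]]])
  lat <- suppressWarnings(as.numeric(raw[[column_map[["lat"]]]]))
  lon <- suppressWarnings(as.numeric(raw[[column_map[["lon"]]]]))
  ok <- nzchar(species) & !is.na(species) &
    is.finite(lat) & is.finite(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  ok[is.na(ok)] <- FALSE
  if (drop_zero_zero) ok <- ok & !(lat == 0 & lon == 0)
  records <- data.frame(species = species[ok], lat = lat[ok], lon = lon[ok],
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, dropped = sum(!ok))
}

#' Write an occurrence table
#'
#' Writes Darwin-Core-style columns (`species`, `decimalLatitude`,
#' `decimalLongitude`) at full double precision, so that
#' `read_occurrences()` round-trips the records exactly.
#'
#' @param records data frame with columns `species`, `lat`, `lon`.
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path, delim = ",") {
  stopifnot(is.data.frame(records),
            all(c("species", "lat", "lon") %in% names(records)))
  header <- paste(c("species", "decimalLatitude", "decimalLongitude"),
                  collapse = delim)
  lines <- paste(records$species, format_full(records$lat),
                 format_full(records$lon), sep = delim)
  writeLines(c(header, lines), path)
  invisible(path)
}
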