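# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Each stochastic stage (thinning, each synthetic surface, each virtual
#' species) draws from its own derived stream so that changing one stage's
#' behaviour does not perturb another's draws. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream.
#' @return an integer seed.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483587
  as.integer((h + abs(as.numeric(seed)) * 7919 + 1) %% 2147483399)
}

#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

#' @noRd
validate_coords <- function(lat, lon) {
  if (length(lat) != length(lon)) stop("lat and lon lengths differ", call. = FALSE)
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(NULL)
}

# Format doubles so that write -> read round-trips exactly.
#' @noRd
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
  out
}
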