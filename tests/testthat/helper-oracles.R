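# Independent brute-force oracles used against the implementation. These
# re-derive each statistic from first principles (enumeration or the bare
# formula) and never call the package's own code paths.

# Exact Mann-Whitney U and two-sided p by enumerating every assignment of
# the pooled ranks to the first sample (valid for small pooled N).
oracle_mann_whitney <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p, null_us = us)
}

# Kruskal-Wallis H from the bare mid-rank formula with tie correction.
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_total <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  g <- rep(seq_along(groups), sizes)
  h <- 12 / (n_total * (n_total + 1)) *
    sum(tapply(r, g, sum)^2 / sizes) - 3 * (n_total + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n_total^3 - n_total))
}

# Exhaustive permutation distribution of H: every assignment of the pooled
# observations to groups of the given sizes.
oracle_kruskal_permutation <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  n_total <- length(x)
  split_h <- function(remaining_idx, sizes) {
    if (length(sizes) == 1L) {
      return(list(list(remaining_idx)))
    }
    out <- list()
    for (first in utils::combn(length(remaining_idx), sizes[1],
                               simplify = FALSE)) {
      rest <- split_h(remaining_idx[-first], sizes[-1])
      for (r in rest) {
        out[[length(out) + 1L]] <- c(list(remaining_idx[first]), r)
      }
    }
    out
  }
  assignments <- split_h(seq_len(n_total), sizes)
  vapply(assignments,
         function(a) oracle_kruskal_h(lapply(a, function(i) x[i])),
         numeric(1))
}

# Moran's I by literal evaluation of the double sum (no matrix algebra).
oracle_moran_double_sum <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * z[i] * z[j]
    }
  }
  (n / sum(w)) * num / sum(z^2)
}

# Linear-interpolation quantile from its definition h = (n - 1) q.
oracle_quantile <- function(values, q) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# All partitions of n items into exactly k non-empty unlabeled groups
# (restricted growth strings), as assignment vectors.
oracle_all_partitions <- function(n, k) {
  out <- list()
  recurse <- function(assign, used) {
    i <- length(assign) + 1L
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    # pruning: remaining slots must still allow reaching k groups
    if (used + (n - i + 1L) < k) return(invisible(NULL))
    for (g in seq_len(min(used + 1L, k))) {
      recurse(c(assign, g), max(used, g))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Total within-group sum of squared distances to group centroids.
partition_within_ss <- function(x, assign) {
  sum(vapply(unique(assign), function(g) {
    sub <- x[assign == g, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2L, ctr)^2)
  }, numeric(1)))
}

# Canonical form of a partition, for label-free comparison.
canonical_partition <- function(assign) {
  match(assign, unique(assign))
}

# Small deterministic toy landscape: a single row of cells with prescribed
# values, shared extent for both variables.
toy_grids <- function(pdq_vals, mtcm_vals, cell = 0.5, y_ll = 0, x_ll = 0) {
  list(
    pdq = climate_grid(matrix(pdq_vals, nrow = 1), x_ll, y_ll, cell, "PDQ"),
    mtcm = climate_grid(matrix(mtcm_vals, nrow = 1), x_ll, y_ll, cell, "MTCM"))
}

# One-row virtual-species table for generator tests.
toy_species <- function(mu_pdq, mu_mtcm, sigma_pdq = 5, sigma_mtcm = 1,
                        n = 10, name = "sp_toy") {
  data.frame(name = name, mu_pdq = mu_pdq, mu_mtcm = mu_mtcm,
             sigma_pdq = sigma_pdq, sigma_mtcm = sigma_mtcm,
             planted_drought = FALSE, planted_cold = FALSE,
             n_occurrences = as.integer(n), stringsAsFactors = FALSE)
}

# Shared small landscape for pipeline-level tests (coarse, fast).
test_surface <- function(seed = 11, nodata_fraction = 0.02) {
  surface_config(lat_min = 24, lat_max = 32, lon_min = 102, lon_max = 112,
                 cell_size = 0.25, nodata_fraction = nodata_fraction,
                 seed = seed)
}

test_grid_pair <- function(config = test_surface()) {
  list(pdq = gen_climate_grid(config, "PDQ"),
       mtcm = gen_climate_grid(config, "MTCM"))
}
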