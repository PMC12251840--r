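# Virtual climate surfaces and virtual species occurrence generation.

test_that("grid generation is deterministic and honours the exact no-noise formula", {
  cfg <- test_surface(seed = 3)
  expect_identical(gen_climate_grid(cfg, "PDQ"), gen_climate_grid(cfg, "PDQ"))
  expect_identical(gen_climate_grid(cfg, "MTCM"), gen_climate_grid(cfg, "MTCM"))
  # PDQ and MTCM use distinct noise streams
  expect_false(identical(gen_climate_grid(cfg, "PDQ")$values,
                         gen_climate_grid(cfg, "MTCM")$values))

  flat <- surface_config(lat_min = 20, lat_max = 22, lon_min = 100,
                         lon_max = 101, cell_size = 0.5,
                         pdq = list(base = 300, gradient = -7.5,
                                    noise_amplitude = 0),
                         nodata_fraction = 0, seed = 1)
  g <- gen_climate_grid(flat, "PDQ")
  lat_centers <- 20 + (g$n_rows - seq_len(g$n_rows) + 0.5) * 0.5
  for (r in seq_len(g$n_rows)) {
    expect_equal(g$values[r, ], rep(300 - 7.5 * lat_centers[r], g$n_cols))
  }
  expect_equal(sum(is.na(g$values)), 0) # nodata_fraction 0 -> no nodata
})

test_that("nodata fraction and config validation behave as declared", {
  cfg <- surface_config(nodata_fraction = 0.1, seed = 2)
  g <- gen_climate_grid(cfg, "PDQ")
  expect_equal(sum(is.na(g$values)), floor(0.1 * g$n_rows * g$n_cols))
  expect_error(surface_config(lat_min = 30, lat_max = 30), "degenerate")
  expect_error(surface_config(cell_size = -1), "> 0")
  expect_error(surface_config(nodata_fraction = 1.5), "\\[0, 1\\]")
})

test_that("the species pool plants exactly the requested counts strictly below landscape Q25", {
  grids <- test_grid_pair(test_surface(seed = 5))
  land_pdq <- grids$pdq$values[!is.na(grids$pdq$values) & !is.na(grids$mtcm$values)]
  land_mtcm <- grids$mtcm$values[!is.na(grids$pdq$values) & !is.na(grids$mtcm$values)]
  q25_pdq <- stats::quantile(land_pdq, 0.25, names = FALSE)
  q25_mtcm <- stats::quantile(land_mtcm, 0.25, names = FALSE)

  pool <- gen_species_pool(35, 9, 9, grids, seed = 11)
  expect_equal(nrow(pool), 35)
  expect_equal(sum(pool$planted_drought), 9)
  expect_equal(sum(pool$planted_cold), 9)
  expect_true(all(pool$mu_pdq[pool$planted_drought] < q25_pdq))
  expect_true(all(pool$mu_mtcm[pool$planted_cold] < q25_mtcm))
  # non-planted centres sit in the interquartile range
  expect_true(all(pool$mu_pdq[!pool$planted_drought] >= q25_pdq))
  expect_true(all(pool$mu_pdq[!pool$planted_drought] <=
                    stats::quantile(land_pdq, 0.75, names = FALSE)))

  none <- gen_species_pool(10, 0, 0, grids, seed = 11)
  expect_false(any(none$planted_drought) || any(none$planted_cold))
  expect_identical(gen_species_pool(35, 9, 9, grids, seed = 11), pool)
  expect_error(gen_species_pool(5, 6, 0, grids, seed = 1), "exceed pool size")
})

test_that("occurrences fall on valid cells inside the extent with the requested count", {
  cfg <- test_surface(seed = 7)
  grids <- test_grid_pair(cfg)
  pool <- gen_species_pool(3, 1, 1, grids, seed = 2, n_occurrences = 30)
  occ <- gen_occurrences(pool, grids, seed = 2)
  expect_equal(nrow(occ), 90)
  expect_equal(as.integer(table(occ$species)), rep(30L, 3))
  expect_true(all(occ$lat > cfg$lat_min & occ$lat < cfg$lat_max))
  expect_true(all(occ$lon > cfg$lon_min & occ$lon < cfg$lon_max))
  linked <- link_climate(occ, grids$pdq, grids$mtcm)
  expect_equal(linked$n_dropped, 0) # never lands on a nodata cell
  expect_identical(gen_occurrences(pool, grids, seed = 2), occ)
})

test_that("a near-degenerate niche with one matching cell places all points in that cell", {
  grids <- toy_grids(pdq_vals = c(100, 100, 40, 100, 100),
                     mtcm_vals = c(5, 5, 5, 5, 5))
  sp <- toy_species(mu_pdq = 40, mu_mtcm = 5, sigma_pdq = 1e-4,
                    sigma_mtcm = 10, n = 25)
  occ <- gen_occurrences(sp, grids, seed = 9)
  # cell 3 spans lon [1.0, 1.5)
  expect_true(all(occ$lon >= 1.0 & occ$lon < 1.5))
  far <- toy_species(mu_pdq = 1e6, mu_mtcm = 5, sigma_pdq = 1e-3,
                     sigma_mtcm = 1e-3)
  expect_error(gen_occurrences(far, grids, seed = 1), "suitability is zero")
})

test_that("sampled climate matches the exact suitability-weighted cell distribution", {
  grids <- toy_grids(pdq_vals = c(30, 50, 70, 90, 110),
                     mtcm_vals = c(0, 1, 2, 3, 4))
  sp <- toy_species(mu_pdq = 55, mu_mtcm = 1.5, sigma_pdq = 20,
                    sigma_mtcm = 2, n = 10000)
  dist <- occurrence_cell_distribution(sp, grids)
  expect_equal(sum(dist$prob), 1)
  mu_exact <- sum(dist$prob * dist$pdq)
  sd_exact <- sqrt(sum(dist$prob * dist$pdq^2) - mu_exact^2)

  occ <- gen_occurrences(sp, grids, seed = 77)
  pdq_at <- extract_at_points(grids$pdq, occ$lat, occ$lon)
  expect_lt(abs(mean(pdq_at) - mu_exact), 4 * sd_exact / sqrt(10000))

  # chi-squared goodness of fit of cell counts against the exact mixture
  counts <- table(factor(pdq_at, levels = dist$pdq))
  gof <- stats::chisq.test(as.integer(counts), p = dist$prob)
  expect_gt(gof$p.value, 0.01)
})

test_that("planted species have lower median extracted climate across replicate pools", {
  grids <- test_grid_pair(test_surface(seed = 19))
  diff_pdq <- diff_mtcm <- numeric(20)
  for (i in 1:20) {
    pool <- gen_species_pool(12, 4, 4, grids, seed = 500 + i,
                             n_occurrences = 15)
    occ <- gen_occurrences(pool, grids, seed = 500 + i)
    linked <- link_climate(occ, grids$pdq, grids$mtcm)$data
    prof <- build_profiles(linked)
    prof <- prof[match(pool$name, prof$species), ]
    diff_pdq[i] <- mean(prof$median_pdq[pool$planted_drought]) -
      mean(prof$median_pdq[!pool$planted_drought])
    diff_mtcm[i] <- mean(prof$median_mtcm[pool$planted_cold]) -
      mean(prof$median_mtcm[!pool$planted_cold])
  }
  expect_lt(mean(diff_pdq), 0)
  expect_lt(mean(diff_mtcm), 0)
  expect_gt(mean(diff_pdq < 0), 0.9)
  expect_gt(mean(diff_mtcm < 0), 0.9)
})

test_that("simulate_study writes rasters, occurrences and a manifest that round-trip", {
  out_dir <- withr::local_tempdir()
  sim <- simulate_study(test_surface(seed = 23), out_dir, n_species = 5,
                        n_planted_drought = 2, n_planted_cold = 1,
                        n_occurrences = 12, seed = 4)
  expect_true(all(file.exists(unlist(sim$paths))))
  back <- read_occurrences(sim$paths$occurrences)
  expect_equal(nrow(back$records), nrow(sim$records))
  expect_identical(back$records$lat, sim$records$lat)
  g <- read_ascii_grid(sim$paths$pdq, "PDQ")
  expect_identical(g$values, sim$grids$pdq$values)
  manifest <- jsonlite::read_json(sim$paths$manifest, simplifyVector = TRUE)
  expect_equal(manifest$n_species, 5)
  expect_equal(sum(manifest$species$planted_drought), 2)
})
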