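# Threshold derivation, strict classification, sensitivity/consistency
# analysis and Mann-Whitney separation validation.

profiles_from_medians <- function(pdq, mtcm = rev(pdq) / 20) {
  data.frame(species = sprintf("sp_%02d", seq_along(pdq)),
             n = 10, median_pdq = pdq, median_mtcm = mtcm,
             stringsAsFactors = FALSE)
}

test_that("thresholds delegate to the linear-interpolation quantile of species medians", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      pdq <- runif(sample(5:40, 1), 30, 170)
      prof <- profiles_from_medians(pdq)
      for (p in c(0.05, 0.25, 0.5)) {
        thr <- derive_thresholds(prof, p)
        expect_equal(thr$pdq_threshold, climate_quantile(prof$median_pdq, p))
        expect_equal(thr$mtcm_threshold, climate_quantile(prof$median_mtcm, p))
      }
    }
  })
  expect_error(derive_thresholds(profiles_from_medians(1), 0.25), "at least 2")
  expect_error(derive_thresholds(profiles_from_medians(1:5), 1.3), "\\[0, 1\\]")
})

test_that("thresholds are monotone non-decreasing in the percentile", {
  withr::with_seed(67, {
    for (rep in 1:20) {
      prof <- profiles_from_medians(runif(12, 30, 170), runif(12, -5, 12))
      ps <- sort(runif(6))
      thr_pdq <- vapply(ps, function(p) derive_thresholds(prof, p)$pdq_threshold,
                        numeric(1))
      thr_mtcm <- vapply(ps, function(p) derive_thresholds(prof, p)$mtcm_threshold,
                         numeric(1))
      expect_true(all(diff(thr_pdq) >= 0))
      expect_true(all(diff(thr_mtcm) >= 0))
    }
  })
})

test_that("classification is strict at the threshold and ranks ascending by median", {
  prof <- profiles_from_medians(c(59.0, 60.5, 30, 50, 120),
                                mtcm = c(5, 5, 5, 5, 5))
  scenario <- structure(list(percentile = 0.25, pdq_threshold = 60.5,
                             mtcm_threshold = 0.925),
                        class = "threshold_scenario")
  cls <- classify_species(prof, scenario)
  # median 59.0 < 60.5 is tolerant; exactly 60.5 is not
  expect_setequal(cls$drought$species, c("sp_01", "sp_03", "sp_04"))
  expect_false("sp_02" %in% cls$drought$species)
  # ranked strongest (driest) first: 30, 50, 59
  expect_equal(cls$drought$median, c(30, 50, 59))
  expect_equal(cls$drought$rank, 1:3)
  expect_equal(nrow(cls$cold), 0) # all medians above the MTCM threshold
})

test_that("a zero percentile with strict comparison yields empty candidate lists", {
  prof <- profiles_from_medians(runif(10, 40, 100))
  cls <- classify_species(prof, derive_thresholds(prof, 0))
  expect_equal(nrow(cls$drought), 0)
  expect_equal(nrow(cls$cold), 0)
})

test_that("tolerant sets nest across percentiles on random profile sets", {
  withr::with_seed(71, {
    for (rep in 1:100) {
      n_sp <- sample(5:35, 1)
      prof <- profiles_from_medians(runif(n_sp, 30, 170),
                                    mtcm = runif(n_sp, -5, 12))
      ps <- sort(sample(seq(0.05, 0.95, by = 0.05), 4))
      sets <- lapply(ps, function(p)
        classify_species(prof, derive_thresholds(prof, p)))
      for (i in seq_len(length(ps) - 1)) {
        expect_true(all(sets[[i]]$drought$species %in%
                          sets[[i + 1]]$drought$species))
        expect_true(all(sets[[i]]$cold$species %in%
                          sets[[i + 1]]$cold$species))
      }
    }
  })
})

test_that("consistency scores and the >= 5-of-7 core rule follow the scenario sets", {
  # medians built so candidate membership changes across the 7 scenarios
  prof <- profiles_from_medians(c(31, 34, 37, 40, 43, 46, 49, 52,
                                  80, 85, 90, 95, 100, 105, 110, 115),
                                mtcm = rep(5, 16))
  sens <- sensitivity_analysis(prof)
  d <- sens[sens$variable == "drought", ]
  expect_equal(nrow(d), 16)
  # nesting implies score = number of scenarios from first qualifying one
  for (i in seq_len(nrow(d))) {
    at <- as.numeric(strsplit(d$tolerant_at[i], ",")[[1]])
    expect_equal(d$consistency_score[i], length(at))
    if (length(at) > 0) {
      # contiguous upper tail of scenarios
      ps_all <- c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35)
      expect_equal(at, ps_all[ps_all >= min(at)])
    }
  }
  expect_identical(d$core, d$consistency_score >= 5)
  # the driest species qualifies everywhere
  expect_equal(d$consistency_score[d$species == "sp_01"], 7)
  expect_true(d$core[d$species == "sp_01"])
  # rank defined only at the reference percentile
  expect_true(all(is.na(d$rank[d$consistency_score == 0])))

  expect_error(sensitivity_analysis(prof, percentiles = c(0.25, 0.25)),
               "duplicate")
  expect_error(sensitivity_analysis(prof, percentiles = c(0.1, 0.2),
                                    reference = 0.25), "reference")
})

test_that("species tolerant in exactly 5 scenarios are core, fewer are not", {
  prof <- profiles_from_medians(seq(40, 110, length.out = 14), rep(5, 14))
  sens <- sensitivity_analysis(prof)
  d <- sens[sens$variable == "drought", ]
  expect_true(any(d$consistency_score >= 5 & d$core))
  expect_true(all(!d$core[d$consistency_score < 5]))
})

test_that("separation validation delegates to the Mann-Whitney test on pooled specimens", {
  withr::with_seed(83, {
    specimens <- data.frame(
      species = rep(sprintf("sp_%d", 1:4), each = 15),
      pdq_mm = c(rnorm(30, 45, 5), rnorm(30, 110, 5)),
      mtcm_c = rnorm(60, 3, 1))
  })
  res <- validate_separation(specimens, c("sp_1", "sp_2"), "drought")
  direct <- mann_whitney_u(specimens$pdq_mm[specimens$species %in% c("sp_1", "sp_2")],
                           specimens$pdq_mm[!specimens$species %in% c("sp_1", "sp_2")])
  expect_identical(res$statistic, direct$statistic)
  expect_identical(res$p_value, direct$p_value)
  expect_lt(res$p_value, 0.01)
  expect_error(validate_separation(specimens, character(0), "drought"),
               "non-empty")
  expect_error(validate_separation(specimens, sprintf("sp_%d", 1:4), "cold"),
               "non-empty")
})
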