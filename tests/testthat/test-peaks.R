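# Peak filtering: Poisson caller calibration, two-caller reconciliation,
# RNAi-sensitivity classification, and Ex/KD ratio distributions.

test_that("window caller is calibrated on null data and silent at cutoff 0", {
  set.seed(27)
  pos <- sample.int(2e5, 4000, replace = TRUE) - 1L
  lib <- make_lib(pos, strand = sample(c("+", "-"), 4000, TRUE), L = 2e5)
  expect_equal(nrow(call_windows_poisson(lib, lib, window = 100,
                                         fdr_cutoff = 0.05)), 0)
  gen <- generate_genome(2e5, 5, 0, 0, min_spacing = 5000, seed = 61)
  libs <- simulate_tag_libraries(gen$truth, seed = 3)
  expect_equal(nrow(call_windows_poisson(libs$exp_hs, libs$preimmune,
                                         fdr_cutoff = 0)), 0)
})

test_that("a single planted peak is called once, near its true center", {
  gen <- generate_genome(1e5, 1, 0, 0, min_spacing = 2000,
                         enrichment_fold = 40, seed = 71)
  libs <- simulate_tag_libraries(gen$truth, background_rate = 0.03, seed = 4)
  peaks <- call_windows_poisson(libs$exp_hs, libs$preimmune, window = 100,
                                fdr_cutoff = 0.05)
  expect_equal(nrow(peaks), 1)
  expect_lt(abs(peaks$center - gen$truth$true_peaks$center), 50)
  expect_true(peaks$start <= peaks$center && peaks$center < peaks$end)
})

test_that("empty background falls back to a uniform model with a message", {
  set.seed(5)
  lib <- make_lib(sample.int(5e4, 2000, TRUE) - 1L, L = 5e4)
  empty <- make_lib(integer(0), L = 5e4)
  expect_message(call_windows_poisson(lib, empty, window = 100),
                 "uniform-background")
})

test_that("reconcile_callers merges by the center-in-boundary rule", {
  region <- data.frame(chrom = "chrS", start = 50L, end = 150L, center = 100L,
                       caller = "caller_A", fdr = 0.01)
  point <- data.frame(chrom = "chrS", start = 95L, end = 105L, center = 100L,
                      caller = "caller_B", fdr = 0.001)
  merged <- reconcile_callers(region, point)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$caller, "both")
  expect_equal(merged$center, 100L)          # point caller's center
  expect_equal(c(merged$start, merged$end), c(50L, 150L))  # region boundary
  expect_equal(merged$fdr, 0.001)
  # center outside the boundary: both candidates retained
  point2 <- data.frame(chrom = "chrS", start = 195L, end = 205L,
                       center = 200L, caller = "caller_B", fdr = 0.001)
  both <- reconcile_callers(region, point2)
  expect_equal(nrow(both), 2)
  expect_setequal(both$caller, c("caller_A", "caller_B"))
  # region-caller-only peaks are retained as candidates
  only <- reconcile_callers(region, point2[0, ])
  expect_equal(nrow(only), 1)
  expect_equal(only$caller, "caller_A")
  # center inside two boundaries goes to the nearer region center
  regions2 <- rbind(region,
                    data.frame(chrom = "chrS", start = 90L, end = 260L,
                               center = 175L, caller = "caller_A", fdr = 0.05))
  expect_message(res <- reconcile_callers(regions2, point), "two region")
  expect_equal(res$end[res$caller == "both"], 150L)
})

test_that("RNAi-sensitivity criteria classify exactly as stated", {
  L <- 1e5
  # experimental window count 50, knockdown 10 -> depletion 5
  exp_lib <- make_window_lib(5000, 50, L = L)
  kd_lib <- make_window_lib(5000, 10, L = L)
  cand <- data.frame(chrom = "chrS", start = 4900L, end = 5100L,
                     center = 5000L, caller = "both", fdr = 0.01)
  kd_called <- data.frame(chrom = "chrS", start = 4950L, end = 5050L,
                          center = 5000L, caller = "caller_B", fdr = 0.05)
  r1 <- classify_rnai_sensitivity(cand, kd_called, exp_lib, kd_lib,
                                  reference_depletion = 10 / 7)
  expect_equal(r1$classification, "sensitive_criterion1")
  expect_equal(r1$depletion, 5)
  # absent from knockdown calls, depletion 3.2 -> criterion 2
  kd32 <- make_window_lib(5000, 50, L = L)
  exp32 <- make_window_lib(5000, 160, L = L)
  no_kd <- kd_called[0, ]
  r2 <- classify_rnai_sensitivity(cand, no_kd, exp32, kd32)
  expect_equal(r2$classification, "sensitive_criterion2")
  # absent from knockdown calls, depletion 2 -> resistant
  exp20 <- make_window_lib(5000, 100, L = L)
  r3 <- classify_rnai_sensitivity(cand, no_kd, exp20, kd32)
  expect_equal(r3$classification, "resistant")
  # called in knockdown but under the reference depletion -> resistant
  r4 <- classify_rnai_sensitivity(cand, kd_called, exp20, kd32,
                                  reference_depletion = 3)
  expect_equal(r4$classification, "resistant")
  # zero knockdown count triggers the pseudocount, flagged
  kd0 <- make_window_lib(5000, 0, extra = 50, L = L)
  expect_message(r5 <- classify_rnai_sensitivity(cand, no_kd, exp20, kd0),
                 "pseudocount")
  expect_equal(r5$depletion, (r5$intensity_exp + 1) / 1)
})

test_that("classification is exhaustive, exclusive, and monotone in the KD count", {
  L <- 1e5
  exp_lib <- make_window_lib(5000, 120, L = L)
  kd_called <- data.frame(chrom = "chrS", start = 4950L, end = 5050L,
                          center = 5000L, caller = "caller_B", fdr = 0.05)
  cand <- data.frame(chrom = "chrS", start = 4900L, end = 5100L,
                     center = 5000L, caller = "both", fdr = 0.01)
  seen <- character(0)
  rank <- c(sensitive_criterion1 = 1, sensitive_criterion2 = 1, resistant = 2)
  for (in_kd in c(TRUE, FALSE)) {
    ranks <- vapply(c(2, 10, 30, 60, 90, 120), function(nkd) {
      kd_lib <- make_window_lib(5000, nkd, L = L)
      r <- classify_rnai_sensitivity(cand, if (in_kd) kd_called else
        kd_called[0, ], exp_lib, kd_lib)
      seen <<- c(seen, r$classification)
      rank[[r$classification]]
    }, numeric(1))
    # increasing the knockdown count can only move a peak toward resistant
    expect_true(all(diff(ranks) >= 0))
  }
  expect_true(all(seen %in% names(rank)))
})

test_that("Ex/KD ratio statistic is self-calibrated on its own null", {
  gen <- generate_genome(4e5, 50, 0, 0, min_spacing = 2500, seed = 81)
  libs <- simulate_tag_libraries(gen$truth, seed = 6)
  # identity libraries: every ratio is 1
  reg <- data.frame(chrom = "chrS",
                    center = seq(2000, 398000, length.out = 200))
  idd <- ex_kd_ratio_distribution(reg, libs$preimmune, libs$preimmune,
                                  n_random = 200, seed = 2)
  expect_true(all(idd$ratios == 1))
  # random regions against the random null: fraction ~ 0.95
  set.seed(17)
  rnd <- data.frame(chrom = "chrS",
                    center = floor(runif(400, 120, 4e5 - 120)))
  cal <- ex_kd_ratio_distribution(rnd, libs$exp_hs, libs$kd_hs,
                                  n_random = 2000, seed = 3)
  se <- sqrt(0.95 * 0.05 / 400)
  expect_lt(abs(cal$fraction_below_upper_tail - 0.95), 3 * se + 0.01)
  # strongly depleted true peaks exceed the null tail almost always
  tp <- data.frame(chrom = "chrS", center = gen$truth$true_peaks$center)
  dep <- ex_kd_ratio_distribution(tp, libs$exp_hs, libs$kd_hs,
                                  n_random = 1000, seed = 4)
  expect_lt(dep$fraction_below_upper_tail, 0.05)
  expect_error(ex_kd_ratio_distribution(tp, libs$exp_hs, libs$kd_hs,
                                        n_random = 50), ">= 100")
})
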