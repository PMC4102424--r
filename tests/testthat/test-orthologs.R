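clean_pair <- function(...) {
  base <- tibble::tibble(
    pair_id = "p1", motif_a = "A", motif_b = "A", motif_size = 1L,
    repeat_number_a = 10, repeat_number_b = 10,
    n_interruptions_a = 0L, n_interruptions_b = 0L,
    interruption_bases_a = "", interruption_bases_b = "",
    interruption_context_a = "", interruption_context_b = "",
    flank_identity = 0.95, min_flank_phred = 40L,
    flank_low_complexity = FALSE, distance_to_nearest_locus_bp = 100L)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("each ortholog filter rejects on its own criterion, in order", {
  cases <- list(
    list(clean_pair(distance_to_nearest_locus_bp = 24L), 1L),
    list(clean_pair(min_flank_phred = 19L), 2L),
    list(clean_pair(flank_low_complexity = TRUE), 3L),
    list(clean_pair(flank_identity = 0.84), 4L),
    list(clean_pair(motif_b = "C"), 5L),
    list(clean_pair(n_interruptions_b = 3L), 6L),
    list(clean_pair(n_interruptions_a = 1L, n_interruptions_b = 1L,
                    interruption_bases_a = "T", interruption_bases_b = "C"), 7L),
    list(clean_pair(n_interruptions_a = 1L, n_interruptions_b = 1L,
                    interruption_bases_a = "T", interruption_bases_b = "T",
                    interruption_context_a = "A|A",
                    interruption_context_b = "A|C"), 8L)
  )
  for (cs in cases) {
    res <- filter_orthologs(cs[[1]])
    expect_equal(nrow(res$kept), 0)
    expect_equal(res$rejection_log$n_rejected[cs[[2]]], 1L)
    expect_equal(sum(res$rejection_log$n_rejected), 1L)
  }
  # boundary values pass: distance 25, phred 20, identity 0.85
  ok <- clean_pair(distance_to_nearest_locus_bp = 25L, min_flank_phred = 20L,
                   flank_identity = 0.85)
  expect_equal(nrow(filter_orthologs(ok)$kept), 1)
})

test_that("a pair failing several filters is logged under the first", {
  p <- clean_pair(min_flank_phred = 10L, flank_identity = 0.5)
  log <- filter_orthologs(p)$rejection_log
  expect_equal(log$n_rejected[2], 1L)
  expect_equal(log$n_rejected[4], 0L)
})

test_that("a clean cohort passes untouched and missing columns name their filter", {
  cohort <- dplyr::bind_rows(lapply(1:5, function(i) clean_pair(pair_id = paste0("p", i))))
  res <- filter_orthologs(cohort)
  expect_equal(nrow(res$kept), 5)
  expect_true(all(res$rejection_log$n_rejected == 0))
  expect_error(filter_orthologs(dplyr::select(cohort, -flank_identity)),
               "flank_identity")
})

test_that("low-complexity detection flags runs and skewed composition", {
  expect_true(is_low_complexity("GCGTAAAAAAAATGC"))      # mono run >= 8
  expect_true(is_low_complexity("GCGTATATATATGCGTCAGT")) # di run >= 8 bp
  expect_true(is_low_complexity("AATAATAAATAAATA"))      # entropy < 1 bit? runs
  expect_false(is_low_complexity("ACGTGCTAGCTAGGATCCAT"))
})

test_that("mutability is the mean squared repeat-number difference", {
  expect_equal(mutability(tibble::tibble(repeat_number_a = c(10, 10),
                                         repeat_number_b = c(12, 10))), 2)
  expect_equal(mutability(tibble::tibble(repeat_number_a = rep(7, 4),
                                         repeat_number_b = rep(7, 4))), 0)
  expect_error(mutability(tibble::tibble(repeat_number_a = numeric(),
                                         repeat_number_b = numeric())),
               "empty")
  # invariant to pair order and species swap; zero-difference pairs never
  # increase it
  d <- tibble::tibble(repeat_number_a = c(10, 11, 9), repeat_number_b = c(12, 11, 10))
  expect_equal(mutability(d), mutability(d[3:1, ]))
  swapped <- dplyr::rename(d, repeat_number_a = repeat_number_b,
                           repeat_number_b = repeat_number_a)
  expect_equal(mutability(d), mutability(swapped))
  expect_lte(mutability(dplyr::bind_rows(d, tibble::tibble(repeat_number_a = 5,
                                                           repeat_number_b = 5))),
             mutability(d))
})

test_that("simulated cohorts recover the closed-form mutability 2gr", {
  pr <- gen_ortholog_pairs(20000, r = 0.01, k = 1, g = 20, rng_seed = 11)
  perf <- pr[pr$cohort == "perfect", ]
  expect_equal(mutability(perf), 2 * 20 * 0.01, tolerance = 0.12)
  # truth columns alone reproduce the statistic's expectation
  expect_equal(mean(perf$steps_a + perf$steps_b), 2 * 20 * 0.01,
               tolerance = 0.1)
})

test_that("bootstrap intervals are degenerate exactly when the data are", {
  same <- tibble::tibble(repeat_number_a = rep(10, 8), repeat_number_b = rep(10, 8))
  expect_equal(unname(bootstrap_ci(same, B = 200, rng_seed = 1)), c(0, 0))
  one <- tibble::tibble(repeat_number_a = 10, repeat_number_b = 13)
  expect_equal(unname(bootstrap_ci(one, B = 200, rng_seed = 1)), c(9, 9))
})

test_that("seed-fixed bootstrap runs are identical and leave the RNG alone", {
  d <- gen_ortholog_pairs(200, rng_seed = 5)
  set.seed(99); before <- runif(1)
  set.seed(99)
  ci1 <- bootstrap_ci(d, B = 300, rng_seed = 42)
  after <- runif(1)
  ci2 <- bootstrap_ci(d, B = 300, rng_seed = 42)
  expect_identical(ci1, ci2)
  expect_identical(before, after)   # RNG state restored
})

test_that("stratified mutability separates interruption strata and flags small bins", {
  pr <- gen_ortholog_pairs(400, r = 0.02, k = 4, g = 20, rng_seed = 8)
  sm <- stratified_mutability(pr, strata = "interruptions", B = 200,
                              rng_seed = 3, min_loci = 20)
  expect_s3_class(sm, "ims_mutability")
  expect_true(all(c("0", "1") %in% sm$stratum))
  expect_true(all(sm$ci_low <= sm$mu + 1e-12 & sm$mu <= sm$ci_high + 1e-12))
  expect_true(any(sm$low_confidence) || all(sm$n_loci >= 20))
  # identical pair multisets give identical mu regardless of stratum label
  d <- pr[pr$cohort == "perfect", ]
  d2 <- d
  d2$n_interruptions_a <- 2L
  both <- dplyr::bind_rows(d, d2)
  sm2 <- stratified_mutability(both, strata = "interruptions", B = 50,
                               rng_seed = 1)
  wide <- split(sm2$mu, sm2$stratum)
  expect_equal(unname(wide[["0"]]), unname(wide[["2"]]))
})

test_that("position strata handle all-perfect cohorts without crashing", {
  pr <- gen_ortholog_pairs(50, r = 0.02, k = 2, g = 10, rng_seed = 2)
  perf <- pr[pr$cohort == "perfect", ]
  sm <- stratified_mutability(perf, strata = "position", B = 50, rng_seed = 1)
  expect_true(all(sm$stratum == "perfect"))
  # interruption identity strata
  smi <- stratified_mutability(pr, strata = "identity", B = 50, rng_seed = 1)
  expect_setequal(unique(smi$stratum), c("perfect", "T"))
})

test_that("fold-change estimates recover the planted reduction", {
  pr <- gen_ortholog_pairs(8000, r = 0.01, k = 4, g = 20, rng_seed = 21)
  ci <- mutability_ratio_ci(pr[pr$cohort == "perfect", ],
                            pr[pr$cohort == "interrupted", ],
                            B = 500, rng_seed = 21)
  expect_gt(ci[["ratio"]], 2.5)
  expect_lt(ci[["ratio"]], 6.5)
  expect_true(ci[["ci_low"]] <= 4 && 4 <= ci[["ci_high"]])
})
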