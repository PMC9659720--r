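test_that("self-coverage is exactly 1 with denoising and resampling off", {
  co <- make_cohort("A", matrix(rnorm(600), 300, 2))
  pc <- bootstrap_pair_coverage(co, co, c("f1", "f2"), n_boot = 1,
                                denoise = FALSE, resample = FALSE, seed = 1)
  expect_identical(pc$mean_coverage, 1)
  expect_identical(pc$sd_coverage, 0)
})

test_that("bootstrap coverage is deterministic under a fixed seed", {
  set.seed(2)
  a <- make_cohort("A", matrix(rnorm(400), 200, 2))
  b <- make_cohort("B", matrix(rnorm(400, sd = 1.5), 200, 2))
  p1 <- bootstrap_pair_coverage(a, b, c("f1", "f2"), n_boot = 10, seed = 99)
  p2 <- bootstrap_pair_coverage(a, b, c("f1", "f2"), n_boot = 10, seed = 99)
  expect_identical(p1, p2)
  p3 <- bootstrap_pair_coverage(a, b, c("f1", "f2"), n_boot = 10, seed = 100)
  expect_false(identical(p1$mean_coverage, p3$mean_coverage))
})

test_that("flag_low_coverage applies Q1 - 1.5 IQR with interpolated quartiles", {
  vals <- c(lo = 0.5, a = 0.9, b = 0.92, c = 0.95, d = 0.96)
  fl <- flag_low_coverage(vals)
  expect_equal(fl$threshold, 0.825)  # Q1 = 0.9, Q3 = 0.95
  expect_equal(fl$flagged, "lo")
  # constant values: IQR = 0, threshold = Q1, nothing strictly below
  expect_equal(flag_low_coverage(setNames(rep(0.8, 5), letters[1:5]))$flagged,
               character(0))
  # spread values but min above threshold
  expect_equal(flag_low_coverage(c(a = 0.7, b = 0.8, c = 0.85, d = 0.9))$flagged,
               character(0))
  expect_error(flag_low_coverage(c(a = 1, b = 1, c = 1)), "at least 4")
})

test_that("feature_coverage takes per-feature medians over containing pairs", {
  mk <- function(fi, fj, cov) tibble::tibble(
    query_site = "A", hull_site = "B", feature_i = fi, feature_j = fj,
    mean_coverage = cov, sd_coverage = 0, n_boot = 1L, seed = 1L)
  # constant coverages: every per-feature median equals the constant
  pcs <- dplyr::bind_rows(
    mk("a", "b", 0.8), mk("a", "c", 0.8), mk("a", "d", 0.8),
    mk("b", "c", 0.8), mk("b", "d", 0.8), mk("c", "d", 0.8))
  fc <- feature_coverage(pcs)
  expect_equal(fc$coverage, rep(0.8, 4))
  # hand-listed coverages vs sort-and-middle over each feature's 3 pairs
  covs <- c(ab = 0.2, ac = 0.4, ad = 0.6, bc = 0.7, bd = 0.9, cd = 1.0)
  pcs2 <- dplyr::bind_rows(
    mk("a", "b", covs["ab"]), mk("a", "c", covs["ac"]), mk("a", "d", covs["ad"]),
    mk("b", "c", covs["bc"]), mk("b", "d", covs["bd"]), mk("c", "d", covs["cd"]))
  fc2 <- feature_coverage(pcs2)
  expect_equal(fc2$coverage[fc2$feature == "a"],
               oracle_median(c(0.2, 0.4, 0.6)))
  expect_equal(fc2$coverage[fc2$feature == "b"],
               oracle_median(c(0.2, 0.7, 0.9)))
  expect_equal(fc2$coverage[fc2$feature == "d"],
               oracle_median(c(0.6, 0.9, 1.0)))
  # p = 2: singleton median equals the single pair's coverage
  fc3 <- feature_coverage(mk("a", "b", 0.37))
  expect_equal(fc3$coverage, c(0.37, 0.37))
  expect_true(all(is.na(fc3$threshold)))
  # a missing pair is an error naming it
  expect_error(feature_coverage(pcs[-1, ]), "a x b")
  # unless it is recorded as skipped
  fc4 <- feature_coverage(pcs[-1, ], skipped = tibble::tibble(feature_i = "a",
                                                              feature_j = "b"))
  expect_equal(nrow(fc4), 4)
})

test_that("coverage matrix of identical cohorts is 1 without noise sources", {
  set.seed(4)
  a <- make_cohort("A", matrix(rnorm(300), 100, 3))
  b <- a; b$site <- "B"; b$patient_id <- sub("A", "B", b$patient_id)
  cm <- coverage_matrix(list(a, b), n_boot = 1, denoise = FALSE,
                        resample = FALSE, seed = 1)
  expect_equal(unname(cm$mean_coverage), matrix(1, 2, 2))
})

test_that("coverage matrix entries stay in range and permute with input order", {
  set.seed(6)
  a <- make_cohort("A", matrix(rnorm(300), 100, 3))
  b <- make_cohort("B", matrix(rnorm(300, sd = 0.5), 100, 3))
  c_ <- make_cohort("C", matrix(rnorm(300, 1), 100, 3))
  cm1 <- coverage_matrix(list(a, b, c_), n_boot = 3, seed = 5)
  expect_true(all(cm1$mean_coverage >= 0 & cm1$mean_coverage <= 1))
  cm2 <- coverage_matrix(list(c_, a, b), n_boot = 3, seed = 5)
  expect_equal(cm2$mean_coverage[c("A", "B", "C"), c("A", "B", "C")],
               cm1$mean_coverage)
})

test_that("nested supports give asymmetric coverage", {
  set.seed(8)
  small <- make_cohort("S", matrix(rnorm(400, sd = 0.3), 200, 2))
  big <- make_cohort("L", matrix(rnorm(400, sd = 2), 200, 2))
  cm <- coverage_matrix(list(small, big), n_boot = 1, denoise = FALSE,
                        resample = FALSE, seed = 1)
  expect_equal(cm$mean_coverage["S", "L"], 1)          # small fully covered
  expect_lt(cm$mean_coverage["L", "S"], 0.75)          # big not covered by small
})

test_that("constant features yield skipped pairs in the QC log, not a crash", {
  set.seed(9)
  vals <- cbind(rnorm(100), rnorm(100), 5)  # f3 is protocol-constant
  a <- make_cohort("A", vals)
  b <- make_cohort("B", vals + 0.1)
  cm <- coverage_matrix(list(a, b), n_boot = 2, seed = 3)
  expect_true(all(c("f3") %in% c(cm$qc$feature_i, cm$qc$feature_j)))
  expect_true(all(is.finite(cm$mean_coverage)))
  # per-feature medians are over surviving pairs only
  expect_true(all(is.na(cm$per_feature$coverage[cm$per_feature$feature == "f3"])))
})

test_that("hull-side-only resampling leaves the query cohort fixed", {
  set.seed(10)
  a <- make_cohort("A", matrix(rnorm(200), 100, 2))
  b <- make_cohort("B", matrix(rnorm(200), 100, 2))
  p <- bootstrap_pair_coverage(a, b, c("f1", "f2"), n_boot = 5, seed = 2,
                               denoise = FALSE, hull_only_resample = TRUE)
  expect_true(p$mean_coverage >= 0 && p$mean_coverage <= 1)
  # degenerate-hull errors carry the replicate index
  const <- make_cohort("C", cbind(rep(1, 50), rep(2, 50)))
  expect_error(
    bootstrap_pair_coverage(a, const, c("f1", "f2"), n_boot = 3, seed = 1,
                            denoise = FALSE),
    "replicate 1", class = "hs_degenerate_hull")
})
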