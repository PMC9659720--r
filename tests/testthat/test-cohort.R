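test_that("load_cohort reads CSV with stable shape and preserves missingness", {
  path <- write_temp_csv(c(
    "patient_id,site,hr,sbp",
    "p1,A,80,120",
    "p2,A,NA,130",
    "p3,A,95,NA"
  ))
  co <- load_cohort(path)
  expect_equal(nrow(co), 3)
  expect_equal(cohort_features(co), c("hr", "sbp"))
  expect_equal(co$patient_id, c("p1", "p2", "p3"))
  expect_equal(sum(is.na(co[, c("hr", "sbp")])), 2)  # one NA per column
})

test_that("load_cohort rejects duplicate ids and non-numeric feature cells", {
  dup <- write_temp_csv(c("patient_id,hr", "p1,80", "p1,90"))
  expect_error(load_cohort(dup, site = "A"), "p1")
  bad <- write_temp_csv(c("patient_id,hr", "p1,80", "p2,high"))
  expect_error(load_cohort(bad, site = "A"), "hr.*row 2|row 2.*hr")
})

test_that("load_cohort handles schema roles, codes and endpoint", {
  path <- write_temp_csv(c(
    "id,hosp,outcome,dx,hr",
    "p1,A,1,J80;I10,80",
    "p2,A,0,,95"
  ))
  co <- load_cohort(path, schema = list(patient_id = "id", site = "hosp",
                                        endpoint = "outcome", codes = "dx"))
  expect_equal(co$endpoint, c(1L, 0L))
  expect_equal(co$codes[[1]], c("J80", "I10"))
  expect_equal(co$codes[[2]], character(0))
  expect_equal(cohort_features(co), "hr")
})

test_that("load_cohort reads Parquet", {
  path <- tempfile(fileext = ".parquet")
  arrow::write_parquet(data.frame(patient_id = c("p1", "p2"), hr = c(80, 90)), path)
  co <- load_cohort(path, site = "A")
  expect_equal(co$hr, c(80, 90))
})

test_that("aggregate_first_day takes medians over the half-open first-day window", {
  recs <- tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2"),
    parameter = "pao2",
    time_h = c(1, 5, 30, 30),
    value = c(80, 100, 90, 70)
  )
  co <- aggregate_first_day(recs, site = "A")
  expect_equal(co$pao2[co$patient_id == "p1"], 90)  # median of 80, 100
  expect_true(is.na(co$pao2[co$patient_id == "p2"]))  # only value outside window
  # measurement at exactly window_h is excluded (half-open window)
  at24 <- tibble::tibble(patient_id = "p1", parameter = "hr", time_h = c(2, 24),
                         value = c(60, 100))
  expect_equal(aggregate_first_day(at24, site = "A")$hr, 60)
})

test_that("aggregate_first_day matches a brute-force median oracle on random records", {
  set.seed(42)
  recs <- tibble::tibble(
    patient_id = sample(paste0("p", 1:5), 50, replace = TRUE),
    parameter = sample(c("hr", "map"), 50, replace = TRUE),
    time_h = runif(50, 0, 48),
    value = rnorm(50, 80, 10)
  )
  co <- aggregate_first_day(recs, window_h = 24, site = "A")
  for (pid in unique(recs$patient_id)) {
    for (par in c("hr", "map")) {
      v <- recs$value[recs$patient_id == pid & recs$parameter == par & recs$time_h < 24]
      expected <- if (length(v)) oracle_median(v) else NA_real_
      expect_equal(co[[par]][co$patient_id == pid], expected)
    }
  }
  expect_error(aggregate_first_day(recs, window_h = 0), "positive")
})

test_that("empty record collection yields an empty cohort, not an error", {
  co <- aggregate_first_day(tibble::tibble(patient_id = character(),
                                           parameter = character(),
                                           time_h = numeric(), value = numeric()),
                            site = "A")
  expect_equal(nrow(co), 0)
})

test_that("sparse-feature filter drops strictly above the threshold and is idempotent", {
  vals <- matrix(1, 100, 3)
  vals[1:31, 1] <- NA  # 31% missing -> dropped
  vals[1:30, 2] <- NA  # exactly 30% -> retained
  co <- make_cohort("A", vals)
  filtered <- filter_sparse_features(co, 0.30)
  expect_equal(cohort_features(filtered), c("f2", "f3"))
  expect_identical(filter_sparse_features(filtered, 0.30), filtered)
  # fully observed cohort is unchanged
  full <- make_cohort("A", matrix(rnorm(30), 10, 3))
  expect_identical(filter_sparse_features(full), full)
})

test_that("intersect_features restricts to the shared set and errors when empty", {
  a <- make_cohort("A", matrix(1, 2, 3), c("a", "b", "c"))
  b <- make_cohort("B", matrix(1, 2, 3), c("b", "c", "d"))
  out <- intersect_features(list(a, b))
  expect_equal(cohort_features(out[[1]]), c("b", "c"))
  expect_equal(cohort_features(out[[1]]), cohort_features(out[[2]]))
  # identical feature sets pass through unchanged
  out2 <- intersect_features(list(a, a))
  expect_equal(cohort_features(out2[[1]]), c("a", "b", "c"))
  d <- make_cohort("D", matrix(1, 2, 2), c("x", "y"))
  expect_error(intersect_features(list(a, d)), "no features")
  expect_error(intersect_features(list(a)), "at least two")
})

test_that("site-median imputation fills gaps without touching observed values", {
  co <- make_cohort("A", cbind(c(1, NA, 3), c(5, 6, 7)))
  imp <- impute_site_median(co)
  expect_equal(imp$f1, c(1, 2, 3))
  expect_identical(imp$f2, co$f2)
  # identity on complete data
  expect_identical(impute_site_median(make_cohort("A", cbind(1:3, 4:6))),
                   make_cohort("A", cbind(1:3, 4:6)))
  # fully missing feature is an error naming the feature
  allna <- make_cohort("A", cbind(c(NA, NA), c(1, 2)))
  expect_error(impute_site_median(allna), "f1")
})

test_that("imputed values equal per-column brute-force medians under a seeded mask", {
  set.seed(7)
  vals <- matrix(rnorm(500), 100, 5)
  mask <- matrix(runif(500) < 0.2, 100, 5)
  masked <- vals; masked[mask] <- NA
  co <- make_cohort("A", masked)
  imp <- impute_site_median(co)
  for (j in 1:5) {
    f <- paste0("f", j)
    expected <- oracle_median(masked[, j])
    expect_equal(imp[[f]][mask[, j]], rep(expected, sum(mask[, j])))
    expect_equal(imp[[f]][!mask[, j]], vals[!mask[, j], j])  # observed untouched
  }
  expect_false(anyNA(imp[, cohort_features(imp)]))
})

test_that("as_cohort validates endpoint and rejects non-numeric features", {
  base <- tibble::tibble(patient_id = c("p1", "p2"), hr = c(1, 2))
  expect_error(as_cohort(dplyr::mutate(base, endpoint = c(1, 2)), site = "A"), "0/1")
  expect_error(as_cohort(dplyr::mutate(base, sex = c("m", "f")), site = "A"),
               "not numeric")
})
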