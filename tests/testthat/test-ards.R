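test_that("Horowitz index handles both FiO2 conventions", {
  expect_equal(horowitz_index(60, 0.21), 60 / 0.21)
  expect_equal(horowitz_index(300, 1.0), 300)
  expect_equal(horowitz_index(120, 40), 300)  # percent input
  expect_error(horowitz_index(60, 0), "positive")
  expect_error(horowitz_index(-5, 0.5), "positive")
  expect_error(horowitz_index(60, 120), "100")
})

test_that("onset detection follows the sustained-below rule", {
  # never below threshold
  r <- detect_onset(c(0, 10, 20), c(320, 310, 305))
  expect_true(is.na(r$onset_time_h))
  expect_false(r$is_day1)
  # below from t = 0 continuously for 30 h
  r2 <- detect_onset(seq(0, 30, by = 5), rep(250, 7))
  expect_equal(r2$onset_time_h, 0)
  expect_true(r2$is_day1)
  # below during [0,12], above at 13, below during [20,48]: onset at 20
  t <- c(0, 6, 12, 13, 20, 30, 40, 48)
  v <- c(250, 260, 270, 320, 280, 270, 260, 250)
  r3 <- detect_onset(t, v)
  expect_equal(r3$onset_time_h, 20)
  expect_true(r3$is_day1)
  expect_equal(oracle_onset(t, v), 20)
  # an unsustained dip does not qualify
  r4 <- detect_onset(c(0, 4, 8, 40), c(350, 250, 340, 330))
  expect_true(is.na(r4$onset_time_h))
  expect_error(detect_onset(numeric(), numeric()), "empty")
})

test_that("onset detector agrees with the exhaustive scan on random trajectories", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:25, 1)
    t <- sort(runif(n, 0, 96))
    v <- runif(n, 150, 450)
    got <- detect_onset(t, v)
    want <- oracle_onset(t, v)
    expect_identical(got$onset_time_h, want)
    expect_identical(got$is_day1, !is.na(want) && want < 24)
  }
})

make_ards_fixture <- function() {
  times <- seq(0, 48, by = 4)
  mk_series <- function(pid, pf) {
    tibble::tibble(
      patient_id = pid,
      parameter = rep(c("pao2", "fio2", "peep"), each = length(times)),
      time_h = rep(times, 3),
      value = c(pf * 0.4, rep(0.4, length(times)), rep(6, length(times))))
  }
  series <- dplyr::bind_rows(
    mk_series("p1", ifelse(times >= 4, 250, 350)),   # early sustained crossing
    mk_series("p2", ifelse(times >= 28, 250, 350)),  # late onset
    mk_series("p3", rep(250, length(times))),        # persistently low, uncoded
    mk_series("p4", rep(350, length(times)))         # never low
  )
  # p5 has no PEEP in the first day -> excluded
  series <- dplyr::bind_rows(
    series,
    tibble::tibble(patient_id = "p5",
                   parameter = c("pao2", "fio2", "peep"),
                   time_h = c(2, 2, 30), value = c(100, 0.4, 6)))
  cohort <- as_cohort(tibble::tibble(
    patient_id = paste0("p", 1:5),
    codes = list("J80", c("J80", "I10"), "I10", character(0), "J80"),
    hr = c(80, 90, 85, 70, 75)
  ), site = "A")
  list(cohort = cohort, series = series)
}

test_that("ARDS labeling combines codes with day-1 sustained onset", {
  fx <- make_ards_fixture()
  res <- assign_ards_labels(fx$cohort, fx$series, code_systems = list(A = "J80"))
  lab <- setNames(res$cohort$endpoint, res$cohort$patient_id)
  expect_equal(lab[["p1"]], 1L)  # coded + onset hour 4
  expect_equal(lab[["p2"]], 0L)  # coded but onset at hour 28 -> control
  expect_equal(lab[["p3"]], 0L)  # low index but no qualifying code
  expect_equal(lab[["p4"]], 0L)
  expect_false("p5" %in% res$cohort$patient_id)  # missing first-day PEEP
  expect_equal(res$counts$n_cases, 1)
  expect_equal(res$counts$n_controls_coded_late, 1)
  expect_equal(res$counts$n_controls_uncoded, 2)
  expect_equal(res$counts$n_excluded, 1)
  # label conservation
  expect_equal(with(res$counts, n_cases + n_controls_uncoded +
                      n_controls_coded_late + n_excluded), nrow(fx$cohort))
  expect_error(assign_ards_labels(fx$cohort, fx$series, code_systems = list(B = "J80")),
               "site 'A'")
})

test_that("ICD-9 style code lists work per site", {
  fx <- make_ards_fixture()
  icd9 <- c("5185", "51851", "51852", "51853", "51882")
  co <- fx$cohort
  co$codes <- list("51851", "486", "5185", character(0), "51882")
  res <- assign_ards_labels(co, fx$series, code_systems = list(A = icd9))
  lab <- setNames(res$cohort$endpoint, res$cohort$patient_id)
  expect_equal(lab[["p1"]], 1L)
  expect_equal(lab[["p2"]], 0L)  # non-qualifying code
})

test_that("cross_predict is deterministic and errors on single-class sites", {
  sc <- generate_scenario("nested-support", p = 3, n = 250, magnitude = 1, seed = 81)
  sc <- sc[c("A", "D")]
  m1 <- cross_predict(sc, seed = 7)
  m2 <- cross_predict(sc, seed = 7)
  expect_identical(m1$auc, m2$auc)
  expect_true(all(m1$auc >= 0 & m1$auc <= 1))
  bad <- sc
  bad$A$endpoint <- 0L
  expect_error(cross_predict(bad, seed = 7), "single endpoint class")
})

test_that("tidy and glance summarise cross-prediction results", {
  sc <- generate_scenario("nested-support", p = 3, n = 250, magnitude = 1, seed = 91)
  cp <- cross_predict(sc[c("A", "D")], seed = 3)
  td <- tidy(cp)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$internal), 2)
  expect_equal(td$drop[td$internal], c(0, 0))
  gl <- glance(cp)
  expect_equal(gl$n_sites, 2)
  expect_true(gl$max_drop_test_site %in% c("A", "D"))
})
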