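#' Horowitz index (PaO2/FiO2 ratio)
#'
#' The oxygenation criterion of the Berlin ARDS definition uses the ratio of
#' arterial oxygen partial pressure (mmHg) to the inspired oxygen fraction.
#' FiO2 values above 1 are interpreted as percentages and divided by 100
#' (both conventions occur in ICU charting).
#'
#' @param pao2 Arterial PaO2 in mmHg (> 0). Vectorized.
#' @param fio2 Inspired oxygen fraction in (0, 1], or percent in (1, 100].
#' @return `pao2 / fio2` with FiO2 as a fraction.
#' @examples
#' horowitz_index(60, 0.21)   # 285.7
#' horowitz_index(120, 40)    # percent FiO2 -> 300
#' @export
horowitz_index <- function(pao2, fio2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0)) abort("`pao2` must be positive")
  if (any(!is.finite(fio2)) || any(fio2 <= 0)) abort("`fio2` must be positive (0 is undefined)")
  if (any(fio2 > 100)) abort("`fio2` above 100 is neither a fraction nor a percent")
  fio2 <- ifelse(fio2 > 1, fio2 / 100, fio2)
  pao2 / fio2
}

#' Detect sustained ARDS oxygenation onset in a Horowitz-index series
#'
#' Onset is the earliest measurement time at which the index is below
#' `threshold` and stays below it for at least `sustain_h` hours. Between
#' measurements the state is carried forward (LOCF): a below-threshold run is
#' broken by the first measurement at or above the threshold, and its span is
#' measured from the run's first measurement to that break (or, if the record
#' ends while still below, to the last measurement — the run then qualifies
#' only if its observed span reaches `sustain_h`).
#'
#' @param time_h Measurement times in hours from admission (sorted
#'   ascending).
#' @param index Horowitz-index values at those times.
#' @param threshold Onset threshold (default 300 mmHg).
#' @param sustain_h Minimum sustained duration in hours (default 24).
#' @return List with `onset_time_h` (`NA` if no qualifying onset) and
#'   `is_day1` (`TRUE` when onset occurs before hour 24).
#' @export
detect_onset <- function(time_h, index, threshold = 300, sustain_h = 24) {
  if (length(time_h) == 0) abort("empty Horowitz-index series")
  if (length(time_h) != length(index)) abort("`time_h` and `index` lengths differ")
  if (is.unsorted(time_h)) {
    o <- order(time_h)
    time_h <- time_h[o]; index <- index[o]
  }
  below <- index < threshold
  n <- length(below)
  onset <- NA_real_
  i <- 1
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      run_end <- if (j < n) time_h[j + 1] else time_h[j]  # break time or last obs
      if (run_end - time_h[i] >= sustain_h) {
        onset <- time_h[i]
        break
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(onset_time_h = onset, is_day1 = !is.na(onset) && onset < 24)
}

#' Label first-day ARDS from diagnosis codes and oxygenation time series
#'
#' A patient is a case (endpoint 1) when they carry a qualifying ARDS
#' diagnosis code AND the Horowitz index shows a sustained (>= `sustain_h`)
#' drop below `threshold` with onset during the first day. Patients without a
#' qualifying code, and coded patients whose onset is later than the first
#' day, are controls (endpoint 0). Patients lacking PEEP, FiO2 or PaO2
#' measurements in the first `window_h` hours cannot be assessed and are
#' dropped (counted as excluded). The Horowitz series is built at PaO2
#' measurement times using the most recent FiO2 value (LOCF); only the
#' oxygenation component of the Berlin definition is evaluated.
#'
#' @param cohort Cohort tibble with a `codes` list-column.
#' @param series Long time-series tibble (`patient_id`, `parameter`,
#'   `time_h`, `value`) with parameters named (case-insensitively) `pao2`,
#'   `fio2`, `peep`.
#' @param code_systems Named list mapping site id to a character vector of
#'   qualifying codes (for example ICD-10 `"J80"`, or the ICD-9 respiratory
#'   failure list `c("5185","51851","51852","51853","51882")`).
#' @param threshold,sustain_h Passed to [detect_onset()].
#' @param window_h Inclusion window for required measurements (default 24).
#' @return List with `cohort` (included patients with an `endpoint` column)
#'   and `counts` (per-site tibble of cases, uncoded controls, coded controls
#'   with late or no onset, and excluded patients).
#' @export
assign_ards_labels <- function(cohort, series, code_systems,
                               threshold = 300, sustain_h = 24, window_h = 24) {
  site <- cohort$site[1]
  if (!site %in% names(code_systems)) {
    abort(paste0("no diagnosis-code list configured for site '", site, "'"))
  }
  if (is.null(cohort[["codes"]])) abort("cohort has no `codes` column")
  qualifying <- code_systems[[site]]
  series <- check_timeseries(series)
  series$parameter <- tolower(series$parameter)

  per_patient <- split(series, series$patient_id)
  status <- vapply(cohort$patient_id, function(pid) {
    s <- per_patient[[pid]]
    if (is.null(s)) return("excluded")
    firstday <- s[s$time_h < window_h, ]
    if (!all(c("pao2", "fio2", "peep") %in% firstday$parameter)) return("excluded")
    pao2 <- s[s$parameter == "pao2", ]
    fio2 <- s[s$parameter == "fio2", ]
    fio2 <- fio2[order(fio2$time_h), ]
    # LOCF FiO2 at each PaO2 time
    pos <- findInterval(pao2$time_h, fio2$time_h)
    ok <- pos >= 1
    if (!any(ok)) return("excluded")
    hi <- horowitz_index(pao2$value[ok], fio2$value[pos[ok]])
    coded <- length(intersect(cohort$codes[[match(pid, cohort$patient_id)]],
                              qualifying)) > 0
    onset <- detect_onset(pao2$time_h[ok], hi, threshold = threshold,
                          sustain_h = sustain_h)
    if (coded && onset$is_day1) "case"
    else if (coded) "control_coded_late"
    else "control_uncoded"
  }, character(1))

  counts <- tibble(
    site = site,
    n_cases = sum(status == "case"),
    n_controls_uncoded = sum(status == "control_uncoded"),
    n_controls_coded_late = sum(status == "control_coded_late"),
    n_excluded = sum(status == "excluded")
  )
  kept <- cohort[status != "excluded", ]
  kept$endpoint <- as.integer(status[status != "excluded"] == "case")
  list(cohort = kept, counts = counts)
}

#' Cross-site endpoint generalization matrix
#'
#' Trains one random-forest endpoint classifier per site (stratified 80/20
#' internal split, balanced class weights, grid search with stratified 5-fold
#' cross-validation on the train split) and evaluates every model on every
#' site. The matrix diagonal is each model's held-out internal test ROC AUC;
#' off-diagonal entry (r, c) is the AUC of site r's model on the whole of
#' site c's cohort (the external site contributes no training data, so no
#' split is taken there). The drop from diagonal to off-diagonal measures
#' transportability.
#'
#' @param cohorts List of cohort tibbles with binary `endpoint` columns and a
#'   shared, fully imputed feature set.
#' @param seed Integer seed.
#' @param grid Random-forest hyperparameter grid (tibble with `num_trees`,
#'   `max_depth`; 0 = unbounded depth).
#' @param split_prop Internal train fraction (default 0.8).
#' @return Object of class `hs_cross_prediction`: list with `auc` matrix
#'   (rows = training site, columns = evaluation site), `sites`, and `meta`.
#' @export
cross_predict <- function(cohorts, seed = 1,
                          grid = default_grids()[["random-forest"]],
                          split_prop = 0.8) {
  sites <- vapply(cohorts, function(co) co$site[1], character(1))
  names(cohorts) <- sites
  features <- cohort_features(cohorts[[1]])
  for (co in cohorts) {
    if (is.null(co[["endpoint"]])) abort(paste0("site '", co$site[1], "' has no endpoint"))
    if (length(unique(co$endpoint)) != 2) {
      abort(paste0("site '", co$site[1], "' has a single endpoint class"))
    }
    if (!setequal(cohort_features(co), features)) abort("cohorts must share one feature set")
    check_prepared(co, features)
  }
  auc <- matrix(NA_real_, length(sites), length(sites),
                dimnames = list(train = sites, test = sites))
  for (r in sites) {
    co <- cohorts[[r]]
    x <- as.matrix(co[, features])
    y <- co$endpoint
    r_seed <- derive_seed(seed, paste0("site-", r))
    train <- stratified_split(y, prop = split_prop, seed = derive_seed(r_seed, "split"))
    gs <- cv_grid_search("random-forest", x[train, , drop = FALSE], y[train],
                         grid, seed = r_seed)
    model <- hs_fit("random-forest", x[train, , drop = FALSE], y[train],
                    gs$params, seed = derive_seed(r_seed, "refit"))
    auc[r, r] <- auc_score(hs_score(model, x[!train, , drop = FALSE]), y[!train])
    for (cc in setdiff(sites, r)) {
      ext <- cohorts[[cc]]
      auc[r, cc] <- auc_score(hs_score(model, as.matrix(ext[, features])),
                              ext$endpoint)
    }
  }
  structure(list(auc = auc, sites = sites,
                 meta = list(seed = seed, grid = grid, split_prop = split_prop)),
            class = "hs_cross_prediction")
}

#' @export
print.hs_cross_prediction <- function(x, ...) {
  cat("<hs_cross_prediction> ROC AUC, rows = training site, columns = evaluation site\n")
  print(round(x$auc, 3))
  invisible(x)
}
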