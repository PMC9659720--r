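#' Cohort tables
#'
#' A cohort is an ordinary tibble with one row per patient and a small set of
#' reserved columns: `site` (site identifier, constant within a cohort),
#' `patient_id` (unique within a site), an optional binary `endpoint`, and an
#' optional `codes` list-column of diagnosis-code character vectors. Every
#' other column is a numeric feature. All pipeline functions take and return
#' tibbles of this shape, so the usual dplyr verbs apply between stages.
#'
#' @param data A data frame with the columns described above.
#' @param site Site label to attach when `data` has no `site` column.
#' @return A validated cohort tibble.
#' @examples
#' as_cohort(tibble::tibble(patient_id = c("p1", "p2"), hr = c(80, 95)), site = "A")
#' @export
as_cohort <- function(data, site = NULL) {
  data <- as_tibble(data)
  if (!is.null(site)) data$site <- as.character(site)
  if (is.null(data[["site"]])) abort("cohort needs a `site` column or a `site` argument")
  if (is.null(data[["patient_id"]])) abort("cohort needs a `patient_id` column")
  data$site <- as.character(data$site)
  data$patient_id <- as.character(data$patient_id)
  dup <- unique(data$patient_id[duplicated(data$patient_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate patient ids in site '", data$site[1], "': ",
                 paste(dup, collapse = ", ")))
  }
  if (!is.null(data[["endpoint"]])) {
    ep <- data[["endpoint"]]
    if (!all(ep %in% c(0, 1)) || anyNA(ep)) {
      abort("`endpoint` must be 0/1 with no missing values")
    }
    data$endpoint <- as.integer(ep)
  }
  for (f in cohort_features(data)) {
    if (!is.numeric(data[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[f]])))) &
                     !is.na(data[[f]]))
      abort(paste0("feature column '", f, "' is not numeric (e.g. row ",
                   if (length(bad)) bad[1] else "?", ")"))
    }
  }
  data[, c("site", "patient_id",
           intersect(c("endpoint", "codes"), names(data)),
           cohort_features(data))]
}

#' @rdname as_cohort
#' @export
cohort_features <- function(data) {
  setdiff(names(data), c("site", "patient_id", "endpoint", "codes"))
}

#' Read a per-site cohort table from CSV or Parquet
#'
#' @param path Path to a CSV or Parquet file, one row per patient.
#' @param schema Named list mapping column roles to column names in the file:
#'   `site`, `patient_id`, and optionally `endpoint`, `codes` and `features`
#'   (character vector; defaults to every remaining column). The `codes`
#'   column holds `;`-separated diagnosis codes.
#' @param site Site label used when the file carries no site column.
#' @return A cohort tibble (see [as_cohort()]) with rows and feature columns
#'   in file order. Cells that fail to parse as numbers are rejected;
#'   missing entries (`NA`, empty) are preserved as `NA`.
#' @export
load_cohort <- function(path, schema = list(), site = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    raw <- as_tibble(arrow::read_parquet(path))
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
  }
  role <- function(r, default = NULL) schema[[r]] %||% default
  out <- tibble(.rows = nrow(raw))
  pid_col <- role("patient_id", "patient_id")
  if (!pid_col %in% names(raw)) abort(paste0("patient-id column '", pid_col, "' not in file"))
  out$patient_id <- as.character(raw[[pid_col]])
  site_col <- role("site", if ("site" %in% names(raw)) "site" else NULL)
  if (!is.null(site_col) && site_col %in% names(raw)) out$site <- as.character(raw[[site_col]])
  used <- c(pid_col, site_col)
  if (!is.null(role("endpoint")) && role("endpoint") %in% names(raw)) {
    out$endpoint <- raw[[role("endpoint")]]
    used <- c(used, role("endpoint"))
  }
  if (!is.null(role("codes")) && role("codes") %in% names(raw)) {
    raw_codes <- as.character(raw[[role("codes")]])
    raw_codes[is.na(raw_codes)] <- ""
    out$codes <- lapply(strsplit(raw_codes, ";", fixed = TRUE),
                        function(x) trimws(x[nzchar(trimws(x))]))
    used <- c(used, role("codes"))
  }
  feats <- role("features", setdiff(names(raw), used))
  missing_feats <- setdiff(feats, names(raw))
  if (length(missing_feats)) {
    abort(paste0("feature columns not in file: ", paste(missing_feats, collapse = ", ")))
  }
  for (f in feats) {
    col <- raw[[f]]
    if (is.character(col)) {
      col[col %in% c("", "NA", "NaN")] <- NA
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(paste0("non-numeric value in feature column '", f, "', row ", bad[1],
                     " ('", col[bad[1]], "')"))
      }
      col <- num
    }
    if (!is.numeric(col)) abort(paste0("feature column '", f, "' is not numeric"))
    out[[f]] <- as.numeric(col)
  }
  as_cohort(out, site = site)
}

check_timeseries <- function(records) {
  records <- as_tibble(records)
  need <- c("patient_id", "parameter", "time_h", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("time-series records need columns: ", paste(miss, collapse = ", ")))
  if (nrow(records) > 0) {
    if (any(!is.finite(records$time_h)) || any(records$time_h < 0)) {
      abort("`time_h` must be finite and non-negative")
    }
    if (any(is.na(records$parameter) | !nzchar(records$parameter))) {
      abort("`parameter` must be non-empty")
    }
  }
  records
}

#' First-day median aggregation of long-format time series
#'
#' Collapses per-patient time-series records to one row per patient, each
#' feature being the median of that parameter's values recorded strictly
#' before `window_h` hours from admission (half-open window `[0, window_h)`).
#' Patients with no in-window value for a parameter get a missing entry.
#'
#' @param records Tibble with columns `patient_id`, `parameter`, `time_h`
#'   (hours from ICU admission), `value`.
#' @param window_h Aggregation window in hours (default 24, the first day).
#' @param site Optional site label for the resulting cohort.
#' @return A cohort tibble with one column per parameter.
#' @export
aggregate_first_day <- function(records, window_h = 24, site = "site") {
  if (window_h <= 0) abort("`window_h` must be positive")
  records <- check_timeseries(records)
  if (nrow(records) == 0) {
    return(as_cohort(tibble(patient_id = character()), site = site))
  }
  wide <- records %>%
    dplyr::filter(.data$time_h < window_h) %>%
    dplyr::group_by(.data$patient_id, .data$parameter) %>%
    dplyr::summarise(value = median(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  # keep patients whose every record falls outside the window as all-missing rows
  all_pat <- unique(records$patient_id)
  wide <- dplyr::left_join(tibble(patient_id = all_pat), wide, by = "patient_id")
  as_cohort(wide, site = site)
}

#' Drop sparsely observed features
#'
#' Removes features missing in more than `max_missing_frac` of patients;
#' a feature missing in exactly that fraction is retained (strict inequality
#' for dropping). Feature order is preserved. Idempotent.
#'
#' @param cohort A cohort tibble.
#' @param max_missing_frac Highest tolerated missing fraction (default 0.3).
#' @return The cohort with sparse features removed.
#' @export
filter_sparse_features <- function(cohort, max_missing_frac = 0.3) {
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    abort("`max_missing_frac` must be in [0, 1]")
  }
  feats <- cohort_features(cohort)
  keep <- feats[vapply(feats, function(f) mean(is.na(cohort[[f]])) <= max_missing_frac,
                       logical(1))]
  cohort[, c(setdiff(names(cohort), feats), keep)]
}

#' Restrict cohorts to their common feature set
#'
#' @param cohorts A list of cohort tibbles (at least two).
#' @return The list with every cohort restricted to the set intersection of
#'   feature names, columns in the order of the first cohort.
#' @export
intersect_features <- function(cohorts) {
  if (length(cohorts) < 2) abort("need at least two cohorts")
  sets <- lapply(cohorts, cohort_features)
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0) {
    desc <- vapply(seq_along(cohorts), function(i) {
      paste0(cohorts[[i]]$site[1], ": {", paste(sets[[i]], collapse = ", "), "}")
    }, character(1))
    abort(paste0("cohorts share no features; per-cohort feature sets:\n",
                 paste(desc, collapse = "\n")))
  }
  shared <- sets[[1]][sets[[1]] %in% shared]  # canonical order: first cohort
  lapply(cohorts, function(co) co[, c(setdiff(names(co), cohort_features(co)), shared)])
}

#' Impute missing entries with the site-wide feature median
#'
#' Each missing entry is replaced by the median of that feature's observed
#' values within this cohort only; observed entries are untouched.
#'
#' @param cohort A cohort tibble.
#' @return The cohort with no remaining missing feature entries.
#' @export
impute_site_median <- function(cohort) {
  for (f in cohort_features(cohort)) {
    x <- cohort[[f]]
    if (all(is.na(x))) {
      abort(paste0("feature '", f, "' is fully missing in site '",
                   cohort$site[1], "'; cannot impute"))
    }
    x[is.na(x)] <- median(x, na.rm = TRUE)
    cohort[[f]] <- x
  }
  cohort
}

#' Prepare a set of cohorts for coverage analysis
#'
#' Convenience composition of the standard preparation order: per-site sparse
#' feature removal, cross-site feature intersection, then per-site median
#' imputation.
#'
#' @param cohorts List of cohort tibbles.
#' @param max_missing_frac Passed to [filter_sparse_features()].
#' @param intersect_first If `TRUE`, intersect features before the sparsity
#'   filter instead of after.
#' @return List of prepared cohort tibbles sharing one feature set, imputed.
#' @export
prepare_cohorts <- function(cohorts, max_missing_frac = 0.3, intersect_first = FALSE) {
  if (intersect_first) cohorts <- intersect_features(cohorts)
  cohorts <- lapply(cohorts, filter_sparse_features, max_missing_frac = max_missing_frac)
  cohorts <- intersect_features(cohorts)
  lapply(cohorts, impute_site_median)
}
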