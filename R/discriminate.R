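#' Stack two cohorts into a site-origin classification dataset
#'
#' @param A,B Cohort tibbles with identical feature sets and no missing
#'   values. Rows of `A` get label 0, rows of `B` label 1.
#' @return List with `x` (feature tibble), `y` (integer 0/1 labels) and
#'   `provenance` (site and patient id per row).
#' @export
make_origin_dataset <- function(A, B) {
  fa <- cohort_features(A); fb <- cohort_features(B)
  if (!setequal(fa, fb)) {
    abort(paste0("feature sets differ: only in A {",
                 paste(setdiff(fa, fb), collapse = ", "), "}, only in B {",
                 paste(setdiff(fb, fa), collapse = ", "), "}"))
  }
  check_prepared(A, fa); check_prepared(B, fa)
  list(
    x = dplyr::bind_rows(A[, fa], B[, fa]),
    y = c(rep(0L, nrow(A)), rep(1L, nrow(B))),
    provenance = tibble(site = c(A$site, B$site),
                        patient_id = c(A$patient_id, B$patient_id))
  )
}

#' Train site-origin classifiers with cross-validated grid search
#'
#' For each model family: stratified 80/20 train/test split, grid search
#' maximizing ROC AUC under stratified 5-fold cross-validation on the train
#' split, refit with the best configuration on the full train split, and
#' evaluation on the held-out test split (ROC AUC, precision, recall, F1).
#' Logistic regression, random forest and the SVM use balanced class weights;
#' AdaBoost does not. A high test AUC indicates diverging underlying
#' distributions between the two sites even when their convex hulls overlap.
#'
#' @param x Feature data frame or matrix.
#' @param y Integer 0/1 site labels (both classes present).
#' @param families Subset of
#'   `c("logistic-regression", "random-forest", "support-vector-machine", "adaboost")`.
#' @param grids Named list of hyperparameter grids; see [default_grids()].
#' @param seed Integer seed; identical seeds give identical reports.
#' @param split_prop Train fraction of the stratified split (default 0.8).
#' @param feature_variant Label recorded in the report ("all" or
#'   "excluding-flagged").
#' @return Tibble with one row per family: `model_family`, `feature_variant`,
#'   `cv_auc`, `test_auc`, `precision`, `recall`, `f1`, `params` (list
#'   column), `seed`, `n_train`, `n_test`.
#' @export
train_origin_classifiers <- function(x, y, families = hs_families(),
                                     grids = default_grids(), seed = 1,
                                     split_prop = 0.8,
                                     feature_variant = "all") {
  x <- as_tibble(x)
  y <- as.integer(y)
  if (length(unique(y)) != 2) abort("`y` must contain both classes")
  bad <- setdiff(families, hs_families())
  if (length(bad)) abort(paste0("unknown families: ", paste(bad, collapse = ", ")))
  train <- stratified_split(y, prop = split_prop, seed = derive_seed(seed, "split"))
  xm <- as.matrix(x)
  purrr::map_dfr(families, function(fam) {
    fam_seed <- derive_seed(seed, paste0("family-", fam))
    gs <- cv_grid_search(fam, xm[train, , drop = FALSE], y[train],
                         grids[[fam]], seed = fam_seed)
    model <- hs_fit(fam, xm[train, , drop = FALSE], y[train], gs$params,
                    seed = derive_seed(fam_seed, "refit"))
    scores <- hs_score(model, xm[!train, , drop = FALSE])
    pred <- hs_predict_class(model, xm[!train, , drop = FALSE])
    dplyr::bind_cols(
      tibble(model_family = fam, feature_variant = feature_variant,
             cv_auc = gs$cv_auc),
      binary_metrics(scores, pred, y[!train]),
      tibble(params = list(gs$params), seed = as.integer(seed %% 2147483647),
             n_train = sum(train), n_test = sum(!train))
    )
  })
}

#' Retrain origin classifiers after removing low-coverage features
#'
#' Identical protocol to [train_origin_classifiers()] on the feature set
#' minus the union of features flagged in either direction of the pair.
#' Comparing the two reports shows whether site discrimination was driven by
#' the low-coverage (support-shifted) features or by broader distributional
#' differences.
#'
#' @param A,B Cohort tibbles with identical feature sets, imputed.
#' @param flagged Character vector of features to exclude (typically
#'   [flagged_union()] of the pair); at least 2 features must remain.
#' @inheritParams train_origin_classifiers
#' @return Report tibble with `feature_variant = "excluding-flagged"`.
#' @export
rerun_excluding_flagged <- function(A, B, flagged, families = hs_families(),
                                    grids = default_grids(), seed = 1,
                                    split_prop = 0.8) {
  feats <- cohort_features(A)
  keep <- setdiff(feats, flagged)
  if (length(keep) < 2) {
    abort(paste0("only ", length(keep), " feature(s) would remain after excluding ",
                 length(flagged), " flagged feature(s); need at least 2"))
  }
  ds <- make_origin_dataset(A[, c(setdiff(names(A), feats), keep)],
                            B[, c(setdiff(names(B), feats), keep)])
  train_origin_classifiers(ds$x, ds$y, families = families, grids = grids,
                           seed = seed, split_prop = split_prop,
                           feature_variant = "excluding-flagged")
}

#' Origin discrimination for one site pair, both feature variants
#'
#' @param A,B Prepared cohort tibbles.
#' @param flagged Features to exclude in the second run; when `NULL` or
#'   empty, only the all-features run is performed.
#' @inheritParams train_origin_classifiers
#' @return Report tibble with `site_a`/`site_b` columns; the row with the
#'   highest test AUC per variant is marked `best = TRUE`.
#' @export
discriminate_sites <- function(A, B, flagged = NULL, families = hs_families(),
                               grids = default_grids(), seed = 1,
                               split_prop = 0.8) {
  ds <- make_origin_dataset(A, B)
  rep_all <- train_origin_classifiers(ds$x, ds$y, families = families,
                                      grids = grids, seed = seed,
                                      split_prop = split_prop)
  reports <- rep_all
  if (!is.null(flagged) && length(flagged) > 0) {
    reports <- dplyr::bind_rows(
      reports,
      rerun_excluding_flagged(A, B, flagged, families = families,
                              grids = grids, seed = seed,
                              split_prop = split_prop))
  }
  reports %>%
    dplyr::mutate(site_a = A$site[1], site_b = B$site[1], .before = 1) %>%
    dplyr::group_by(.data$feature_variant) %>%
    dplyr::mutate(best = .data$test_auc == max(.data$test_auc)) %>%
    dplyr::ungroup()
}
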