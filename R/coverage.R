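feature_matrix <- function(cohort, features) {
  m <- as.matrix(cohort[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

check_prepared <- function(cohort, features) {
  miss <- setdiff(features, cohort_features(cohort))
  if (length(miss)) {
    abort(paste0("site '", cohort$site[1], "' lacks features: ", paste(miss, collapse = ", ")))
  }
  if (anyNA(cohort[, features])) {
    abort(paste0("site '", cohort$site[1], "' has missing feature values; impute first"))
  }
  invisible(cohort)
}

#' Bootstrap convex-hull coverage for one feature pair
#'
#' For one ordered site pair and one 2D feature projection, estimates the
#' fraction of the query site's patients that fall inside the convex hull of
#' the hull site's patients. Each bootstrap replicate resamples both cohorts'
#' rows with replacement at original size, removes density outliers from the
#' hull-forming sample with DBSCAN (query points are never removed), builds
#' the hull, and scores membership. Coordinates are z-scored per feature with
#' the pooled statistics of the two original cohorts, so the DBSCAN radius
#' and geometric tolerance are scale-free.
#'
#' @param query_cohort,hull_cohort Cohort tibbles sharing the pair's
#'   features, with no missing values.
#' @param feature_pair Character vector of two feature names `(i, j)`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @param denoise Apply DBSCAN denoising to the hull-forming sample.
#' @param resample Bootstrap-resample the cohorts each replicate; when
#'   `FALSE` the original rows are used in every replicate.
#' @param hull_only_resample Resample only the hull-forming cohort
#'   (sensitivity analysis); the query cohort is used as-is.
#' @param min_samples,eps,eps_prob DBSCAN parameters; `eps` defaults to the
#'   `eps_prob` percentile of 5-nearest-neighbour distances of the hull
#'   site's standardized points, computed once on the original sample.
#' @param tol Membership tolerance on standardized coordinates.
#' @return One-row tibble: `query_site`, `hull_site`, `feature_i`,
#'   `feature_j`, `mean_coverage`, `sd_coverage`, `n_boot`, `seed`.
#'   Degenerate hulls raise an error annotated with the replicate index
#'   (condition class `hs_degenerate_hull`).
#' @export
bootstrap_pair_coverage <- function(query_cohort, hull_cohort, feature_pair,
                                    n_boot = 100, seed = 1,
                                    denoise = TRUE, resample = TRUE,
                                    hull_only_resample = FALSE,
                                    min_samples = 5, eps = NULL, eps_prob = 0.9,
                                    tol = 1e-9) {
  stopifnot(length(feature_pair) == 2, n_boot >= 1)
  check_prepared(query_cohort, feature_pair)
  check_prepared(hull_cohort, feature_pair)
  qm <- feature_matrix(query_cohort, feature_pair)
  hm <- feature_matrix(hull_cohort, feature_pair)
  if (nrow(qm) == 0) abort("query cohort is empty")

  # pooled standardization of the 2D projection
  pooled <- rbind(qm, hm)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  qm <- sweep(sweep(qm, 2, ctr), 2, scl, "/")
  hm <- sweep(sweep(hm, 2, ctr), 2, scl, "/")
  if (denoise && is.null(eps)) eps <- dbscan_eps(hm, k = 5, prob = eps_prob)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  cov <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    qb <- if (resample && !hull_only_resample) {
      qm[sample.int(nrow(qm), replace = TRUE), , drop = FALSE]
    } else qm
    hb <- if (resample || hull_only_resample) {
      hm[sample.int(nrow(hm), replace = TRUE), , drop = FALSE]
    } else hm
    res <- tryCatch({
      if (denoise) hb <- denoise_pair(hb, eps = eps, min_samples = min_samples)
      pair_coverage(qb, build_hull(hb, feature_pair), tol = tol)
    }, hs_degenerate_hull = function(e) {
      abort(paste0(conditionMessage(e), " (feature pair ",
                   paste(feature_pair, collapse = " x "), ", replicate ", b, ")"),
            class = "hs_degenerate_hull")
    })
    cov[b] <- res
  }
  tibble(
    query_site = query_cohort$site[1], hull_site = hull_cohort$site[1],
    feature_i = feature_pair[1], feature_j = feature_pair[2],
    mean_coverage = mean(cov),
    sd_coverage = if (n_boot == 1) 0 else sd(cov),
    n_boot = as.integer(n_boot), seed = as.integer(seed %% 2147483647)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Flag low-coverage features by the Q1 - 1.5 IQR rule
#'
#' @param per_feature Named numeric vector of per-feature median coverages
#'   (at least 4 values so that quartiles are meaningful).
#' @return List with `threshold` (Q1 minus 1.5 times the interquartile range,
#'   quartiles by linear interpolation) and `flagged` (names of features
#'   strictly below the threshold).
#' @export
flag_low_coverage <- function(per_feature) {
  vals <- per_feature[!is.na(per_feature)]
  if (length(vals) < 4) abort("need at least 4 features to compute quartile threshold")
  q <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  threshold <- q[1] - 1.5 * (q[2] - q[1])
  flagged <- names(vals)[vals < threshold]
  list(threshold = threshold, flagged = if (is.null(flagged)) character() else flagged)
}

#' Per-feature median coverage for one ordered site pair
#'
#' Aggregates the pairwise coverages of all 2D feature projections: each
#' feature's coverage is the median of the coverages of all pairs containing
#' it. Features whose coverage falls strictly below Q1 - 1.5 IQR of the
#' per-feature distribution are flagged as low-coverage.
#'
#' @param pair_coverages Tibble of [bootstrap_pair_coverage()] rows for one
#'   ordered site pair.
#' @param features Character vector of all features; defaults to those seen
#'   in `pair_coverages`.
#' @param skipped Optional tibble (`feature_i`, `feature_j`) of feature pairs
#'   skipped as degenerate; medians are taken over surviving pairs. A pair
#'   neither present nor skipped is an error.
#' @return Tibble: `query_site`, `hull_site`, `feature`, `coverage`,
#'   `threshold`, `flagged`. With fewer than 4 features the threshold is `NA`
#'   and nothing is flagged. Features with no surviving pair get `NA`
#'   coverage.
#' @export
feature_coverage <- function(pair_coverages, features = NULL, skipped = NULL) {
  pc <- as_tibble(pair_coverages)
  if (length(unique(pc$query_site)) > 1 || length(unique(pc$hull_site)) > 1) {
    abort("`pair_coverages` must belong to a single ordered site pair")
  }
  if (is.null(features)) features <- unique(c(pc$feature_i, pc$feature_j))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  have <- key(pc$feature_i, pc$feature_j)
  skip <- if (!is.null(skipped) && nrow(skipped) > 0) {
    key(skipped$feature_i, skipped$feature_j)
  } else character()
  all_pairs <- combn(features, 2)
  want <- key(all_pairs[1, ], all_pairs[2, ])
  miss <- setdiff(want, c(have, skip))
  if (length(miss)) {
    abort(paste0("missing pair coverage for: ",
                 paste(gsub("\r", " x ", miss), collapse = ", ")))
  }
  per_feature <- vapply(features, function(f) {
    v <- pc$mean_coverage[pc$feature_i == f | pc$feature_j == f]
    if (length(v) == 0) NA_real_ else median(v)
  }, numeric(1))
  if (sum(!is.na(per_feature)) >= 4) {
    fl <- flag_low_coverage(per_feature)
    threshold <- fl$threshold
    flagged <- names(per_feature) %in% fl$flagged
  } else {
    threshold <- NA_real_
    flagged <- rep(FALSE, length(per_feature))
  }
  tibble(
    query_site = pc$query_site[1], hull_site = pc$hull_site[1],
    feature = features, coverage = unname(per_feature),
    threshold = threshold, flagged = flagged
  )
}

#' Per-feature coverage analysis for one ordered site pair
#'
#' Runs [bootstrap_pair_coverage()] over every pair of shared features for
#' one ordered (query, hull) site pair and aggregates with
#' [feature_coverage()]. Degenerate feature pairs are skipped and returned in
#' the `skipped` attribute.
#'
#' @inheritParams bootstrap_pair_coverage
#' @inheritParams coverage_matrix
#' @return The [feature_coverage()] tibble for this ordered pair, with the QC
#'   tibble of skipped pairs as attribute `"skipped"`.
#' @export
site_pair_coverage <- function(query_cohort, hull_cohort, n_boot = 100, seed = 1,
                               denoise = TRUE, resample = TRUE,
                               min_samples = 5, eps = NULL, eps_prob = 0.9,
                               tol = 1e-9) {
  features <- cohort_features(query_cohort)
  if (length(features) < 2) abort("need at least two features")
  q <- query_cohort$site[1]; h <- hull_cohort$site[1]
  pairs <- combn(features, 2)
  rows <- list(); skipped <- list()
  for (k in seq_len(ncol(pairs))) {
    fp <- pairs[, k]
    sub_seed <- derive_seed(seed, paste(q, h, fp[1], fp[2], sep = "|"))
    res <- tryCatch(
      bootstrap_pair_coverage(query_cohort, hull_cohort, fp,
                              n_boot = n_boot, seed = sub_seed,
                              denoise = denoise, resample = resample,
                              min_samples = min_samples, eps = eps,
                              eps_prob = eps_prob, tol = tol),
      hs_degenerate_hull = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1]] <- tibble(
        query_site = q, hull_site = h,
        feature_i = fp[1], feature_j = fp[2], reason = res)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) {
    abort(paste0("every feature pair degenerate for (", q, ", ", h, ")"))
  }
  skip_tbl <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble(query_site = character(), hull_site = character(),
           feature_i = character(), feature_j = character(), reason = character())
  fc <- feature_coverage(dplyr::bind_rows(rows), features = features,
                         skipped = skip_tbl)
  attr(fc, "skipped") <- skip_tbl
  fc
}

#' Site-by-site mean convex-hull coverage matrix
#'
#' Runs the full pairwise coverage analysis over every ordered pair of sites
#' and every pair of shared features: bootstrap coverage per 2D projection,
#' per-feature medians, low-coverage flags, and the mean coverage over
#' features as the site-pair summary. The matrix diagonal is 1 by convention.
#' Feature pairs with degenerate hulls (for example a protocol-constant
#' feature) are skipped and recorded in the QC log; aggregates are taken over
#' surviving pairs.
#'
#' @param cohorts List of prepared cohort tibbles (shared feature set, no
#'   missing values; see [prepare_cohorts()]).
#' @inheritParams bootstrap_pair_coverage
#' @return An object of class `hs_coverage_matrix`: a list with
#'   `mean_coverage` (matrix, rows = query site, columns = hull site),
#'   `per_feature` (long tibble with thresholds and flags), `flagged`
#'   (flagged subset), `qc` (skipped feature pairs), and `meta` (seed,
#'   n_boot, DBSCAN parameters, quantile convention).
#' @export
coverage_matrix <- function(cohorts, n_boot = 100, seed = 1,
                            denoise = TRUE, resample = TRUE,
                            min_samples = 5, eps = NULL, eps_prob = 0.9,
                            tol = 1e-9) {
  if (length(cohorts) < 2) abort("need at least two cohorts")
  sites <- vapply(cohorts, function(co) co$site[1], character(1))
  if (anyDuplicated(sites)) abort("duplicate site ids among cohorts")
  names(cohorts) <- sites
  features <- cohort_features(cohorts[[1]])
  for (co in cohorts) {
    if (!identical(sort(cohort_features(co)), sort(features))) {
      abort("cohorts must share one feature set; run intersect_features() first")
    }
    check_prepared(co, features)
  }
  if (length(features) < 2) abort("need at least two features")

  mat <- matrix(1, length(sites), length(sites), dimnames = list(sites, sites))
  per_feature <- list()
  qc <- list()
  for (q in sites) {
    for (h in setdiff(sites, q)) {
      fc <- site_pair_coverage(cohorts[[q]], cohorts[[h]], n_boot = n_boot,
                               seed = seed, denoise = denoise,
                               resample = resample, min_samples = min_samples,
                               eps = eps, eps_prob = eps_prob, tol = tol)
      per_feature[[paste(q, h)]] <- fc
      skip_tbl <- attr(fc, "skipped")
      if (nrow(skip_tbl)) qc[[paste(q, h)]] <- skip_tbl
      mat[q, h] <- mean(fc$coverage, na.rm = TRUE)
    }
  }
  structure(list(
    sites = sites,
    mean_coverage = mat,
    per_feature = dplyr::bind_rows(per_feature),
    flagged = dplyr::bind_rows(per_feature) %>% dplyr::filter(.data$flagged),
    qc = if (length(qc)) dplyr::bind_rows(qc) else
      tibble(query_site = character(), hull_site = character(),
             feature_i = character(), feature_j = character(), reason = character()),
    meta = list(seed = seed, n_boot = n_boot, denoise = denoise,
                resample = resample, min_samples = min_samples,
                eps = eps, eps_prob = eps_prob, tol = tol,
                quantile_type = 7L)
  ), class = "hs_coverage_matrix")
}

#' @export
print.hs_coverage_matrix <- function(x, ...) {
  cat("<hs_coverage_matrix> ", length(x$sites), " sites, ",
      length(unique(x$per_feature$feature)), " features, n_boot = ",
      x$meta$n_boot, "\n", sep = "")
  print(round(x$mean_coverage, 3))
  nf <- nrow(x$flagged)
  if (nf) cat(nf, "low-coverage feature flags; see $flagged\n")
  invisible(x)
}

#' Union of flagged features over both directions of a site pair
#'
#' @param cm An `hs_coverage_matrix`.
#' @param site_a,site_b The two site ids.
#' @return Character vector of features flagged in either direction.
#' @export
flagged_union <- function(cm, site_a, site_b) {
  fl <- cm$flagged
  sel <- (fl$query_site == site_a & fl$hull_site == site_b) |
    (fl$query_site == site_b & fl$hull_site == site_a)
  unique(fl$feature[sel])
}
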