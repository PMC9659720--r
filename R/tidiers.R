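#' Tidy a coverage matrix into long form
#'
#' @param x An `hs_coverage_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per ordered site pair: `query_site`,
#'   `hull_site`, `mean_coverage` (diagonal entries included, fixed at 1).
#' @export
tidy.hs_coverage_matrix <- function(x, ...) {
  as_tibble(x$mean_coverage, rownames = "query_site") %>%
    tidyr::pivot_longer(-"query_site", names_to = "hull_site",
                        values_to = "mean_coverage")
}

#' One-row summary of a coverage analysis
#'
#' @inheritParams tidy.hs_coverage_matrix
#' @return Tibble with site/feature counts, the off-diagonal coverage range,
#'   flag and QC-skip counts.
#' @export
glance.hs_coverage_matrix <- function(x, ...) {
  off <- x$mean_coverage[row(x$mean_coverage) != col(x$mean_coverage)]
  tibble(
    n_sites = length(x$sites),
    n_features = length(unique(x$per_feature$feature)),
    n_boot = x$meta$n_boot,
    mean_coverage = mean(off),
    min_coverage = min(off),
    n_flagged = nrow(x$flagged),
    n_skipped_pairs = nrow(x$qc)
  )
}

#' Tidy a cross-prediction matrix into long form
#'
#' @param x An `hs_cross_prediction`.
#' @param ... Unused.
#' @return Tibble with `train_site`, `test_site`, `auc`, `internal` (whether
#'   the entry is the diagonal held-out performance), and `drop`
#'   (internal minus this entry, for external rows).
#' @export
tidy.hs_cross_prediction <- function(x, ...) {
  as_tibble(x$auc, rownames = "train_site") %>%
    tidyr::pivot_longer(-"train_site", names_to = "test_site", values_to = "auc") %>%
    dplyr::group_by(.data$train_site) %>%
    dplyr::mutate(internal = .data$train_site == .data$test_site,
                  drop = .data$auc[.data$internal] - .data$auc) %>%
    dplyr::ungroup()
}

#' One-row summary of a cross-prediction matrix
#'
#' @inheritParams tidy.hs_cross_prediction
#' @return Tibble with mean internal/external AUC and the largest
#'   internal-to-external drop with its site pair.
#' @export
glance.hs_cross_prediction <- function(x, ...) {
  td <- tidy(x)
  ext <- td[!td$internal, ]
  worst <- ext[which.max(ext$drop), ]
  tibble(
    n_sites = length(x$sites),
    mean_internal_auc = mean(td$auc[td$internal]),
    mean_external_auc = mean(ext$auc),
    max_drop = worst$drop,
    max_drop_train_site = worst$train_site,
    max_drop_test_site = worst$test_site
  )
}
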