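as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 2) abort("points must be n x 2")
  storage.mode(points) <- "double"
  points
}

#' Default DBSCAN radius for a 2D point cloud
#'
#' The 90th percentile of 5-nearest-neighbour distances, a scale-free choice
#' intended to be computed on standardized (z-scored) coordinates.
#'
#' @param points n x 2 numeric matrix.
#' @param k Neighbour rank (default 5).
#' @param prob Percentile of the k-NN distance distribution (default 0.9).
#' @return A positive radius.
#' @export
dbscan_eps <- function(points, k = 5, prob = 0.9) {
  points <- as_point_matrix(points)
  d <- cpp_knn_dist(points, as.integer(k))
  eps <- as.numeric(quantile(d, prob, na.rm = TRUE, type = 7))
  if (!is.finite(eps) || eps <= 0) eps <- max(d[is.finite(d)], 1e-8)
  eps
}

#' Remove density outliers with DBSCAN before hull construction
#'
#' Keeps the points that belong to some density cluster (core points and
#' points within `eps` of a core point); DBSCAN noise points are dropped.
#' Neighbour counts include the point itself, so `min_samples = 1` retains
#' everything.
#'
#' @param points n x 2 numeric matrix (rows are points).
#' @param eps Neighbourhood radius; defaults to [dbscan_eps()] of the input.
#' @param min_samples Minimum neighbourhood size for a core point (default 5).
#' @return The retained subset of `points` (row order preserved), with the
#'   logical retention mask in attribute `"retained"`.
#' @export
denoise_pair <- function(points, eps = NULL, min_samples = 5) {
  points <- as_point_matrix(points)
  if (nrow(points) == 0) abort("cannot denoise an empty point set")
  if (min_samples < 1) abort("`min_samples` must be >= 1")
  if (is.null(eps)) eps <- dbscan_eps(points)
  if (eps <= 0) abort("`eps` must be positive")
  keep <- cpp_dbscan_retain(points, eps, as.integer(min_samples))
  if (!any(keep)) {
    abort(paste0("DBSCAN classified all ", nrow(points), " points as noise; ",
                 "increase eps (", signif(eps, 3), ") or decrease min_samples (",
                 min_samples, ")"))
  }
  out <- points[keep, , drop = FALSE]
  attr(out, "retained") <- keep
  out
}

#' Build the 2D convex hull of a point set
#'
#' @param points n x 2 numeric matrix.
#' @param feature_pair Optional character pair naming the projection axes.
#' @return An object of class `hs_hull`: counterclockwise vertex matrix plus
#'   the feature pair. Fewer than 3 distinct points, or an all-collinear set,
#'   raises a degenerate-hull error (condition class `hs_degenerate_hull`).
#' @export
build_hull <- function(points, feature_pair = NULL) {
  points <- as_point_matrix(points)
  degenerate <- function(msg) {
    abort(msg, class = "hs_degenerate_hull")
  }
  if (nrow(points) < 3) degenerate("degenerate hull: fewer than 3 points")
  idx <- grDevices::chull(points[, 1], points[, 2])
  if (length(idx) < 3) degenerate("degenerate hull: fewer than 3 distinct points")
  v <- points[idx, , drop = FALSE]
  # signed area: positive for counterclockwise vertex order
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] - v[c(2:nrow(v), 1), 1] * v[, 2])
  span <- max(apply(v, 2, function(z) diff(range(z))), 1)
  if (nrow(v) < 3 || abs(area2) < 1e-12 * span^2) {
    degenerate("degenerate hull: points are collinear")
  }
  if (area2 < 0) v <- v[nrow(v):1, , drop = FALSE]
  structure(list(vertices = v, feature_pair = feature_pair), class = "hs_hull")
}

#' @export
print.hs_hull <- function(x, ...) {
  cat("<hs_hull> ", nrow(x$vertices), " vertices",
      if (!is.null(x$feature_pair)) paste0(" (", paste(x$feature_pair, collapse = " x "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Convex-hull membership of 2D points
#'
#' Half-plane sign test against the counterclockwise hull edges; points on
#' the boundary count as inside, with absolute tolerance `tol` on the signed
#' point-to-edge distance.
#'
#' @param points n x 2 numeric matrix of query points.
#' @param hull An `hs_hull` from [build_hull()].
#' @param tol Geometric tolerance (default 1e-9, intended for standardized
#'   coordinates).
#' @return Logical vector, one entry per query point.
#' @export
in_hull <- function(points, hull, tol = 1e-9) {
  if (!inherits(hull, "hs_hull")) abort("`hull` must be an hs_hull")
  points <- as_point_matrix(points)
  cpp_in_hull(points, hull$vertices, tol)
}

#' Fraction of query points covered by a convex hull
#'
#' The coverage of a query dataset by a reference hull: the share of query
#' points lying inside or on the hull polygon.
#'
#' @inheritParams in_hull
#' @param query n x 2 numeric matrix of query points (non-empty).
#' @return A fraction in `[0, 1]`.
#' @export
pair_coverage <- function(query, hull, tol = 1e-9) {
  query <- as_point_matrix(query)
  if (nrow(query) == 0) abort("`query` must be non-empty")
  mean(in_hull(query, hull, tol = tol))
}
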