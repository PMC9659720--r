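# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Half-plane sign test, plain R: point inside a convex polygon iff it lies on
# the same (left, after CCW orientation) side of every edge.
oracle_in_hull <- function(points, vertices, tol = 1e-9) {
  # orient counterclockwise (positive signed area) first
  nx <- c(2:nrow(vertices), 1)
  area2 <- sum(vertices[, 1] * vertices[nx, 2] - vertices[nx, 1] * vertices[, 2])
  if (area2 < 0) vertices <- vertices[nrow(vertices):1, , drop = FALSE]
  n <- nrow(points)
  m <- nrow(vertices)
  inside <- rep(TRUE, n)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1 else k + 1
    ex <- vertices[k2, 1] - vertices[k, 1]
    ey <- vertices[k2, 2] - vertices[k, 2]
    cr <- ex * (points[, 2] - vertices[k, 2]) - ey * (points[, 1] - vertices[k, 1])
    inside <- inside & (cr >= -tol * sqrt(ex^2 + ey^2))
  }
  inside
}

# O(n^2) brute-force hull: a point is a hull vertex iff it lies outside the
# hull of all the other points.
oracle_hull_vertices <- function(points) {
  n <- nrow(points)
  is_vertex <- vapply(seq_len(n), function(i) {
    rest <- points[-i, , drop = FALSE]
    idx <- grDevices::chull(rest)
    !oracle_in_hull(points[i, , drop = FALSE], rest[idx, , drop = FALSE])
  }, logical(1))
  points[is_vertex, , drop = FALSE]
}

# Sort-and-middle median.
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Exhaustive onset scan: try every measurement time as a candidate onset and
# apply the sustained-below rule directly.
oracle_onset <- function(time_h, index, threshold = 300, sustain_h = 24) {
  o <- order(time_h)
  time_h <- time_h[o]; index <- index[o]
  n <- length(time_h)
  for (i in seq_len(n)) {
    if (index[i] >= threshold) next
    later <- which(time_h > time_h[i] & index >= threshold)
    break_t <- if (length(later)) time_h[min(later)] else NA_real_
    span <- (if (is.na(break_t)) time_h[n] else break_t) - time_h[i]
    if (span >= sustain_h) return(time_h[i])
  }
  NA_real_
}

sorted_pair_set <- function(m) {
  # canonical string form of a set of 2D points, for set equality tests
  sort(apply(round(m, 10), 1, paste, collapse = ","))
}
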