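# Internal classifier machinery shared by the origin-discrimination and
# cross-prediction modules: four model families with small hyperparameter
# grids, balanced class weights where the protocol calls for them, stratified
# splitting and 5-fold cross-validated grid search maximizing ROC AUC.

hs_families <- function() {
  c("logistic-regression", "random-forest", "support-vector-machine", "adaboost")
}

#' Default hyperparameter grids for the origin classifiers
#'
#' Deliberately small, desk-scale grids: ridge-logistic regularization
#' C in \{0.01, 0.1, 1, 10\}; random forest trees \{100, 300\} by max depth
#' \{unbounded, 10\}; RBF support vector machine cost \{0.1, 1, 10\};
#' AdaBoost \{50, 200\} stumps. Each grid is a tibble whose rows are
#' candidate configurations; supply your own to override.
#'
#' @return Named list of tibbles, one per model family.
#' @export
default_grids <- function() {
  list(
    "logistic-regression" = tibble(C = c(0.01, 0.1, 1, 10)),
    "random-forest" = tidyr::expand_grid(num_trees = c(100, 300), max_depth = c(0, 10)),
    "support-vector-machine" = tibble(cost = c(0.1, 1, 10)),
    "adaboost" = tibble(n_estimators = c(50, 200))
  )
}

balanced_class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  n <- length(y)
  c("0" = n / (2 * tab[["0"]]), "1" = n / (2 * tab[["1"]]))
}

stratified_split <- function(y, prop = 0.8, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  train <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    train[idx[seq_len(round(prop * length(idx)))]] <- TRUE
  }
  train
}

stratified_folds <- function(y, k = 5, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(paste0("class ", cls, " has fewer members (", length(idx),
                   ") than folds (", k, ")"))
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mann-Whitney ROC AUC with midrank tie handling.
auc_score <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

hs_fit <- function(family, x, y, params, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  model <- list(family = family, params = params, features = colnames(x))
  if (family %in% c("logistic-regression", "support-vector-machine")) {
    model$center <- colMeans(x)
    model$scale <- apply(x, 2, sd)
    model$scale[!is.finite(model$scale) | model$scale == 0] <- 1
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  bw <- balanced_class_weights(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  if (family == "logistic-regression") {
    lambda <- 1 / (nrow(x) * params$C)
    model$fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                                alpha = 0, lambda = lambda, standardize = FALSE,
                                weights = unname(bw[as.character(y)]))
    model$lambda <- lambda
  } else if (family == "random-forest") {
    model$fit <- ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      class.weights = unname(bw), probability = TRUE,
      seed = as.integer(seed %% 2147483647), num.threads = 1
    )
  } else if (family == "support-vector-machine") {
    model$fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                            cost = params$cost, class.weights = bw, scale = FALSE)
  } else if (family == "adaboost") {
    model$fit <- fit_adaboost(x, y, n_estimators = params$n_estimators)
  } else {
    abort(paste0("unknown model family: ", family))
  }
  model
}

hs_score <- function(model, x) {
  x <- as.matrix(x[, model$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  switch(model$family,
    "logistic-regression" = as.numeric(predict(model$fit, x, s = model$lambda,
                                               type = "link")),
    "random-forest" = as.numeric(predict(model$fit, data = as.data.frame(x),
                                         num.threads = 1)$predictions[, "1"]),
    "support-vector-machine" = {
      pr <- predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the decision value toward the first level in the header
      if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
    },
    "adaboost" = predict_adaboost(model$fit, x),
    abort(paste0("unknown model family: ", model$family))
  )
}

# Classification threshold per family: probability 0.5 for probabilistic
# scores, 0 for margin-type scores.
hs_predict_class <- function(model, x) {
  s <- hs_score(model, x)
  thr <- switch(model$family,
    "random-forest" = 0.5,
    0
  )
  as.integer(s > thr)
}

# Exhaustive weighted decision stump: best single-feature threshold split
# over all features, thresholds and polarities. Sort orders are precomputed
# once per boosting run; each stump costs O(n p) via cumulative sums.
fit_stump <- function(x, y1, w, orders) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    o <- orders[[j]]
    v <- x[o, j]
    w1c <- cumsum(w[o] * y1[o])          # class-1 weight at or below each value
    w0c <- cumsum(w[o] * (1 - y1[o]))
    W1 <- w1c[length(w1c)]; W0 <- w0c[length(w0c)]
    ok <- which(v[-length(v)] < v[-1])   # splittable positions (distinct values)
    # predict 1 for x > threshold: error = class-1 weight below + class-0 above
    err_hi <- c(W0, w1c[ok] + (W0 - w0c[ok]), W1)
    cand_err <- pmin(err_hi, (W0 + W1) - err_hi)
    k <- which.min(cand_err)
    if (cand_err[k] < best$err) {
      thr <- if (k == 1) -Inf else if (k == length(err_hi)) Inf else
        (v[ok[k - 1]] + v[ok[k - 1] + 1]) / 2
      best <- list(err = cand_err[k], feature = j, threshold = thr,
                   polarity = if (err_hi[k] <= (W0 + W1) - err_hi[k]) 1 else -1)
    }
  }
  best
}

predict_stump <- function(st, x) {
  # +1/-1 vote; polarity 1 votes class 1 above the threshold
  s <- ifelse(x[, st$feature] > st$threshold, 1, -1)
  st$polarity * s
}

# Discrete AdaBoost (SAMME / AdaBoost.M1) over depth-1 stumps. Class weights
# stay uniform at initialization: the reference protocol applies balanced
# weighting to the other three families only.
fit_adaboost <- function(x, y, n_estimators = 50) {
  n <- nrow(x)
  y1 <- as.numeric(y == 1)
  ypm <- 2 * y1 - 1
  w <- rep(1 / n, n)
  orders <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  stumps <- list(); alphas <- numeric()
  for (m in seq_len(n_estimators)) {
    st <- fit_stump(x, y1, w, orders)
    pred <- predict_stump(st, x)
    err <- sum(w[pred != ypm])
    if (err <= 1e-12) {
      stumps[[length(stumps) + 1]] <- st
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != ypm))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    # no stump beat chance (degenerate data); fall back to the prior
    return(list(stumps = list(), alphas = numeric(), prior = mean(y1)))
  }
  list(stumps = stumps, alphas = alphas, prior = NULL)
}

predict_adaboost <- function(fit, x) {
  x <- as.matrix(x)
  if (length(fit$stumps) == 0) return(rep(fit$prior - 0.5, nrow(x)))
  votes <- vapply(seq_along(fit$stumps), function(m) {
    fit$alphas[m] * predict_stump(fit$stumps[[m]], x)
  }, numeric(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  rowSums(votes)
}

# Grid search maximizing mean ROC AUC over stratified k-fold CV.
cv_grid_search <- function(family, x, y, grid, seed = 1, k = 5) {
  fold <- stratified_folds(y, k = k, seed = derive_seed(seed, paste0("folds-", family)))
  x <- as.matrix(x)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- hs_fit(family, x[tr, , drop = FALSE], y[tr], params,
                  seed = derive_seed(seed, paste(family, g, f)))
      auc_score(hs_score(m, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(cv_auc)
  list(params = as.list(grid[best, ]), cv_auc = cv_auc[best])
}

binary_metrics <- function(scores, pred, y) {
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(test_auc = auc_score(scores, y), precision = precision,
         recall = recall, f1 = f1)
}
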