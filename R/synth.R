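#' Specification of one synthetic site
#'
#' Describes a site as a Gaussian mixture over `p` features with optional
#' support scaling, missingness and a logistic endpoint model.
#'
#' @param site_id Site label.
#' @param n_patients Number of patients (positive).
#' @param components List of mixture components, each
#'   `list(weight, mean, cov)`; weights must sum to 1 and covariances be
#'   symmetric positive definite.
#' @param support_scale Per-feature multiplicative scale about the mixture
#'   grand mean (scalar recycled); values above 1 widen the site's support
#'   without moving its centre.
#' @param missing_frac Per-feature missing-completely-at-random fraction in
#'   `[0, 1)` (scalar recycled).
#' @param endpoint_model `list(beta, intercept, peak = NULL)` of a
#'   single-index logistic model, or `NULL` for no endpoint. The linear
#'   predictor is `intercept + s(x %*% beta)` on the complete (pre-masking,
#'   post-scaling) features, identical across sites sharing the model. With
#'   `peak = NULL`, `s` is the identity (ordinary logistic model); with a
#'   numeric `peak`, `s` is the tent map `u` for `u <= peak`, `2*peak - u`
#'   above it — a rise-then-fall dose-response whose downturn can be placed
#'   outside a narrow site's support.
#' @param features Feature names (default `f1..fp`).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A `site_spec` list.
#' @export
site_spec <- function(site_id, n_patients, components, support_scale = 1,
                      missing_frac = 0, endpoint_model = NULL,
                      features = NULL, seed = 1) {
  if (n_patients < 1) abort("`n_patients` must be positive")
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) abort("component weights must sum to 1")
  p <- length(components[[1]]$mean)
  for (cc in components) {
    if (length(cc$mean) != p || !all(dim(cc$cov) == p)) {
      abort("component mean/cov dimensions disagree")
    }
    if (max(abs(cc$cov - t(cc$cov))) > 1e-8) abort("covariance must be symmetric")
    ev <- eigen(cc$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("covariance must be positive definite")
  }
  if (any(missing_frac < 0 | missing_frac >= 1)) abort("`missing_frac` must be in [0, 1)")
  structure(list(
    site_id = as.character(site_id), n_patients = as.integer(n_patients),
    components = components,
    support_scale = rep_len(support_scale, p),
    missing_frac = rep_len(missing_frac, p),
    endpoint_model = endpoint_model,
    features = features %||% paste0("f", seq_len(p)),
    seed = as.integer(seed %% 2147483647)
  ), class = "site_spec")
}

#' Generate one synthetic site cohort
#'
#' Draws `n_patients` rows from the spec's Gaussian mixture, scales them
#' about the mixture grand mean by `support_scale`, draws the optional binary
#' endpoint from the logistic model on the unscaled (latent, pre-masking)
#' draw, and finally masks entries missing completely at random per feature.
#'
#' @param spec A [site_spec()].
#' @return A cohort tibble; identical specs (including seed) give identical
#'   tables.
#' @export
generate_site <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_patients
  p <- length(spec$features)
  w <- vapply(spec$components, function(cc) cc$weight, numeric(1))
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  z <- matrix(0, n, p)
  for (k in seq_along(spec$components)) {
    idx <- which(comp == k)
    if (length(idx)) {
      z[idx, ] <- MASS::mvrnorm(length(idx), mu = spec$components[[k]]$mean,
                                Sigma = spec$components[[k]]$cov)
    }
  }
  grand <- colSums(w * do.call(rbind, lapply(spec$components, `[[`, "mean")))
  x <- sweep(sweep(sweep(z, 2, grand), 2, spec$support_scale, "*"), 2, grand, "+")
  colnames(x) <- spec$features
  out <- dplyr::bind_cols(
    tibble(site = spec$site_id,
           patient_id = sprintf("%s-%05d", spec$site_id, seq_len(n))),
    as_tibble(x)
  )
  if (!is.null(spec$endpoint_model)) {
    em <- spec$endpoint_model
    u <- as.numeric(x %*% em$beta)
    if (!is.null(em$peak)) u <- tent_map(u, em$peak)
    out$endpoint <- rbinom(n, 1, stats::plogis(em$intercept + u))
    out <- out[, c("site", "patient_id", "endpoint", spec$features)]
  }
  for (j in seq_len(p)) {
    if (spec$missing_frac[j] > 0) {
      mask <- runif(n) < spec$missing_frac[j]
      out[[spec$features[j]]][mask] <- NA_real_
    }
  }
  out
}

# Rise-then-fall single-index link: identity up to `peak`, declining beyond.
tent_map <- function(u, peak) ifelse(u <= peak, u, 2 * peak - u)

# Logistic intercept giving a target endpoint prevalence at a reference site
# where the single index (before intercept) is N(0, s^2).
calibrate_intercept <- function(lp_sd, prevalence, peak = NULL) {
  zs <- lp_sd * qnorm((seq_len(2000) - 0.5) / 2000)
  if (!is.null(peak)) zs <- tent_map(zs, peak)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + zs)) - prevalence,
                 c(-30, 10))$root
}

default_endpoint_model <- function(p, prevalence = 0.07, strength = 2, peak = NULL) {
  beta <- rep(strength / sqrt(p), p)
  list(beta = beta,
       intercept = calibrate_intercept(strength, prevalence, peak = peak),
       peak = peak)
}

#' Generate a named multi-site shift scenario
#'
#' Canonical study conditions for exercising the pipeline:
#' \describe{
#'   \item{identical}{two i.i.d. sites (A, B) from one distribution — the
#'     null case; origin classifiers should sit at AUC 0.5.}
#'   \item{single-feature-shift}{site B's first feature mean shifted by
#'     `magnitude` pooled standard deviations; the shifted feature should be
#'     flagged and drive origin discrimination.}
#'   \item{nested-support}{sites A, B, C at unit support plus a wide site D
#'     with `support_scale = 1 + magnitude` strictly containing the others;
#'     endpoints are generated so cross-prediction shows the directional
#'     degradation of narrow-site models on the wide site.}
#'   \item{cluster-gap}{site A bimodal in feature 1 with inter-mode gap
#'     `magnitude` standard deviations, site B unimodal centred in the gap:
#'     hull coverage is high while the distributions clearly differ — hull
#'     overlap is necessary but not sufficient for homogeneity.}
#' }
#'
#' @param name One of the scenario names above.
#' @param p Number of features.
#' @param n Patients per site.
#' @param magnitude Scenario-specific shift magnitude (>= 0).
#' @param seed Integer seed.
#' @param missing_frac MCAR missingness per feature (default 0, complete).
#' @param endpoint Attach a logistic endpoint (~7% prevalence, mirroring
#'   day-1 ARDS rates) to every site; defaults to `TRUE` only for
#'   "nested-support".
#' @return Named list of cohort tibbles.
#' @export
generate_scenario <- function(name, p = 10, n = 2000, magnitude = 1, seed = 1,
                              missing_frac = 0, endpoint = NULL) {
  valid <- c("identical", "single-feature-shift", "nested-support", "cluster-gap")
  if (!name %in% valid) {
    abort(paste0("unknown scenario '", name, "'; valid scenarios: ",
                 paste(valid, collapse = ", ")))
  }
  if (magnitude < 0) abort("`magnitude` must be >= 0")
  endpoint <- endpoint %||% (name == "nested-support")
  # The nested-support endpoint is non-monotone (tent peak at 2.5 reference
  # sd of the single index), with the downturn outside the narrow sites'
  # support: narrow-site models learn a monotone relation and extrapolate it
  # wrongly into the wide site's tail, while the wide-site model sees the
  # full dose-response. Outcome process is identical across sites.
  em <- if (endpoint) {
    default_endpoint_model(p, peak = if (name == "nested-support") 5 else NULL)
  } else NULL
  base_comp <- list(list(weight = 1, mean = rep(0, p), cov = diag(p)))
  mk <- function(id, components = base_comp, support_scale = 1) {
    generate_site(site_spec(id, n, components, support_scale = support_scale,
                            missing_frac = missing_frac, endpoint_model = em,
                            features = paste0("f", seq_len(p)),
                            seed = derive_seed(seed, paste0(name, "-", id))))
  }
  switch(name,
    "identical" = list(A = mk("A"), B = mk("B")),
    "single-feature-shift" = {
      shifted <- list(list(weight = 1, mean = c(magnitude, rep(0, p - 1)), cov = diag(p)))
      list(A = mk("A"), B = mk("B", components = shifted))
    },
    "nested-support" = list(
      A = mk("A"), B = mk("B"), C = mk("C"),
      D = mk("D", support_scale = 1 + magnitude)
    ),
    "cluster-gap" = {
      m1 <- c(-magnitude / 2, rep(0, p - 1)); m2 <- c(magnitude / 2, rep(0, p - 1))
      bimodal <- list(list(weight = 0.5, mean = m1, cov = diag(p)),
                      list(weight = 0.5, mean = m2, cov = diag(p)))
      list(A = mk("A", components = bimodal), B = mk("B"))
    }
  )
}

#' Generate oxygenation time series consistent with endpoint labels
#'
#' Emits long-format PaO2/FiO2/PEEP records per patient on a regular
#' measurement grid. Patients with `endpoint == 1` get a Horowitz-index
#' trajectory crossing below 300 within the first day and staying below for
#' the rest of the record (sustained >= 24 h); controls get one of three
#' templates — never below, a sustained crossing after hour 24 (late onset),
#' or a single unsustained dip.
#'
#' @param cohort Cohort tibble; an `endpoint` column selects the case
#'   template, otherwise all patients are controls.
#' @param trajectory_spec List: `cadence_h` (measurement spacing, > 0),
#'   `horizon_h` (record length), `fio2` (constant inspired fraction),
#'   `peep` (constant PEEP).
#' @param seed Integer seed.
#' @return Tibble of time-series records (`patient_id`, `parameter`,
#'   `time_h`, `value`).
#' @export
generate_timeseries <- function(cohort,
                                trajectory_spec = list(cadence_h = 4, horizon_h = 72,
                                                       fio2 = 0.4, peep = 6),
                                seed = 1) {
  ts <- trajectory_spec
  cadence <- ts$cadence_h %||% 4
  horizon <- ts$horizon_h %||% 72
  fio2 <- ts$fio2 %||% 0.4
  peep <- ts$peep %||% 6
  if (cadence <= 0) abort("`cadence_h` must be positive")
  if (horizon < 48 + cadence) abort("`horizon_h` too short for a sustained late onset")
  times <- seq(0, horizon, by = cadence)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  ep <- cohort[["endpoint"]] %||% rep(0L, nrow(cohort))
  recs <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    if (ep[i] == 1) {
      onset <- sample(times[times <= 16], 1)
      pf <- ifelse(times < onset, runif(length(times), 305, 360),
                   runif(length(times), 230, 290))
    } else {
      template <- sample(c("never", "late", "dip"), 1)
      pf <- runif(length(times), 305, 380)
      if (template == "late") {
        late_candidates <- times[times >= 24 + cadence & times <= horizon - 24]
        onset <- sample(late_candidates, 1)
        pf[times >= onset] <- runif(sum(times >= onset), 230, 290)
      } else if (template == "dip") {
        at <- sample(times[times > 0 & times < 20], 1)
        pf[times == at] <- runif(1, 230, 290)
      }
    }
    tibble(patient_id = cohort$patient_id[i],
           parameter = rep(c("pao2", "fio2", "peep"), each = length(times)),
           time_h = rep(times, 3),
           value = c(pf * fio2, rep(fio2, length(times)), rep(peep, length(times))))
  })
  recs
}
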