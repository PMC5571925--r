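#' Default covariate model for simulated cohorts
#'
#' Distributions for the prognostic covariates of a simulated bone-sarcoma
#' cohort. The lesion shape factor (elongation) is log-normal around 1.4,
#' spanning roughly 1--3; metastasis flags are Bernoulli; baseline SUVmax is
#' log-normal around 7. These are the package's own modelling choices for a
#' plausible pediatric sarcoma cohort (see the methods vignette).
#'
#' @return Named list of distribution specifications, each a list with a
#'   `dist` field (`"normal"`, `"lognormal"`, `"bernoulli"`, `"uniform"`)
#'   plus its parameters.
#' @export
default_covariate_model <- function() {
  list(
    elongation = list(dist = "lognormal", meanlog = log(1.4), sdlog = 0.25),
    lung_metastasis = list(dist = "bernoulli", p = 0.25),
    bone_metastasis = list(dist = "bernoulli", p = 0.15),
    suv_max = list(dist = "lognormal", meanlog = log(7), sdlog = 0.4)
  )
}

#' Cohort specification
#'
#' Parameters of a simulated survival cohort: sample size, true per-covariate
#' log hazard ratios, a Weibull baseline hazard, a target censoring fraction
#' and the covariate distributions.
#'
#' @param n_patients number of patients, >= 2.
#' @param true_log_hr named numeric vector of log hazard ratios; names must
#'   refer to covariates of `covariate_model` (unnamed covariates get 0).
#' @param baseline_hazard list with Weibull `scale` (days) and `shape`.
#' @param censoring_fraction target censored proportion in `[0, 1)`.
#' @param covariate_model see [default_covariate_model()].
#' @param os_scale_factor multiplier applied to the Weibull scale for the
#'   overall-survival endpoint (overall survival runs longer than
#'   progression-free survival).
#' @param seed integer RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 62L,
                        true_log_hr = c(elongation = 0, lung_metastasis = 0,
                                        bone_metastasis = 0, suv_max = 0),
                        baseline_hazard = list(scale = 1500, shape = 1.2),
                        censoring_fraction = 0.3,
                        covariate_model = default_covariate_model(),
                        os_scale_factor = 1.6,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stopf("n_patients must be >= 2")
  if (censoring_fraction < 0 || censoring_fraction >= 1) {
    stopf("censoring_fraction must be in [0, 1)")
  }
  if (baseline_hazard$scale <= 0 || baseline_hazard$shape <= 0) {
    stopf("Weibull scale and shape must be > 0")
  }
  if (is.null(names(covariate_model)) || any(names(covariate_model) == "")) {
    stopf("covariate_model must be a named list")
  }
  bad <- setdiff(names(true_log_hr), names(covariate_model))
  if (length(bad)) stopf("true_log_hr names not in covariate_model: %s",
                         paste(bad, collapse = ", "))
  structure(list(n_patients = n_patients, true_log_hr = true_log_hr,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 covariate_model = covariate_model,
                 os_scale_factor = os_scale_factor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_covariates <- function(model, n) {
  cols <- lapply(model, function(m) {
    switch(m$dist,
      normal = stats::rnorm(n, m$mean %||% 0, m$sd %||% 1),
      lognormal = stats::rlnorm(n, m$meanlog %||% 0, m$sdlog %||% 1),
      bernoulli = stats::rbinom(n, 1L, m$p),
      uniform = stats::runif(n, m$min %||% 0, m$max %||% 1),
      stopf("unknown covariate distribution '%s'", m$dist)
    )
  })
  do.call(cbind, cols)
}

# Weibull proportional-hazards event times: S(t|x) = exp(-(t/scale)^shape *
# exp(eta)); inverting gives t = scale * (-log U / exp(eta))^(1/shape).
weibull_ph_times <- function(n, eta, scale, shape) {
  u <- stats::runif(n)
  scale * (-log(u) / exp(eta))^(1 / shape)
}

# Calibrate the upper bound of uniform censoring so the expected censored
# fraction matches the target: P(C < T) = E[min(T / t_max, 1)], decreasing
# in t_max; solved by bisection.
calibrate_censoring_tmax <- function(event_times, target) {
  f <- function(tmax) mean(pmin(event_times / tmax, 1))
  lo <- min(event_times) * 1e-4
  hi <- max(event_times) * 1e4
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a survival cohort with known hazard structure
#'
#' Draws covariates from the cohort's covariate model, event times for
#' progression-free and overall survival from a Weibull proportional-hazards
#' model with linear predictor `true_log_hr . covariates`, and an
#' independent uniform censoring time whose upper bound is calibrated by
#' bisection to the target censoring fraction. Descriptive fields (subgroup,
#' histologic subtype, Salzer-Kuntschik regression grade) are sampled
#' independently of the hazard unless named in the covariate model.
#'
#' @param cspec a [cohort_spec()].
#' @return A `data.frame` (class `sarcoma_cohort`) with one row per patient:
#'   `id`, `subgroup`, `histologic_subtype`, `salzer_kuntschik_grade`, one
#'   column per covariate, and `pfs_days`, `pfs_event`, `os_days`,
#'   `os_event`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 50, seed = 3))
#' mean(co$pfs_event)
#' @export
generate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  with_seed(cspec$seed, {
    n <- cspec$n_patients
    X <- draw_covariates(cspec$covariate_model, n)
    colnames(X) <- names(cspec$covariate_model)
    if (all(apply(X, 2L, stats::var) == 0)) {
      stopf("degenerate covariate_model: zero variance in all covariates")
    }
    beta <- stats::setNames(numeric(ncol(X)), colnames(X))
    beta[names(cspec$true_log_hr)] <- cspec$true_log_hr
    # center the linear predictor so the Weibull scale keeps its meaning
    eta <- as.vector(scale(X, center = TRUE, scale = FALSE) %*% beta)
    sc <- cspec$baseline_hazard$scale
    sh <- cspec$baseline_hazard$shape
    t_pfs <- weibull_ph_times(n, eta, sc, sh)
    t_os <- t_pfs + weibull_ph_times(n, eta, sc * (cspec$os_scale_factor - 1) + 1e-9, sh)
    if (cspec$censoring_fraction > 0) {
      tmax <- calibrate_censoring_tmax(t_pfs, cspec$censoring_fraction)
      cens <- stats::runif(n, 0, tmax)
    } else {
      cens <- rep(Inf, n)
    }
    grade <- sample(1:6, n, replace = TRUE,
                    prob = c(0.15, 0.30, 0.35, 0.12, 0.05, 0.03))
    subgroup <- sample(c("EWS", "OST"), n, replace = TRUE)
    subtype <- ifelse(subgroup == "OST",
                      sample(c("osteoblastic", "chondroblastic", "telangiectatic"),
                             n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                      "ewing")
    out <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      subgroup = subgroup,
      histologic_subtype = subtype,
      salzer_kuntschik_grade = grade,
      X,
      pfs_days = pmax(pmin(t_pfs, cens), 0.5),
      pfs_event = t_pfs <= cens,
      os_days = pmax(pmin(t_os, cens), 0.5),
      os_event = t_os <= cens,
      stringsAsFactors = FALSE
    )
    class(out) <- c("sarcoma_cohort", "data.frame")
    out
  })
}

#' Read and write cohorts as CSV
#' @param cohort a cohort `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly, or the cohort read back.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("pfs_event", "os_event")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  class(out) <- c("sarcoma_cohort", "data.frame")
  out
}

#' @rdname write_spec_yaml
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$kind, "cohort_spec")) stopf("%s is not a cohort_spec", path)
  x$kind <- NULL
  x$true_log_hr <- unlist(x$true_log_hr)
  do.call(cohort_spec, x)
}
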