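#' Univariate Cox proportional-hazards screen of one covariate
#'
#' Fits a Cox model for one covariate against progression-free or overall
#' survival (Efron correction for tied event times) and reports the hazard
#' ratio with Wald statistics. Monotone-likelihood separation (a covariate
#' perfectly ordering the events) is flagged with a warning rather than
#' returned as a silently diverged fit.
#'
#' @param records a cohort `data.frame` with columns `<endpoint>_days`,
#'   `<endpoint>_event` and the covariate (e.g. from [generate_cohort()] or
#'   a pipeline feature table).
#' @param covariate column name of the covariate to screen.
#' @param endpoint `"pfs"` or `"os"`.
#' @param dichotomize split a continuous covariate at its median before
#'   fitting, the common clinical alternative to entering it untransformed.
#' @return An object of class `cox_fit`: a list with `table` (one row per
#'   term: `term`, `coef`, `hazard_ratio`, `se`, `z`, `p_value`, `ci_lower`,
#'   `ci_upper`), `loglik`, `n`, `n_events`, `endpoint`, `flags`.
#' @export
cox_univariate <- function(records, covariate,
                           endpoint = c("pfs", "os"), dichotomize = FALSE) {
  endpoint <- match.arg(endpoint)
  cox_fit_impl(records, covariate, endpoint, dichotomize)
}

cox_endpoint_frame <- function(records, covariates, endpoint) {
  records <- as.data.frame(records)
  tcol <- paste0(endpoint, "_days")
  ecol <- paste0(endpoint, "_event")
  missing <- setdiff(c(tcol, ecol, covariates), names(records))
  if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
  df <- records[, c(tcol, ecol, covariates), drop = FALSE]
  names(df)[1:2] <- c(".time", ".event")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.event <- as.logical(df$.event)
  if (sum(df$.event) < 2L) stopf(">= 2 events required")
  df
}

cox_fit_impl <- function(records, covariates, endpoint, dichotomize = FALSE) {
  df <- cox_endpoint_frame(records, covariates, endpoint)
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.character(x)) x <- factor(x)
    if (is.logical(x)) x <- as.numeric(x)
    if (length(unique(x)) < 2L) stopf("covariate '%s' is constant", cv)
    if (dichotomize && is.numeric(x) && length(unique(x)) > 2L) {
      x <- as.numeric(x > stats::median(x))
      if (length(unique(x)) < 2L) stopf("covariate '%s' is constant after dichotomization", cv)
    }
    df[[cv]] <- x
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        flags <<- union(flags, "monotone_likelihood")
        warning("possible monotone-likelihood separation: coefficient unreliable",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hazard_ratio = exp(co[, "coef"]),
    se = co[, "se(coef)"],
    z = co[, "z"],
    p_value = co[, "Pr(>|z|)"],
    ci_lower = exp(co[, "coef"] - stats::qnorm(0.975) * co[, "se(coef)"]),
    ci_upper = exp(co[, "coef"] + stats::qnorm(0.975) * co[, "se(coef)"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, loglik = fit$loglik[2L], n = sm$n,
                 n_events = sm$nevent, endpoint = endpoint, flags = flags,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> endpoint %s, n = %d, events = %d%s\n", x$endpoint,
              x$n, x$n_events,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Multivariate Cox model with univariate pre-screening
#'
#' Candidates are first screened univariately; only those with a Wald p at
#' or below `inclusion_alpha` (default 0.10, operationalizing "significant
#' or nearly significant") enter the joint model. Candidates dropped by the
#' screen are reported with status `"not retained in model"`.
#'
#' @inheritParams cox_univariate
#' @param candidates character vector of candidate covariate columns.
#' @param inclusion_alpha univariate screening level.
#' @return An object of class `cox_screen`: list with `fit` (the joint
#'   `cox_fit`, or `NULL` when no candidate passes), `screen` (per-candidate
#'   univariate p and retention flag), `status`.
#' @export
cox_multivariate <- function(records, candidates, endpoint = c("pfs", "os"),
                             inclusion_alpha = 0.10, dichotomize = FALSE) {
  endpoint <- match.arg(endpoint)
  uni <- lapply(candidates, function(cv) {
    tryCatch(cox_univariate(records, cv, endpoint, dichotomize),
             error = function(e) e)
  })
  p_uni <- vapply(uni, function(u) {
    if (inherits(u, "error")) NA_real_ else min(u$table$p_value)
  }, numeric(1))
  screen <- data.frame(term = candidates, p_univariate = p_uni,
                       retained = !is.na(p_uni) & p_uni <= inclusion_alpha,
                       stringsAsFactors = FALSE)
  screen$status <- ifelse(screen$retained, "retained",
                          ifelse(is.na(screen$p_univariate), "unfittable",
                                 "not retained in model"))
  if (!any(screen$retained)) {
    return(structure(list(fit = NULL, screen = screen, endpoint = endpoint,
                          status = "empty model: no candidate passed the screen"),
                     class = "cox_screen"))
  }
  fit <- cox_fit_impl(records, screen$term[screen$retained], endpoint, dichotomize)
  structure(list(fit = fit, screen = screen, endpoint = endpoint, status = "ok"),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf("<cox_screen> endpoint %s: %s\n", x$endpoint, x$status))
  print(x$screen, digits = 4)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Spearman correlation of a feature delta with the regression grade
#'
#' Rank correlation (mid-ranks for ties, p from the t approximation)
#' between a percent-change feature and the Salzer-Kuntschik grade of the
#' resected tumor.
#'
#' @param records data.frame with the delta column and a grade column.
#' @param delta_feature name of the delta column.
#' @param grade_col grade column name.
#' @return List with `rho`, `p_value`, `n`, `status` (`"ok"`, or
#'   `"undefined: constant ranks"` with `rho = NA`).
#' @export
spearman_delta_vs_grade <- function(records, delta_feature,
                                    grade_col = "salzer_kuntschik_grade") {
  records <- as.data.frame(records)
  if (!all(c(delta_feature, grade_col) %in% names(records))) {
    stopf("missing column: %s", paste(setdiff(c(delta_feature, grade_col),
                                              names(records)), collapse = ", "))
  }
  x <- records[[delta_feature]]
  g <- records[[grade_col]]
  ok <- stats::complete.cases(x, g)
  x <- x[ok]; g <- g[ok]
  if (length(x) < 4L) stopf(">= 4 paired observations required")
  if (length(unique(x)) < 2L || length(unique(g)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                status = "undefined: constant ranks"))
  }
  ct <- suppressWarnings(stats::cor.test(x, g, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       status = "ok")
}

#' Build a lesion-detection contingency table
#'
#' One row per modality and lesion class with true/false positive/negative
#' counts against the reference standard.
#'
#' @param modality imaging modality label(s).
#' @param lesion_class lesion site class (`primary`, `bone`, `lung`,
#'   `skip`, ...).
#' @param tp,fn,tn,fp non-negative counts.
#' @return A `data.frame` of class `detection_table`.
#' @export
detection_table <- function(modality, lesion_class, tp, fn, tn = 0L, fp = 0L) {
  df <- data.frame(modality = modality, lesion_class = lesion_class,
                   tp = as.integer(tp), fn = as.integer(fn),
                   tn = as.integer(tn), fp = as.integer(fp),
                   stringsAsFactors = FALSE)
  if (any(df[, c("tp", "fn", "tn", "fp")] < 0L)) stopf("counts must be non-negative")
  class(df) <- c("detection_table", "data.frame")
  df
}

#' Detection sensitivity and specificity with exact binomial intervals
#'
#' Per modality and lesion class: sensitivity `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)` in percent, with exact (Clopper-Pearson)
#' 95\% confidence intervals; metrics with a zero denominator are reported
#' as `NA` (undefined).
#'
#' @param table a [detection_table()].
#' @return The table with columns `sensitivity`, `sens_lo`, `sens_hi`,
#'   `specificity`, `spec_lo`, `spec_hi` appended (percent scale).
#' @export
detection_performance <- function(table) {
  stopifnot(inherits(table, "detection_table"))
  rate_ci <- function(k, n) {
    if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
    ci <- stats::binom.test(k, n)$conf.int
    c(100 * k / n, 100 * ci[1], 100 * ci[2])
  }
  sens <- t(mapply(rate_ci, table$tp, table$tp + table$fn))
  spec <- t(mapply(rate_ci, table$tn, table$tn + table$fp))
  table$sensitivity <- sens[, 1]; table$sens_lo <- sens[, 2]; table$sens_hi <- sens[, 3]
  table$specificity <- spec[, 1]; table$spec_lo <- spec[, 2]; table$spec_hi <- spec[, 3]
  table
}

#' Screen many covariates against both survival endpoints
#'
#' Convenience driver used by the pipeline report: univariate Cox fits for
#' every covariate and endpoint, plus the multivariate retention flag.
#' Constant or unfittable covariates are skipped with the reason recorded.
#'
#' @inheritParams cox_multivariate
#' @param covariates character vector of covariate columns to screen.
#' @param endpoints endpoints to screen, subset of `c("pfs", "os")`.
#' @return A `data.frame` with one row per (endpoint, covariate):
#'   `endpoint`, `term`, `hazard_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `retained_multivariate`, `status`.
#' @export
prognostic_screen <- function(records, covariates, endpoints = c("pfs", "os"),
                              inclusion_alpha = 0.10, dichotomize = FALSE) {
  rows <- list()
  for (ep in endpoints) {
    mv <- cox_multivariate(records, covariates, ep, inclusion_alpha, dichotomize)
    for (cv in covariates) {
      uni <- tryCatch(cox_univariate(records, cv, ep, dichotomize),
                      error = function(e) e)
      if (inherits(uni, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, term = cv, hazard_ratio = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
          retained_multivariate = FALSE,
          status = paste("skipped:", conditionMessage(uni)),
          stringsAsFactors = FALSE)
        next
      }
      tb <- uni$table[1L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, term = cv, hazard_ratio = tb$hazard_ratio,
        ci_lower = tb$ci_lower, ci_upper = tb$ci_upper, p_value = tb$p_value,
        retained_multivariate = mv$screen$retained[mv$screen$term == cv],
        status = if (length(uni$flags)) paste(uni$flags, collapse = ";") else "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
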