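mk_surv_df <- function(time, event, x, name = "x") {
  df <- data.frame(pfs_days = time, pfs_event = event,
                   os_days = time, os_event = event)
  df[[name]] <- x
  df
}

test_that("the Cox score at beta = 0 matches the closed form on tiny data", {
  # two groups, no ties: score U(0) = sum over events of (x_i - xbar(risk set))
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(TRUE, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  df <- mk_surv_df(time, event, x)
  fit <- cox_univariate(df, "x", "pfs")
  # hand-computed score statistic at beta = 0
  u <- 0; v <- 0
  for (i in order(time)) {
    rs <- which(time >= time[i])
    xb <- mean(x[rs])
    u <- u + (x[i] - xb)
    v <- v + mean((x[rs] - xb)^2)
  }
  sc <- survival::coxph(survival::Surv(time, event) ~ x,
                        init = 0, control = survival::coxph.control(iter.max = 0))
  expect_equal(unname(sc$score), u^2 / v, tolerance = 1e-8)
  expect_true(is.finite(fit$table$p_value))
  expect_equal(fit$n_events, 6L)
})

test_that("hazard ratios follow the covariate rescaling law exactly", {
  co <- generate_cohort(cohort_spec(n_patients = 200L,
                                    true_log_hr = c(elongation = 0.8),
                                    censoring_fraction = 0.2, seed = 13L))
  f1 <- cox_univariate(co, "elongation", "pfs")
  co2 <- co
  co2$elongation <- co$elongation / 2
  f2 <- cox_univariate(co2, "elongation", "pfs")
  expect_equal(f2$table$coef, 2 * f1$table$coef, tolerance = 1e-6)
  expect_equal(f2$table$p_value, f1$table$p_value, tolerance = 1e-6)
})

test_that("null p-values are roughly uniform across seeded simulations", {
  p <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec(
      n_patients = 120L, true_log_hr = c(lung_metastasis = 0),
      covariate_model = list(lung_metastasis = list(dist = "bernoulli",
                                                    p = 0.5)),
      censoring_fraction = 0.2, seed = 400L + s))
    cox_univariate(co, "lung_metastasis", "pfs")$table$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate Cox inputs error with clear messages", {
  df <- mk_surv_df(1:10, rep(FALSE, 10), rnorm(10))
  expect_error(cox_univariate(df, "x", "pfs"), ">= 2 events")
  df2 <- mk_surv_df(1:10, rep(TRUE, 10), rep(1, 10))
  expect_error(cox_univariate(df2, "x", "pfs"), "constant")
})

test_that("monotone-likelihood separation is flagged, not silent", {
  # covariate perfectly separates early from late events
  time <- c(1, 2, 3, 4, 50, 60, 70, 80)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  df <- mk_surv_df(time, rep(TRUE, 8), x)
  expect_warning(fit <- cox_univariate(df, "x", "pfs"), "monotone")
  expect_true("monotone_likelihood" %in% fit$flags)
})

test_that("multivariate screening retains true effects and reports NRM", {
  co <- generate_cohort(cohort_spec(
    n_patients = 300L,
    true_log_hr = c(lung_metastasis = log(4)),
    censoring_fraction = 0.3, seed = 71L))
  mv <- cox_multivariate(co, c("lung_metastasis", "elongation", "suv_max"),
                         "pfs")
  sc <- mv$screen
  expect_true(sc$retained[sc$term == "lung_metastasis"])
  expect_true(all(sc$status[!sc$retained] == "not retained in model"))
  hr <- mv$fit$table$hazard_ratio[mv$fit$table$term == "lung_metastasis"]
  expect_gt(hr, 1.5)

  # a single passing candidate: multivariate fit equals the univariate fit
  mv1 <- cox_multivariate(co, "lung_metastasis", "pfs")
  uni <- cox_univariate(co, "lung_metastasis", "pfs")
  expect_equal(mv1$fit$table, uni$table, tolerance = 1e-10)

  # nothing passes a zero screening level: explicit empty model
  mv0 <- cox_multivariate(co, "elongation", "pfs", inclusion_alpha = 1e-12)
  expect_null(mv0$fit)
  expect_match(mv0$status, "empty model")
})

test_that("null covariates are retained at about the screening rate", {
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    co <- generate_cohort(cohort_spec(
      n_patients = 150L, true_log_hr = c(elongation = 0),
      censoring_fraction = 0.2, seed = 900L + s))
    mv <- cox_multivariate(co, "elongation", "pfs", inclusion_alpha = 0.10)
    hits <- hits + sum(mv$screen$retained)
    total <- total + 1L
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.30)
})

test_that("spearman correlation of deltas against grade behaves", {
  d <- data.frame(delta_tlg = c(-90, -70, -50, -30, -10),
                  salzer_kuntschik_grade = 1:5)
  r <- spearman_delta_vs_grade(d, "delta_tlg")
  expect_equal(r$rho, 1)
  d2 <- d; d2$delta_tlg <- rev(d2$delta_tlg)
  expect_equal(spearman_delta_vs_grade(d2, "delta_tlg")$rho, -1)

  expect_error(spearman_delta_vs_grade(d[1:3, ], "delta_tlg"), ">= 4")
  d3 <- d; d3$delta_tlg <- rep(-50, 5)
  expect_match(spearman_delta_vs_grade(d3, "delta_tlg")$status, "undefined")

  # independence: |rho| small in most seeded replicates
  small <- vapply(1:30, function(s) {
    set.seed(1500 + s)
    dd <- data.frame(delta_tlg = rnorm(200),
                     salzer_kuntschik_grade = sample(1:6, 200, replace = TRUE))
    abs(spearman_delta_vs_grade(dd, "delta_tlg")$rho) < 0.2
  }, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("detection performance reports rates with exact intervals", {
  tab <- detection_table(
    modality = c("FDG-PET", "CI", "FDG-PET"),
    lesion_class = c("bone", "bone", "lung"),
    tp = c(4L, 3L, 10L), fn = c(1L, 2L, 0L),
    tn = c(20L, 20L, 15L), fp = c(1L, 1L, 0L))
  perf <- detection_performance(tab)
  expect_equal(perf$sensitivity, c(80, 60, 100))
  expect_true(all(perf$sens_lo <= perf$sensitivity &
                    perf$sensitivity <= perf$sens_hi, na.rm = TRUE))
  # zero denominator: undefined, not zero
  tab0 <- detection_table("FDG-PET", "skip", tp = 0L, fn = 0L)
  p0 <- detection_performance(tab0)
  expect_true(is.na(p0$sensitivity))
  expect_error(detection_table("m", "c", tp = -1L, fn = 0L), "non-negative")
})
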