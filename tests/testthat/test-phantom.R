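test_that("phantom lesion volume matches the analytic ellipsoid volume", {
  # sphere of radius 10 mm, 2 mm voxels, lattice-aligned center
  sp <- phantom_spec(grid_shape = c(31L, 31L, 31L), spacing = c(2, 2, 2),
                     lesion_center = c(16, 16, 16), semi_axes = c(10, 10, 10),
                     lesion_suv = 8, noise_sd = 0, background_noise_sd = 0)
  ph <- generate_phantom(sp)
  v_mask <- sum(ph$mask$values) * voxel_volume(ph$mask)
  v_true <- 4 / 3 * pi * 10^3
  expect_lt(abs(v_mask - v_true) / v_true, 0.05)

  # finer sampling reduces the discretization error
  sp_fine <- phantom_spec(grid_shape = c(61L, 61L, 61L), spacing = c(1, 1, 1),
                          lesion_center = c(31, 31, 31),
                          semi_axes = c(10, 10, 10), lesion_suv = 8)
  ph_fine <- generate_phantom(sp_fine)
  v_fine <- sum(ph_fine$mask$values) * voxel_volume(ph_fine$mask)
  expect_lt(abs(v_fine - v_true), abs(v_mask - v_true))
})

test_that("zero lesion contrast is rejected and overflow names the axis", {
  expect_error(phantom_spec(background_suv = 2, lesion_suv = 2),
               "exceed background")
  sp <- phantom_spec(grid_shape = c(20L, 40L, 40L), spacing = c(1, 1, 1),
                     lesion_center = c(10, 20, 20), semi_axes = c(15, 5, 5),
                     lesion_suv = 5)
  expect_error(generate_phantom(sp), "axis 1")
})

test_that("phantom generation is bit-identical under a fixed seed", {
  sp <- phantom_spec(noise_sd = 0.3, background_noise_sd = 0.1,
                     texture_pattern = list(type = "blobs", count = 3L),
                     seed = 99L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
})

test_that("texture patterns stay within the requested contrast", {
  for (tp in list("uniform", "gradient",
                  list(type = "checkerboard", period = 2L),
                  list(type = "blobs", count = 4L, amplitude = 1.5))) {
    sp <- phantom_spec(texture_pattern = tp, lesion_suv = 9, noise_sd = 0,
                       background_noise_sd = 0, seed = 5L)
    ph <- generate_phantom(sp)
    lesion_vals <- ph$volume$values[ph$mask$values]
    expect_lte(max(lesion_vals), 9 + 1e-12)
    expect_gt(min(lesion_vals), sp$background_suv)
    expect_equal(max(lesion_vals), 9, tolerance = 1e-9)
  }
})

test_that("response pairs scale uptake and volume as requested", {
  sp <- phantom_spec(grid_shape = c(30L, 30L, 30L), spacing = c(2, 2, 2),
                     semi_axes = c(12, 10, 10), lesion_suv = 10,
                     background_suv = 0.8, noise_sd = 0,
                     background_noise_sd = 0)
  # identity scales leave both studies identical up to noise realization
  pr1 <- generate_response_pair(sp, uptake_scale = 1, volume_scale = 1)
  d1 <- delta_percent(lesion_features(pr1$baseline$volume, pr1$baseline$mask),
                      lesion_features(pr1$post$volume, pr1$post$mask))
  expect_equal(unname(d1), rep(0, 5), tolerance = 1e-9)

  # 60% uptake reduction measured through the intensity features
  pr <- generate_response_pair(sp, uptake_scale = 0.4, volume_scale = 1)
  d <- delta_percent(lesion_features(pr$baseline$volume, pr$baseline$mask),
                     lesion_features(pr$post$volume, pr$post$mask))
  expect_equal(unname(d["delta_suv_mean"]), -60, tolerance = 2)

  # volume scaling contracts the truth mask by the requested factor
  prv <- generate_response_pair(sp, uptake_scale = 1, volume_scale = 0.5)
  ratio <- sum(prv$post$mask$values) / sum(prv$baseline$mask$values)
  expect_equal(ratio, 0.5, tolerance = 0.1)

  expect_error(generate_response_pair(sp, uptake_scale = -0.1), ">= 0")
})

test_that("vanished uptake drives TLG delta to -100 via the fallback VOI", {
  sp <- phantom_spec(grid_shape = c(30L, 30L, 30L), spacing = c(2, 2, 2),
                     semi_axes = c(12, 10, 10), lesion_suv = 10,
                     background_suv = 0.8, noise_sd = 0,
                     background_noise_sd = 0)
  pr <- generate_response_pair(sp, uptake_scale = 0, volume_scale = 1)
  # post lesion indistinguishable from background
  expect_equal(max(pr$post$volume$values), sp$background_suv, tolerance = 1e-12)
  expect_true(is_not_delineable(
    adaptive_segment(pr$post$volume, c(15, 15, 15), sp$background_suv)))
  # fallback VOI: baseline geometry, background uptake, flagged empty metrics
  fb <- fallback_voi(pr$baseline$mask, pr$post$volume)
  expect_equal(unname(suv_basic(pr$post$volume, fb)["suv_mean"]),
               sp$background_suv, tolerance = 1e-9)
  pre <- lesion_features(pr$baseline$volume, pr$baseline$mask)
  post <- lesion_features(pr$post$volume, fb)
  post["mtv"] <- 0
  post["tlg"] <- 0
  d <- delta_percent(pre, post)
  expect_equal(unname(d["delta_tlg"]), -100)
})

test_that("cohort censoring calibration and event flags behave", {
  co <- generate_cohort(cohort_spec(n_patients = 1000L,
                                    censoring_fraction = 0.3, seed = 5L))
  expect_lt(abs(mean(!co$pfs_event) - 0.3), 0.05)
  expect_true(all(co$pfs_days > 0) && all(co$os_days > 0))
  expect_true(all(co$salzer_kuntschik_grade %in% 1:6))

  co0 <- generate_cohort(cohort_spec(n_patients = 100L,
                                     censoring_fraction = 0, seed = 5L))
  expect_true(all(co0$pfs_event) && all(co0$os_event))

  expect_identical(co, generate_cohort(cohort_spec(n_patients = 1000L,
                                                   censoring_fraction = 0.3,
                                                   seed = 5L)))
  expect_error(cohort_spec(censoring_fraction = 1), "censoring_fraction")
  expect_error(cohort_spec(n_patients = 1), "n_patients")
})

test_that("a degenerate covariate model is rejected", {
  cs <- cohort_spec(n_patients = 50L,
                    true_log_hr = c(flag = 0),
                    covariate_model = list(flag = list(dist = "bernoulli",
                                                       p = 0)))
  expect_error(generate_cohort(cs), "degenerate")
})

test_that("null cohorts show no spurious hazard signal", {
  cs <- cohort_spec(n_patients = 500L,
                    true_log_hr = c(elongation = 0, lung_metastasis = 0),
                    censoring_fraction = 0.3, seed = 21L)
  co <- generate_cohort(cs)
  for (cv in c("elongation", "lung_metastasis")) {
    fit <- cox_univariate(co, cv, "pfs")
    expect_lt(abs(fit$table$coef), 3 * fit$table$se)
  }
})

test_that("phantom and cohort specs round-trip through YAML", {
  sp <- phantom_spec(texture_pattern = list(type = "checkerboard", period = 2L),
                     seed = 17L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(sp, f)
  expect_equal(read_phantom_spec(f), sp)

  cs <- cohort_spec(n_patients = 40L, true_log_hr = c(elongation = 0.5),
                    seed = 3L)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(cs, f2)
  cs2 <- read_cohort_spec(f2)
  expect_equal(cs2$true_log_hr, cs$true_log_hr)
  # serialized parameters round to 15 digits, so cohorts agree numerically
  expect_equal(generate_cohort(cs2), generate_cohort(cs), tolerance = 1e-6)
})
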