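test_that("spec validation names the offending field", {
  expect_error(phantom_spec(wall_thickness = 0), "wall_thickness")
  expect_error(phantom_spec(es_cavity_scale = 1), "es_cavity_scale")
  expect_error(phantom_spec(es_cavity_scale = 0), "es_cavity_scale")
  expect_error(phantom_spec(trabecular_amplitude = 40), "trabecular_amplitude")
  expect_error(phantom_spec(n_phases = 1), "n_phases")
  expect_error(phantom_spec(slice_spacing = -1), "slice_spacing")
})

test_that("smooth anatomy has identical rounded and trabecular truth", {
  sp <- fast_spec(trabecular_amplitude = 0, papillary_radius = 0)
  tr <- as.data.frame(phantom_truth(sp))
  expect_equal(tr$cavity_volume_rounded_ml, tr$cavity_volume_trabecular_ml)
  expect_equal(tr$myo_volume_rounded_ml, tr$myo_volume_trabecular_ml)
})

test_that("trabeculation strictly separates the two truths in the expected direction", {
  tr <- as.data.frame(phantom_truth(fast_spec()))
  expect_true(all(tr$cavity_volume_trabecular_ml < tr$cavity_volume_rounded_ml))
  expect_true(all(tr$myo_volume_trabecular_ml > tr$myo_volume_rounded_ml))
  expect_true(all(tr[, 3:6] > 0))
})

test_that("voxelization oracle matches the closed-form half-ellipsoid volume", {
  # cavity = half-ellipsoid with semi-axes (20, 20, 40) mm when the clip
  # plane sits at the equator: (2/3) * pi * 20 * 20 * 40 mm^3
  sp <- phantom_spec(epi_semi_axes = c(28, 28, 48), wall_thickness = 8,
                     trabecular_amplitude = 0, papillary_radius = 0)
  v <- cinelv:::.voxelize_volumes(sp, s = 1,
                                  mp = list(point = c(0, 0, 0), normal = c(0, 0, -1)),
                                  res_mm = 0.25)
  closed <- (2 / 3) * pi * 20 * 20 * 40 / 1000
  expect_lt(abs(v[["cr"]] - closed) / closed, 0.01)
})

test_that("increasing ridge depth never increases the trabecular cavity", {
  prev <- Inf
  for (A in c(0, 1, 2, 3)) {
    tr <- as.data.frame(phantom_truth(fast_spec(trabecular_amplitude = A)))
    expect_lte(tr$cavity_volume_trabecular_ml[1], prev)
    prev <- tr$cavity_volume_trabecular_ml[1]
  }
})

test_that("truth voxelization converges: 0.5 mm vs 0.25 mm within 0.5%", {
  sp <- phantom_spec()
  t1 <- as.data.frame(phantom_truth(sp, res_mm = 0.5))
  t2 <- as.data.frame(phantom_truth(sp, res_mm = 0.25))
  for (cl in names(t1)[3:6])
    expect_lt(max(abs(t1[[cl]] - t2[[cl]]) / t2[[cl]]), 0.005)
})

test_that("phantom generation is deterministic given spec and seed", {
  sp <- fast_spec(n_slices = 6)
  p1 <- make_phantom(sp, seed = 5, truth = FALSE)
  p2 <- make_phantom(sp, seed = 5, truth = FALSE)
  expect_identical(p1$sax[[1]]$data, p2$sax[[1]]$data)
  expect_identical(p1$ch2[[2]]$data, p2$ch2[[2]]$data)
  expect_identical(p1$landmarks, p2$landmarks)
  p3 <- make_phantom(sp, seed = 6, truth = FALSE)
  expect_false(identical(p1$sax[[1]]$data, p3$sax[[1]]$data))
})

test_that("rescan pair: zero jitter reproduces or re-noises as requested", {
  sp <- fast_spec(n_slices = 6)
  pr <- make_rescan_pair(sp, jitter = list(slice_offset_sd_mm = 0,
                                           rotation_sd_deg = 0,
                                           reseed_noise = FALSE),
                         seed = 9, compute_truth = FALSE)
  expect_identical(pr$scan1$sax[[1]]$data, pr$scan2$sax[[1]]$data)
  expect_identical(pr$scan1$sax[[1]]$affine, pr$scan2$sax[[1]]$affine)

  pr2 <- make_rescan_pair(sp, jitter = list(slice_offset_sd_mm = 0,
                                            rotation_sd_deg = 0,
                                            reseed_noise = TRUE),
                          seed = 9, compute_truth = TRUE)
  expect_identical(pr2$scan1$sax[[1]]$affine, pr2$scan2$sax[[1]]$affine)
  expect_false(identical(pr2$scan1$sax[[1]]$data, pr2$scan2$sax[[1]]$data))
  # same anatomy, same truth object
  expect_identical(pr2$scan1$truth, pr2$scan2$truth)
})

test_that("repositioning jitter changes the grid but not the truth", {
  sp <- fast_spec(n_slices = 6)
  pr <- make_rescan_pair(sp, jitter = list(slice_offset_sd_mm = 2,
                                           rotation_sd_deg = 2,
                                           reseed_noise = TRUE),
                         seed = 12, compute_truth = FALSE)
  expect_false(isTRUE(all.equal(pr$scan1$sax[[1]]$affine, pr$scan2$sax[[1]]$affine)))
  expect_true(abs(pr$jitter_drawn$slice_offset_mm) < 4 * 2 + 1e-9)
})

test_that("excessive slice offset warns about aliasing", {
  sp <- fast_spec(n_slices = 6)
  expect_warning(make_phantom(sp, seed = 1, truth = FALSE,
                              jitter = list(slice_offset_mm = 10)),
                 "aliasing")
})

test_that("error audit: perfect agreement, degenerate prevalence, validation", {
  aud <- simulate_error_audit(100, 0.1, 1, seed = 3)
  expect_identical(aud[, 1], aud[, 2])
  aud0 <- simulate_error_audit(100, 0, 0.9, seed = 3)
  expect_true(all(aud0 == 0))
  expect_true(attr(aud0, "degenerate"))
  expect_error(simulate_error_audit(1, 0.5, 0.5), "n_cases")
  expect_error(simulate_error_audit(10, 1.5, 0.5), "error_prevalence")
  # marginal rate approximates the requested prevalence
  audl <- simulate_error_audit(5000, 0.1, 0.95, seed = 4)
  expect_lt(abs(mean(audl) - 0.1 * (1 - 0.025)), 0.02)
})

test_that("audit determinism: identical arguments give identical labels", {
  expect_identical(simulate_error_audit(200, 0.05, 0.9, seed = 8),
                   simulate_error_audit(200, 0.05, 0.9, seed = 8))
})

test_that("survival simulation: censoring horizon and degeneracy flags", {
  cov <- data.frame(edvi = rnorm(50, 75, 10))
  expect_warning(
    s0 <- simulate_cohort_survival(list(n_subjects = 50, beta_per_covariate = 0.02,
                                        baseline_rate = 0.05, censor_horizon = 0,
                                        seed = 1), cov),
    "censored")
  expect_true(all(s0$event == 0))
  expect_true(attr(s0, "degenerate"))

  s1 <- simulate_cohort_survival(list(n_subjects = 50, beta_per_covariate = 0.02,
                                      baseline_rate = 0.05, censor_horizon = 5,
                                      seed = 1), cov)
  expect_true(all(s1$time <= 5))
  expect_true(all(s1$event %in% 0:1))
  expect_true(any(s1$event == 1))
  expect_error(simulate_cohort_survival(list(n_subjects = 10, beta_per_covariate = 0,
                                             baseline_rate = 0.05, censor_horizon = 5,
                                             seed = 1), cov), "one row per subject")
})

test_that("higher hazard slope produces earlier events", {
  cov <- data.frame(x = seq(-2, 2, length.out = 400))
  s <- simulate_cohort_survival(list(n_subjects = 400, beta_per_covariate = 1.5,
                                     baseline_rate = 0.2, censor_horizon = 20,
                                     seed = 2), cov)
  hi <- s$time[s$x > 1]; lo <- s$time[s$x < -1]
  expect_lt(mean(hi), mean(lo))
})
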