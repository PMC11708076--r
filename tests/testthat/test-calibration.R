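# Calibration procedures: ladder collection, linearisation fitting,
# sensitivity estimation and calibration file I/O.

test_that("ladder collection honours fraction and clamping contracts", {
  inst <- small_instrument(32, noise_scale = 0)
  scene <- flat_scene(LADDER_SCENE_LEVEL)
  pose <- gimbal_state(0L, 0L)
  one <- collect_linearisation_ladder(inst, scene, pose, fractions = 1.0)
  expect_length(one$times, 1)
  expect_equal(one$times, one$base_time)
  lad <- collect_linearisation_ladder(inst, scene, pose)
  expect_true(all(diff(lad$times) > 0))
  expect_true(all(lad$times >= 500))
  expect_length(lad$times, 16)
  expect_error(
    collect_linearisation_ladder(inst, scene, pose, fractions = c(0.5, 2)),
    "0, 1.5")
  # too-dim scene: ladder cap reached -> warning
  expect_warning(
    collect_linearisation_ladder(inst, flat_scene(1e-9), pose,
                                 fractions = c(0.5, 1)),
    "too dim")
})

test_that("noise-free linear ladder response is proportional to time", {
  inst <- small_instrument(32, nonlinearity_a = 1, nonlinearity_b = 0,
                           noise_scale = 0, quantise = FALSE)
  lad <- collect_linearisation_ladder(inst, flat_scene(LADDER_SCENE_LEVEL),
                                      gimbal_state(0L, 0L))
  usable <- which(!vapply(lad$light, `[[`, logical(1), "saturated"))
  expect_gte(length(usable), 12)
  pk <- which.max(lad$light[[max(usable)]]$counts -
                    lad$dark[[max(usable)]]$counts)
  y <- vapply(usable, function(i) {
    lad$light[[i]]$counts[pk] - lad$dark[[i]]$counts[pk]
  }, numeric(1))
  expect_equal(y / lad$times[usable],
               rep(y[1] / lad$times[usable][1], length(usable)),
               tolerance = 1e-9)
})

test_that("perfectly linear noise-free sensor fits a = 1, R^2 = 1", {
  inst <- small_instrument(64, nonlinearity_a = 1, nonlinearity_b = 0,
                           noise_scale = 0, quantise = FALSE)
  lad <- collect_linearisation_ladder(inst, flat_scene(LADDER_SCENE_LEVEL),
                                      gimbal_state(0L, 0L))
  fit <- fit_linearisation(lad)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("ground-truth nonlinearity is recovered from a noisy ladder", {
  sim <- sim_ladder(seed = 17)
  fit0 <- fit_linearisation(sim$ladder)
  scale <- true_scale_at(sim$instrument, fit0$peak_bin)
  fit <- fit_linearisation(sim$ladder, scale = scale)
  expect_lt(abs(fit$a - 1.04) / 1.04, 0.02)
  expect_gt(fit$r_squared, 0.999)
  expect_true(all(diff(fit$ladder$integration_time) > 0))
})

test_that("recovery bias of a vanishes as noise vanishes", {
  bias <- vapply(c(1, 0.3, 0), function(ns) {
    errs <- vapply(1:6, function(s) {
      sim <- sim_ladder(seed = 100 + s, noise_scale = ns, n = 96L)
      fit_linearisation(sim$ladder)$a - 1.04
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_true(all(diff(bias) <= 0))
  expect_lt(bias[3], 2e-3)
})

test_that("fit is invariant to a global gain on all counts", {
  sim <- sim_ladder(seed = 23, n = 96L)
  fit1 <- fit_linearisation(sim$ladder)
  gained <- sim$ladder
  gained$light <- lapply(gained$light, function(f) {
    # rescale counts and ceiling together so saturation flags are preserved
    raw_frame(f$counts * 1.7, f$integration_time,
              saturation_level = f$saturation_level * 1.7)
  })
  gained$dark <- lapply(gained$dark, function(f) {
    dark_frame(f$counts * 1.7, f$integration_time)
  })
  fit2 <- fit_linearisation(gained)
  expect_equal(fit2$a, fit1$a, tolerance = 1e-6)
})

test_that("saturated and non-positive ladder points are handled", {
  inst <- small_instrument(32, noise_scale = 0)
  # bright scene chosen so the sensor saturates at ~1.2x the auto-exposed
  # base time: the topmost fraction (1.5) saturates and must be removed
  scene <- flat_scene(0.0667)
  lad <- collect_linearisation_ladder(inst, scene, gimbal_state(0L, 0L))
  expect_true(any(vapply(lad$light, `[[`, logical(1), "saturated")))
  fit <- fit_linearisation(lad)
  expect_false(any(fit$ladder$light_peak >= inst$saturation_level))
  # fewer than 4 usable points errors
  short <- collect_linearisation_ladder(inst, scene, gimbal_state(0L, 0L),
                                        fractions = c(0.5, 1, 1.5))
  expect_error(fit_linearisation(short), "fewer than 4")
})

test_that("sensitivity fitting recovers a flat instrument exactly", {
  # flat reference (Le = 1), flat sensitivity k -> s = k everywhere
  k <- 25
  inst <- small_instrument(32, sensitivity_fn = function(wl) rep(k, length(wl)),
                           nonlinearity_a = 1, nonlinearity_b = 0,
                           noise_scale = 0, quantise = FALSE)
  scene <- flat_scene(1e-4)
  cube <- run_scan(inst, scene, scan_plan(0, 2 * 64, 64, 0, 16, 16))
  ref <- spectrum(inst$wl, rep(1e-4, 32), kind = "radiance")
  sens <- fit_sensitivity(cube, ref, c(1, 0))
  expect_equal(sens$values, rep(k, 32), tolerance = 1e-6)
})

test_that("ground-truth sensitivity curve is recovered at high SNR", {
  inst <- instrument_model(nonlinearity_a = 1.04, nonlinearity_b = 0.2,
                           rng_seed = 31)
  cube <- standard_cube(inst)
  expect_length(unique(as.vector(cube$itime)), 1)
  ref <- spectrum(inst$wl, standard_radiance_fn(inst$wl), kind = "radiance")
  sens <- fit_sensitivity(cube, ref, c(1.04, 0.2))
  expect_equal(sens$n_pixels, 35L)
  band <- inst$wl >= 350 & inst$wl <= 800
  rel <- abs(sens$values[band] - inst$sensitivity[band]) /
    inst$sensitivity[band]
  expect_lt(max(rel), 0.05)
})

test_that("reference coverage gaps mark sensitivity undefined", {
  inst <- small_instrument(32, noise_scale = 0)
  cube <- run_scan(inst, standard_scene(), scan_plan(0, 64, 64, 0, 0, 1))
  # reference covering only 400-700 nm
  wl_ref <- seq(400, 700, by = 10)
  ref <- spectrum(wl_ref, standard_radiance_fn(wl_ref), kind = "radiance")
  sens <- fit_sensitivity(cube, ref, c(1, 0))
  expect_true(any(is.na(sens$values)))
  covered <- inst$wl >= 400 & inst$wl <= 700
  expect_true(all(!is.na(sens$values[covered])))
})

test_that("averaging 35 standard pixels reduces curve noise ~ sqrt(35)", {
  inst <- small_instrument(16, nonlinearity_a = 1.04, nonlinearity_b = 0.2,
                           rng_seed = 77)
  pose <- gimbal_state(0L, 0L)
  scene <- standard_scene()
  t <- 64000
  le <- standard_radiance_fn(inst$wl)
  est_s <- function(n_px) {
    light <- rowMeans(vapply(seq_len(n_px), function(i) {
      expose(inst, scene, pose, t)$counts
    }, numeric(16)))
    dark <- rowMeans(vapply(1:2, function(i) {
      dark_position_expose(inst, t)$counts
    }, numeric(16)))
    linearise_counts(light, dark, 1.04, 0.2)[8] / (t * le[8])
  }
  reps <- 60
  s1 <- vapply(seq_len(reps), function(i) est_s(1), numeric(1))
  s35 <- vapply(seq_len(reps), function(i) est_s(35), numeric(1))
  ratio <- sd(s1) / sd(s35)
  # sqrt(35) = 5.92; wide band reflects the sd-of-sd estimation error at 60
  # replicates (~16% relative on the ratio)
  expect_gt(ratio, 3.9)
  expect_lt(ratio, 8.9)
})

test_that("calibration records round-trip through calibration_data.txt", {
  wl_cal <- small_wl_cal(16)
  sens <- sensitivity_curve(wavelengths(wl_cal),
                            default_sensitivity(wavelengths(wl_cal)))
  rec1 <- calibration_record(1L, wl_cal, 1.04, 0.2, sens)
  rec2 <- calibration_record(2L, wl_cal, 0.98, -0.05, sens)
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(list(rec1, rec2), path)
  # reader must ignore blank lines and comments
  lines <- readLines(path)
  writeLines(c("# calibration data", "", lines), path)
  recs <- read_calibration(path, n_photosites = 16)
  expect_length(recs, 2)
  back <- read_calibration(path, unit_id = 2L, n_photosites = 16)
  expect_equal(back$lin_a, 0.98)
  expect_equal(back$lin_b, -0.05)
  expect_equal(back$sensitivity$values, sens$values, tolerance = 1e-8)
  expect_equal(back$wavelength_cal$coefficients, wl_cal$coefficients,
               tolerance = 1e-8)
  expect_error(read_calibration(path, unit_id = 9L), "no calibration")
})

test_that("reference radiance CSV reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,radiance", "400,0.01", "500,0.02", "600,0.015"),
             path)
  ref <- read_reference_radiance(path)
  expect_s3_class(ref, "wb_spectrum")
  expect_equal(ref$kind, "radiance")
  expect_equal(ref$values, c(0.01, 0.02, 0.015))
})

test_that("ladder CSV round trip", {
  sim <- sim_ladder(seed = 3, n = 16L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ladder(sim$ladder, path)
  back <- read_ladder(path)
  expect_equal(back$times, sim$ladder$times)
  for (i in seq_along(back$times)) {
    expect_equal(back$light[[i]]$counts, sim$ladder$light[[i]]$counts)
    expect_equal(back$dark[[i]]$counts, sim$ladder$dark[[i]]$counts)
  }
  fit1 <- fit_linearisation(sim$ladder)
  fit2 <- fit_linearisation(back)
  expect_equal(fit2$a, fit1$a, tolerance = 1e-9)
  expect_equal(fit2$b, fit1$b, tolerance = 1e-9)
})
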