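# Radiometric conversion and rendering.

test_that("noise-free radiance round trip recovers the scene", {
  inst <- small_instrument(48, nonlinearity_a = 1.04, nonlinearity_b = 0.2,
                           noise_scale = 0, quantise = FALSE)
  le_fn <- function(w) 1e-3 * exp(-0.5 * ((w - 520) / 80)^2) + 5e-5
  scene <- scene_model(function(az, el, w) le_fn(w), "roundtrip")
  cube <- run_scan(inst, scene, scan_plan(0, 2 * 64, 64, 0, 16, 16))
  rc <- cube_to_radiance(cube, as_calibration_record(inst))
  truth <- le_fn(rc$wavelengths)
  for (ri in 1:2) for (ci in 1:3) {
    expect_equal(rc$le[ri, ci, ], truth, tolerance = 1e-4)
  }
})

test_that("zero-count pixel maps to zero radiance", {
  inst <- small_instrument(16, noise_scale = 0)
  cube <- run_scan(inst, flat_scene(0), scan_plan(0, 0, 1, 0, 0, 1))
  rc <- cube_to_radiance(cube, as_calibration_record(inst))
  expect_equal(rc$le[1, 1, ], rep(0, 16))
})

test_that("radiance is exposure-invariant and linear in the scene", {
  inst <- small_instrument(32, nonlinearity_a = 1.02, nonlinearity_b = -0.1,
                           noise_scale = 0, quantise = FALSE)
  cal <- as_calibration_record(inst)
  scene1 <- flat_scene(1e-3)
  # same scene point captured at different integration times via different
  # exposure ceilings
  c_long <- run_scan(inst, scene1, scan_plan(0, 0, 1, 0, 0, 1))
  c_short <- run_scan(inst, scene1,
                      scan_plan(0, 0, 1, 0, 0, 1, max_integration = 2e4))
  expect_false(c_long$itime[1, 1] == c_short$itime[1, 1])
  le1 <- cube_to_radiance(c_long, cal)$le[1, 1, ]
  le2 <- cube_to_radiance(c_short, cal)$le[1, 1, ]
  expect_equal(le1, le2, tolerance = 1e-6)
  # doubling scene radiance doubles Le everywhere
  c_double <- run_scan(inst, flat_scene(2e-3),
                       scan_plan(0, 0, 1, 0, 0, 1, max_integration = 2e4))
  le3 <- cube_to_radiance(c_double, cal)$le[1, 1, ]
  expect_equal(le3, 2 * le2, tolerance = 1e-6)
})

test_that("missing matched dark errors with the integration time named", {
  inst <- small_instrument(16, noise_scale = 0)
  cube <- run_scan(inst, flat_scene(1e-3), scan_plan(0, 0, 1, 0, 0, 1))
  cube$darks <- list()
  expect_error(cube_to_radiance(cube, as_calibration_record(inst)),
               as.character(cube$itime[1, 1]))
})

test_that("reflectance is percent relative to the standard pixel", {
  wl <- seq(350, 800, by = 10)
  std <- rep(2e-3, length(wl))
  rc <- make_rcube(wl, list(std, std / 2, std * 0.25), 1, 3)
  refl <- to_reflectance(rc, c(1, 1))
  expect_equal(refl$values[1, 1, ], rep(100, length(wl)))
  expect_equal(refl$values[1, 2, ], rep(50, length(wl)))
  expect_equal(refl$values[1, 3, ], rep(25, length(wl)))
  # known standard reflectance rescales
  refl99 <- to_reflectance(rc, c(1, 1), standard_reflectance = 0.99)
  expect_equal(refl99$values[1, 2, ], rep(49.5, length(wl)))
  # saturated or interpolated standards are rejected
  rc_sat <- make_rcube(wl, list(std, std), 1, 2,
                       sat = matrix(c(TRUE, FALSE), 1, 2))
  expect_error(to_reflectance(rc_sat, c(1, 1)), "saturated")
  rc_int <- make_rcube(wl, list(std, std), 1, 2,
                       interp = matrix(c(TRUE, FALSE), 1, 2))
  expect_error(to_reflectance(rc_int, c(1, 1)), "not a measured")
})

test_that("pastel reflectance recovery through the full simulator", {
  inst <- instrument_model(nonlinearity_a = 1.04, nonlinearity_b = 0.2,
                           rng_seed = 41)
  illum <- function(w) 0.02 * (0.4 + 0.6 * exp(-0.5 * ((w - 560) / 180)^2))
  pastel <- function(w) 0.35 + 0.3 * exp(-0.5 * ((w - 620) / 60)^2) +
    0.15 * exp(-0.5 * ((w - 380) / 40)^2)
  scene <- scene_model(function(az, el, w) {
    if (az < 6) illum(w) else illum(w) * pastel(w)
  }, "pastel-board")
  cube <- run_scan(inst, scene, scan_plan(0, 64, 64, 0, 0, 1))
  rc <- cube_to_radiance(cube, as_calibration_record(inst))
  refl <- to_reflectance(rc, c(1, 1))
  band <- rc$wavelengths >= 350 & rc$wavelengths <= 750
  err <- abs(refl$values[1, 2, band] / 100 - pastel(rc$wavelengths[band]))
  expect_lt(mean(err), 0.01)
})

test_that("sRGB rendering: black, neutral grey and hue ordering", {
  wl <- seq(350, 800, by = 5)
  black <- make_rcube(wl, list(rep(0, length(wl)), rep(0, length(wl))), 1, 2)
  img <- render_srgb(black)
  expect_true(all(img == 0))
  # equal-energy pixels -> neutral grey (equal-energy white balance)
  ee <- rep(1e-3, length(wl))
  grey <- render_srgb(make_rcube(wl, list(ee, ee, ee, ee), 2, 2))
  for (k in 1:3) expect_equal(grey[, , k], grey[, , 1])
  imbalance <- diff(range(grey[1, 1, ])) / max(grey[1, 1, ])
  expect_lt(imbalance, 0.02)
  # monochromatic 450 nm -> blue channel strictly dominant
  mono <- ifelse(abs(wl - 450) < 6, 1e-3, 0)
  px <- render_srgb(make_rcube(wl, list(mono, ee), 1, 2))
  expect_gt(px[1, 1, 3], px[1, 1, 1])
  expect_gt(px[1, 1, 3], px[1, 1, 2])
  expect_true(all(px >= 0 & px <= 255))
})

test_that("extended-range rendering maps NIR/Y/UV to R/G/B", {
  wl <- seq(330, 870, by = 5)
  uv_only <- ifelse(wl < 395, 1e-3, 0)
  nir_only <- ifelse(wl > 755, 1e-3, 0)
  vis <- exp(-0.5 * ((wl - 555) / 40)^2) * 1e-3
  img <- render_extended(make_rcube(wl, list(uv_only, nir_only, vis), 1, 3))
  expect_gt(img[1, 1, 3], img[1, 1, 1])  # UV pixel blue-dominant
  expect_gt(img[1, 2, 1], img[1, 2, 3])  # NIR pixel red-dominant
  expect_gt(img[1, 3, 2], 0)
})

test_that("band integrals match a direct trapezoid oracle", {
  wl <- sort(c(seq(340, 860, by = 7), 624, 698))  # non-uniform grid
  le <- 1e-3 * (1 + sin(wl / 40))
  rc <- make_rcube(wl, list(le), 1, 1)
  band <- c(620, 700)
  inb <- which(wl >= band[1] & wl <= band[2])
  # independent trapezoid integral restricted to in-band samples, matching
  # the package's masked-weight convention
  w <- numeric(length(wl))
  w[2:(length(wl) - 1)] <- (wl[3:length(wl)] - wl[1:(length(wl) - 2)]) / 2
  w[1] <- (wl[2] - wl[1]) / 2
  w[length(wl)] <- diff(wl[length(wl) - 1:0]) / 2
  oracle <- sum((le * w)[inb])
  expect_equal(whiskbroom:::band_integral(rc, band), oracle,
               tolerance = 1e-12)
})

test_that("saturation mask equals the stored flags", {
  inst <- small_instrument(16, noise_scale = 0)
  cube <- run_scan(inst, flat_scene(1e-3), scan_plan(0, 64, 64, 0, 0, 1))
  expect_true(all(!render_saturation_mask(cube)))
  cube$sat[1, 2] <- TRUE
  m <- render_saturation_mask(cube)
  expect_identical(sum(m), 1L)
  expect_true(m[1, 2])
})

test_that("hdr-night saturation mask flags exactly the flare", {
  inst <- small_instrument(32, rng_seed = 12)
  scene <- make_reference_scene("hdr-night")
  plan <- scan_plan(0, 2047 - 64, 64, 0, 128, 64)
  cube <- run_scan(inst, scene, plan)
  m <- render_saturation_mask(cube)
  flare <- attr(scene, "flare")
  # flare at az 33.75 (col 4), el 22.5 (row 3)
  expect_true(m[3, 4])
  expect_identical(sum(m), 1L)
})

test_that("NDVI obeys its bounds and band-integral definition", {
  wl <- seq(350, 870, by = 5)
  flat <- rep(1e-3, length(wl))
  none <- rep(0, length(wl))
  nir_only <- ifelse(wl >= 750 & wl <= 850, 1e-3, 0)
  veg <- ifelse(wl >= 720, 1e-3, 2e-4)  # red-edge step
  rc <- make_rcube(wl, list(flat, none, nir_only, veg), 2, 2)
  ndvi <- render_ndvi(rc)
  w <- trapezoid_weights(wl)
  bi <- function(le, band) sum((le * w)[wl >= band[1] & wl <= band[2]])
  # Red = NIR -> 0 (flat spectrum has equal band means only if equal
  # integrals; compute the oracle instead of assuming symmetry)
  oracle_flat <- (bi(flat, c(750, 850)) - bi(flat, c(620, 700))) /
    (bi(flat, c(750, 850)) + bi(flat, c(620, 700)))
  expect_equal(ndvi[1, 1], oracle_flat, tolerance = 1e-12)
  expect_equal(ndvi[1, 2], 0)      # 0/0 -> 0
  expect_equal(ndvi[2, 1], 1)      # NIR > 0, Red = 0 -> +1
  oracle_veg <- (bi(veg, c(750, 850)) - bi(veg, c(620, 700))) /
    (bi(veg, c(750, 850)) + bi(veg, c(620, 700)))
  expect_equal(ndvi[2, 2], oracle_veg, tolerance = 1e-12)
  expect_true(all(ndvi >= -1 & ndvi <= 1))
})

test_that("cone catches are quantal trapezoid integrals", {
  wl <- seq(320, 700, by = 2)
  emission <- ifelse(abs(wl - 450) <= 10, 2e-3, 0)
  rc <- make_rcube(wl, list(emission, rep(0, length(wl))), 1, 2)
  rec_wl <- seq(300, 700, by = 5)
  receptors <- receptor_set(
    rec_wl,
    sws = exp(-0.5 * ((rec_wl - 445) / 30)^2),
    # truncated support: exactly zero below 550 nm (disjoint from emission)
    lws = ifelse(rec_wl > 550, exp(-0.5 * ((rec_wl - 605) / 40)^2), 0))
  q <- cone_catch(rc, receptors)
  # independent trapezoid oracle: loop over intervals
  s_interp <- approx(rec_wl, exp(-0.5 * ((rec_wl - 445) / 30)^2),
                     xout = wl)$y
  integrand <- emission * wl * s_interp
  oracle <- 0
  for (i in seq_len(length(wl) - 1)) {
    oracle <- oracle + (integrand[i] + integrand[i + 1]) / 2 *
      (wl[i + 1] - wl[i])
  }
  expect_equal(q$sws[1, 1], oracle, tolerance = 1e-6)
  # zero radiance -> 0 for every receptor
  expect_equal(q$sws[1, 2], 0)
  expect_equal(q$lws[1, 2], 0)
  # receptor support disjoint from the emission's support -> exactly 0
  expect_equal(q$lws[1, 1], 0)
  # additive over spectra and homogeneous of degree 1
  rc2 <- make_rcube(wl, list(3 * emission), 1, 1)
  q2 <- cone_catch(rc2, receptors)
  expect_equal(q2$sws[1, 1], 3 * q$sws[1, 1], tolerance = 1e-12)
  # zero overlap errors
  nir_rec <- receptor_set(seq(900, 1000, by = 10), nir = rep(1, 11))
  expect_error(cone_catch(rc, nir_rec), "no wavelength overlap")
})

test_that("receptor CSV fixture loads and integrates", {
  path <- system.file("extdata", "sensitivity_data_synthetic.csv",
                      package = "whiskbroom")
  receptors <- read_receptors(path)
  expect_setequal(colnames(receptors$values), c("uv", "sws", "mws", "lws"))
  wl <- seq(320, 700, by = 5)
  rc <- make_rcube(wl, list(rep(1e-3, length(wl))), 1, 1)
  q <- cone_catch(rc, receptors)
  expect_length(q, 4)
  expect_true(all(vapply(q, function(m) m[1, 1], numeric(1)) > 0))
})

test_that("scene peak ratio excludes interpolated and saturated pixels", {
  wl <- seq(400, 700, by = 10)
  hi <- rep(1, length(wl)); lo <- rep(2e-5, length(wl))
  huge <- rep(100, length(wl))
  rc <- make_rcube(wl, list(hi, lo, huge, lo), 2, 2,
                   sat = matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2,
                                byrow = TRUE),
                   interp = matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2,
                                   byrow = TRUE))
  expect_equal(scene_peak_ratio(rc), 1 / 2e-5)
  # flat cube -> ratio 1
  rcf <- make_rcube(wl, list(hi, hi), 1, 2)
  expect_equal(scene_peak_ratio(rcf), 1)
  # degenerate minimum -> infinite with warning
  rc0 <- make_rcube(wl, list(hi, rep(0, length(wl))), 1, 2)
  expect_warning(r <- scene_peak_ratio(rc0), "infinite")
  expect_identical(r, Inf)
})

test_that("spectrum export writes kind and values", {
  sp <- spectrum(c(400, 500, 600), c(0.1, 0.25, 0.2), kind = "radiance")
  path <- withr::local_tempfile(fileext = ".csv")
  export_spectrum(sp, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# kind: radiance")
  expect_identical(lines[2], "wavelength_nm,value")
  df <- read.csv(path, comment.char = "#")
  expect_equal(df$value, c(0.1, 0.25, 0.2))
})
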