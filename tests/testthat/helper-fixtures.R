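# Shared fixture builders. Most tests run on a reduced photosite count for
# speed; every operation under test is length-generic.

# linear wavelength calibration covering 320-880 nm over n photosites
small_wl_cal <- function(n = 64L) {
  wavelength_calibration(c(320, 560 / (n - 1)), n_photosites = n)
}

# instrument with a reduced detector; defaults mirror instrument_model()
small_instrument <- function(n = 64L, ...) {
  instrument_model(wavelength_cal = small_wl_cal(n), n_photosites = n, ...)
}

# spectrally flat, isotropic scene
flat_scene <- function(level) {
  make_reference_scene("flat", level = level)
}

# hand-rolled radiance_cube for renderer tests: `spectra` is a list of
# radiance vectors laid out row-major on an nr x nc grid
make_rcube <- function(wl, spectra, nr, nc, sat = NULL, interp = NULL) {
  le <- array(NA_real_, dim = c(nr, nc, length(wl)))
  k <- 0L
  for (ri in seq_len(nr)) for (ci in seq_len(nc)) {
    k <- k + 1L
    le[ri, ci, ] <- spectra[[k]]
  }
  if (is.null(sat)) sat <- matrix(FALSE, nr, nc)
  if (is.null(interp)) interp <- matrix(FALSE, nr, nc)
  structure(list(wavelengths = wl, le = le, sat = sat, interp = interp,
                 measured = !interp, metadata = list()),
            class = "radiance_cube")
}

# flat-level calibration scene bright enough that the auto-exposed ladder
# tops out in the 200,000-800,000 microsecond range on the default sensor
LADDER_SCENE_LEVEL <- 3.5e-3

# default-size instrument + ladder for linearisation recovery tests
sim_ladder <- function(seed, a = 1.04, b = 0.2, noise_scale = 1,
                       n = WB_N_PHOTOSITES) {
  inst <- if (n == WB_N_PHOTOSITES) {
    instrument_model(nonlinearity_a = a, nonlinearity_b = b,
                     noise_scale = noise_scale, rng_seed = seed)
  } else {
    small_instrument(n, nonlinearity_a = a, nonlinearity_b = b,
                     noise_scale = noise_scale, rng_seed = seed)
  }
  ladder <- collect_linearisation_ladder(
    inst, flat_scene(LADDER_SCENE_LEVEL), gimbal_state(0L, 0L))
  list(instrument = inst, ladder = ladder)
}

# ground-truth linear-counts-per-microsecond scale at a peak bin
true_scale_at <- function(inst, bin, level = LADDER_SCENE_LEVEL) {
  inst$sensitivity[bin] * level
}

# white-standard radiance field (broadband lamp on a near-perfect diffuser)
standard_radiance_fn <- function(w) {
  0.02 * (0.4 + 0.6 * exp(-0.5 * ((w - 560) / 180)^2))
}

standard_scene <- function() {
  scene_model(function(az, el, w) standard_radiance_fn(w), "white-standard")
}

# 7 x 5 = 35-pixel scan of the white standard
standard_cube <- function(inst) {
  run_scan(inst, standard_scene(),
           scan_plan(0, 6 * 64, 64, 0, 4 * 16, 16))
}
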