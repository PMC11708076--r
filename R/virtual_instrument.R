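# Forward model of the spectrometer + gimbal + scene. Everything downstream
# (acquisition, calibration, radiometry) is exercised against this simulated
# instrument, whose ground truth is known exactly.

#' Default spectral sensitivity curve of the simulated detector
#'
#' A smooth bell peaking near 580 nm, in linear counts per microsecond per
#' radiance unit (W sr^-1 m^-2 nm^-1). Loosely shaped like a silicon CMOS
#' response behind a UV-transmitting optic; the absolute scale is chosen so
#' that typical night-scene radiances (1e-6 .. 1 W sr^-1 m^-2 nm^-1) span
#' the instrument's integration-time ladder.
#'
#' @param wl Wavelengths in nm.
#' @param peak Peak sensitivity in counts per microsecond per radiance unit.
#' @return Numeric vector of sensitivities, same length as `wl`.
#' @export
default_sensitivity <- function(wl, peak = 50) {
  peak * exp(-0.5 * ((wl - 580) / 150)^2)
}

#' Default wavelength calibration of the simulated unit
#'
#' A gently curved polynomial typical of this detector family, covering
#' roughly 318-871 nm over 288 photosites.
#'
#' @param n_photosites Number of photosites.
#' @return A [wavelength_calibration()].
#' @export
default_wavelength_cal <- function(n_photosites = WB_N_PHOTOSITES) {
  wavelength_calibration(c(318, 2.0, -2.5e-4), n_photosites = n_photosites)
}

#' Construct a simulated instrument
#'
#' The sensor's raw output embodies the inverse of the linearisation model:
#' ideal linear counts are `c(lambda) = sensitivity(lambda) * Le(lambda) * t`
#' and the raw signal above dark is `exp((ln c - b) / a)`, so that
#' [linearise_counts()] with the true `(a, b)` recovers `c` exactly. Dark
#' counts are affine in integration time (`dark_offset + dark_slope * t`).
#' Noise is Gaussian with a shot-noise-like standard deviation
#' `noise_scale * sqrt(noise_gain * mu + read_noise^2)` where `mu` is the
#' expected raw count; set `noise_scale = 0` for a noise-free sensor. Counts
#' are clipped at `saturation_level` and quantised to integers by default
#' (set `quantise = FALSE` for continuous-count analyses such as exact
#' round-trip checks).
#'
#' The instrument carries its own random-number stream seeded by `rng_seed`:
#' the same seed and the same call sequence give bit-identical frames, and
#' instrument noise never disturbs the caller's RNG state.
#'
#' @param sensitivity_fn Function of wavelength (nm) returning sensitivity in
#'   counts per microsecond per radiance unit.
#' @param nonlinearity_a,nonlinearity_b Ground-truth linearisation
#'   coefficients embodied by the sensor.
#' @param dark_offset Per-photosite dark offset in counts (scalar recycled).
#' @param dark_slope Dark current in counts per microsecond (scalar recycled).
#' @param noise_gain Shot-noise gain (counts of variance per expected count).
#' @param read_noise Read noise standard deviation in counts.
#' @param noise_scale Overall noise multiplier; 0 disables noise.
#' @param noise_sd_fn Optional function mapping expected counts to noise SD,
#'   overriding the default model.
#' @param saturation_level ADC ceiling in counts.
#' @param wavelength_cal A [wavelength_calibration()].
#' @param n_photosites Number of photosites.
#' @param quantise Round counts to integers (ADC behaviour)?
#' @param rng_seed Seed of the instrument's private RNG stream.
#' @param unit_id Integer unit identifier carried into scan metadata.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(sensitivity_fn = default_sensitivity,
                             nonlinearity_a = 1,
                             nonlinearity_b = 0,
                             dark_offset = 100,
                             dark_slope = 5e-5,
                             noise_gain = 1,
                             read_noise = 6,
                             noise_scale = 1,
                             noise_sd_fn = NULL,
                             saturation_level = WB_SATURATION_LEVEL,
                             wavelength_cal = NULL,
                             n_photosites = WB_N_PHOTOSITES,
                             quantise = TRUE,
                             rng_seed = 1L,
                             unit_id = 1L) {
  n_photosites <- as.integer(n_photosites)
  if (is.null(wavelength_cal)) {
    wavelength_cal <- default_wavelength_cal(n_photosites)
  }
  stopifnot(inherits(wavelength_cal, "wavelength_calibration"))
  if (wavelength_cal$n_photosites != n_photosites) {
    stop("wavelength calibration covers ", wavelength_cal$n_photosites,
         " photosites, instrument has ", n_photosites)
  }
  wl <- wavelengths(wavelength_cal)
  sens <- sensitivity_fn(wl)
  if (any(sens < 0)) stop("sensitivity must be non-negative")
  dark_offset <- rep_len(as.numeric(dark_offset), n_photosites)
  dark_slope <- rep_len(as.numeric(dark_slope), n_photosites)
  if (is.null(noise_sd_fn)) {
    force(noise_gain); force(read_noise); force(noise_scale)
    noise_sd_fn <- function(mu) {
      noise_scale * sqrt(noise_gain * pmax(mu, 0) + read_noise^2)
    }
  }
  max_dark <- max(dark_offset + dark_slope * 30e6)
  if (saturation_level <= max_dark) {
    stop("saturation level must exceed the maximum dark count")
  }
  model <- structure(
    list(wavelength_cal = wavelength_cal,
         wl = wl,
         sensitivity = sens,
         nonlinearity_a = nonlinearity_a,
         nonlinearity_b = nonlinearity_b,
         dark_offset = dark_offset,
         dark_slope = dark_slope,
         noise_sd_fn = noise_sd_fn,
         noise_scale = noise_scale,
         saturation_level = saturation_level,
         n_photosites = n_photosites,
         quantise = quantise,
         rng_seed = as.integer(rng_seed),
         unit_id = as.integer(unit_id),
         rng_env = new.env(parent = emptyenv())),
    class = "instrument_model")
  model
}

#' Reset an instrument's private RNG stream to its seed
#'
#' @param model An [instrument_model()].
#' @return The model, invisibly.
#' @export
reset_instrument_rng <- function(model) {
  stopifnot(inherits(model, "instrument_model"))
  if (exists("state", envir = model$rng_env, inherits = FALSE)) {
    rm("state", envir = model$rng_env)
  }
  invisible(model)
}

# Draw n standard normals from the instrument's private stream without
# touching the caller's .Random.seed.
instrument_rnorm <- function(model, n) {
  glob <- globalenv()
  had_seed <- exists(".Random.seed", envir = glob, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = glob) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = glob)
    else if (exists(".Random.seed", envir = glob, inherits = FALSE)) {
      rm(".Random.seed", envir = glob)
    }
  })
  if (!exists("state", envir = model$rng_env, inherits = FALSE)) {
    set.seed(model$rng_seed)
    assign("state", get(".Random.seed", envir = glob),
           envir = model$rng_env)
  }
  assign(".Random.seed", get("state", envir = model$rng_env), envir = glob)
  x <- stats::rnorm(n)
  assign("state", get(".Random.seed", envir = glob), envir = model$rng_env)
  x
}

#' Gimbal pose in stepper-motor steps
#'
#' Pan covers azimuth (360 degrees per `steps_per_revolution * gear_ratio`
#' steps); tilt covers elevation, mechanically limited to -20..90 degrees.
#' An optional per-axis gear ratio (printed reduction gearing between motor
#' and axis) defaults to 1.
#'
#' @param pan_step,tilt_step Integer stepper positions.
#' @param steps_per_revolution Motor steps per revolution (default 2048).
#' @param gear_ratio Length-2 numeric (pan, tilt) gear ratios.
#' @return An object of class `gimbal_state` with derived `azimuth_deg` and
#'   `elevation_deg`.
#' @export
gimbal_state <- function(pan_step, tilt_step,
                         steps_per_revolution = 2048L,
                         gear_ratio = c(1, 1)) {
  gear_ratio <- rep_len(as.numeric(gear_ratio), 2L)
  az <- pan_step * 360 / (steps_per_revolution * gear_ratio[1])
  el <- tilt_step * 360 / (steps_per_revolution * gear_ratio[2])
  if (el < -20 - 1e-9 || el > 90 + 1e-9) {
    stop("tilt position ", el,
         " degrees is outside the mechanical range -20..90")
  }
  structure(list(pan_step = as.integer(pan_step),
                 tilt_step = as.integer(tilt_step),
                 steps_per_revolution = as.integer(steps_per_revolution),
                 gear_ratio = gear_ratio,
                 azimuth_deg = az %% 360,
                 elevation_deg = el),
            class = "gimbal_state")
}

#' Construct a scene model
#'
#' A scene is a per-direction spectral radiance field: `radiance_fn(az, el,
#' wl)` must return non-negative Le (W sr^-1 m^-2 nm^-1) at the requested
#' wavelengths for any azimuth in `[0, 360)` and elevation in `[-20, 90]`.
#' The instrument samples the field at the pose's central direction only
#' (pinhole approximation; the real optic's blur is out of scope).
#'
#' @param radiance_fn Function `(azimuth_deg, elevation_deg, wavelengths_nm)`
#'   returning a radiance vector.
#' @param description Label for the scene.
#' @return An object of class `scene_model`.
#' @export
scene_model <- function(radiance_fn, description = "scene") {
  stopifnot(is.function(radiance_fn))
  structure(list(radiance = radiance_fn, description = description),
            class = "scene_model")
}

# raw signal above dark implied by linear counts c under the sensor's
# ground-truth nonlinearity (inverse of the linearisation equation)
invert_linearisation <- function(c_linear, a, b) {
  out <- numeric(length(c_linear))
  pos <- c_linear > 0
  out[pos] <- exp((log(c_linear[pos]) - b) / a)
  out
}

#' Simulate one exposure
#'
#' Computes ideal linear counts `c(lambda) = sensitivity * Le * t`, pushes
#' them through the sensor's inverse-linearisation nonlinearity, adds the
#' dark level and noise, clips at saturation and (by default) quantises to
#' integer counts.
#'
#' @param model An [instrument_model()].
#' @param scene A [scene_model()].
#' @param pose A [gimbal_state()].
#' @param integration_time Microseconds, >= 500.
#' @return A [raw_frame()] with the saturated flag set iff any photosite
#'   clipped.
#' @export
expose <- function(model, scene, pose, integration_time) {
  stopifnot(inherits(model, "instrument_model"),
            inherits(scene, "scene_model"),
            inherits(pose, "gimbal_state"))
  if (integration_time < WB_MIN_INTEGRATION) {
    stop("integration_time must be >= ", WB_MIN_INTEGRATION)
  }
  le <- scene$radiance(pose$azimuth_deg, pose$elevation_deg, model$wl)
  le <- rep_len(as.numeric(le), model$n_photosites)
  if (any(le < 0)) stop("scene radiance must be non-negative")
  c_lin <- model$sensitivity * le * integration_time
  signal <- invert_linearisation(c_lin, model$nonlinearity_a,
                                 model$nonlinearity_b)
  mu <- model$dark_offset + model$dark_slope * integration_time + signal
  raw <- mu
  if (model$noise_scale > 0) {
    sd <- model$noise_sd_fn(mu)
    raw <- raw + instrument_rnorm(model, model$n_photosites) * sd
  }
  raw <- pmin(pmax(raw, 0), model$saturation_level)
  if (model$quantise) raw <- round(raw)
  raw_frame(raw, integration_time,
            saturation_level = model$saturation_level)
}

#' Simulate a dark measurement
#'
#' The gimbal rotates the spectrometer down into its housing, so the frame
#' contains only the dark level (affine in integration time) plus noise.
#'
#' @param model An [instrument_model()].
#' @param integration_time Microseconds, >= 500.
#' @return A [dark_frame()].
#' @export
dark_position_expose <- function(model, integration_time) {
  stopifnot(inherits(model, "instrument_model"))
  if (integration_time < WB_MIN_INTEGRATION) {
    stop("integration_time must be >= ", WB_MIN_INTEGRATION)
  }
  mu <- model$dark_offset + model$dark_slope * integration_time
  raw <- mu
  if (model$noise_scale > 0) {
    sd <- model$noise_sd_fn(mu)
    raw <- raw + instrument_rnorm(model, model$n_photosites) * sd
  }
  raw <- pmin(pmax(raw, 0), model$saturation_level)
  if (model$quantise) raw <- round(raw)
  dark_frame(raw, integration_time)
}

# great-circle angular distance in degrees
angular_distance <- function(az1, el1, az2, el2) {
  d2r <- pi / 180
  cosd <- sin(el1 * d2r) * sin(el2 * d2r) +
    cos(el1 * d2r) * cos(el2 * d2r) * cos((az1 - az2) * d2r)
  acos(pmin(pmax(cosd, -1), 1)) / d2r
}

gauss_peak <- function(wl, centre, sigma) exp(-0.5 * ((wl - centre) / sigma)^2)

# normalised Planck-like spectral shape (peak 1 over 250-1000 nm)
planck_shape <- function(wl, temperature) {
  lam <- wl * 1e-9
  h <- 6.62607015e-34; cc <- 2.99792458e8; kb <- 1.380649e-23
  b <- 1 / (lam^5 * (exp(h * cc / (lam * kb * temperature)) - 1))
  grid <- seq(250, 1000, by = 1) * 1e-9
  bmax <- max(1 / (grid^5 * (exp(h * cc / (grid * kb * temperature)) - 1)))
  b / bmax
}

#' Deterministic reference scenes
#'
#' Parametric scenes used as fixtures and ground truth:
#'
#' * `flat` - isotropic, spectrally flat radiance `level` everywhere.
#' * `blackbody-like` - isotropic Planck-shaped spectrum (default 2856 K)
#'   scaled to peak `level`.
#' * `narrowband-set` - point-like sources on a very dim flat background,
#'   each with a single narrow Gaussian emission peak at a distinct
#'   wavelength.
#' * `hdr-night` - a night scene: a dim skyglow-like background plus
#'   point-like lamps with distinct emission spectra (sodium-like, LED-like,
#'   line-spectrum-like). The brightest (non-flare) lamp's spectral peak is
#'   `ratio` (default 70,000, comfortably above the 5e4 contrast the use
#'   case demands) times the background's spectral peak; the constructed
#'   ratio is stored in the `construction_ratio` attribute. With
#'   `include_flare = TRUE` an additional ultra-bright source is placed high
#'   in the scene that saturates the default instrument even at the minimum
#'   500 microsecond exposure (for testing saturation handling; it is not
#'   part of the constructed ratio since its radiance cannot be measured).
#'
#' Sources are hard discs of angular radius `source_radius` degrees, centred
#' on grid-friendly directions (multiples of 11.25 degrees).
#'
#' @param kind Scene kind.
#' @param level Radiance scale for flat / blackbody-like scenes.
#' @param ratio Peak-radiance construction ratio of the hdr-night scene.
#' @param bright_peak Peak radiance of the brightest non-flare lamp.
#' @param include_flare Include the saturating flare source (hdr-night)?
#' @param source_radius Angular radius of point-like sources, degrees.
#' @return A [scene_model()]; hdr-night carries attributes
#'   `construction_ratio`, `sources` and `flare`.
#' @export
make_reference_scene <- function(kind = c("flat", "blackbody-like",
                                          "narrowband-set", "hdr-night"),
                                 level = 1e-3,
                                 ratio = 7e4,
                                 bright_peak = 0.5,
                                 include_flare = TRUE,
                                 source_radius = 3) {
  kind <- match.arg(kind)
  if (kind == "flat") {
    force(level)
    return(scene_model(function(az, el, wl) rep(level, length(wl)),
                       description = "flat"))
  }
  if (kind == "blackbody-like") {
    force(level)
    return(scene_model(function(az, el, wl) level * planck_shape(wl, 2856),
                       description = "blackbody-like"))
  }
  if (kind == "narrowband-set") {
    sources <- data.frame(az = c(56.25, 180, 303.75),
                          el = c(0, 0, 0),
                          centre = c(380, 550, 660),
                          sigma = c(8, 8, 8),
                          peak = c(0.05, 0.05, 0.05))
    bg <- 1e-6
    fn <- function(az, el, wl) {
      out <- rep(bg, length(wl))
      for (i in seq_len(nrow(sources))) {
        if (angular_distance(az, el, sources$az[i], sources$el[i]) <=
            source_radius) {
          out <- out + sources$peak[i] *
            gauss_peak(wl, sources$centre[i], sources$sigma[i])
        }
      }
      out
    }
    sc <- scene_model(fn, description = "narrowband-set")
    attr(sc, "sources") <- sources
    return(sc)
  }
  # hdr-night
  bg_peak <- bright_peak / ratio
  bg_shape <- function(wl) {
    s <- 0.3 + 0.7 * gauss_peak(wl, 590, 120)
    s / max(0.3 + 0.7)  # peak value 1 at 590 nm
  }
  sodium <- function(wl) {
    s <- gauss_peak(wl, 589, 6) + 0.12 * gauss_peak(wl, 569, 30)
    s / max(1 + 0.12 * gauss_peak(589, 569, 30))
  }
  led <- function(wl) {
    s <- 0.9 * gauss_peak(wl, 452, 12) + 0.65 * gauss_peak(wl, 560, 55)
    s / 0.9
  }
  lines <- function(wl) {
    s <- 0.4 * gauss_peak(wl, 405, 5) + 0.7 * gauss_peak(wl, 436, 5) +
      gauss_peak(wl, 546, 5) + 0.8 * gauss_peak(wl, 578, 5) +
      0.15 * gauss_peak(wl, 500, 120)
    s / 1.05
  }
  sources <- list(
    list(az = 90, el = 0, shape = sodium, peak = bright_peak),
    list(az = 180, el = 0, shape = led, peak = 0.36 * bright_peak),
    list(az = 270, el = 0, shape = lines, peak = 0.7 * bright_peak))
  flare <- if (include_flare) {
    list(az = 33.75, el = 22.5,
         shape = function(wl) 0.5 + 0.5 * gauss_peak(wl, 560, 140),
         peak = 80 * bright_peak)
  } else NULL
  fn <- function(az, el, wl) {
    out <- bg_peak * bg_shape(wl)
    for (s in sources) {
      if (angular_distance(az, el, s$az, s$el) <= source_radius) {
        out <- out + s$peak * s$shape(wl)
      }
    }
    if (!is.null(flare) &&
        angular_distance(az, el, flare$az, flare$el) <= source_radius) {
      out <- out + flare$peak * flare$shape(wl)
    }
    out
  }
  sc <- scene_model(fn, description = "hdr-night")
  attr(sc, "construction_ratio") <- (bg_peak + bright_peak) / bg_peak
  attr(sc, "sources") <- sources
  attr(sc, "flare") <- flare
  sc
}

#' Ground-truth calibration record of a simulated instrument
#'
#' Packages the simulator's true wavelength calibration, nonlinearity
#' coefficients and sensitivity curve as a [calibration_record()], for
#' closing radiometric loops against known truth.
#'
#' @param model An [instrument_model()].
#' @return A [calibration_record()].
#' @export
as_calibration_record <- function(model) {
  stopifnot(inherits(model, "instrument_model"))
  calibration_record(
    unit_id = model$unit_id,
    wavelength_cal = model$wavelength_cal,
    lin_a = model$nonlinearity_a,
    lin_b = model$nonlinearity_b,
    sensitivity = sensitivity_curve(model$wl, model$sensitivity,
                                    reference_id = "simulator-ground-truth",
                                    n_pixels = NA_integer_))
}
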