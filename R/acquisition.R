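# Firmware decision logic: per-pixel octave auto-exposure, dark-frame
# scheduling, scan-grid planning with Mercator pole skipping, and
# interpolation of skipped pixels. Operates against any instrument
# implementing the expose()/dark_position_expose() contract.

#' Hard cap on integration time (microseconds)
#' @export
WB_MAX_INTEGRATION_CAP <- 30e6

#' Define a scan plan
#'
#' Start point, stop point and resolution (stepper steps per measurement)
#' for the pan and tilt axes independently; exposure limits; and the dark
#' measurement cadence (dark frames are taken every `dark_interval` panning
#' passes, and always at scan end).
#'
#' @param pan_start,pan_stop,pan_step_size Pan axis, in stepper steps.
#' @param tilt_start,tilt_stop,tilt_step_size Tilt axis, in stepper steps.
#' @param max_integration Per-pixel exposure ceiling in microseconds
#'   (default 2 s, hard cap 30 s).
#' @param min_integration Exposure floor in microseconds (500).
#' @param dark_interval Rows (panning passes) between dark measurements.
#' @param steps_per_revolution Motor steps per revolution.
#' @param gear_ratio Length-2 (pan, tilt) gear ratios.
#' @return An object of class `scan_plan`.
#' @export
scan_plan <- function(pan_start, pan_stop, pan_step_size,
                      tilt_start, tilt_stop, tilt_step_size,
                      max_integration = 2e6,
                      min_integration = WB_MIN_INTEGRATION,
                      dark_interval = 1L,
                      steps_per_revolution = 2048L,
                      gear_ratio = c(1, 1)) {
  gear_ratio <- rep_len(as.numeric(gear_ratio), 2L)
  if (pan_step_size < 1 || tilt_step_size < 1) {
    stop("step sizes must be >= 1")
  }
  if (pan_stop < pan_start || tilt_stop < tilt_start) {
    stop("stop positions must not precede start positions")
  }
  deg_per_pan <- 360 / (steps_per_revolution * gear_ratio[1])
  deg_per_tilt <- 360 / (steps_per_revolution * gear_ratio[2])
  if ((pan_stop - pan_start) * deg_per_pan > 360 + 1e-9) {
    stop("pan span exceeds 360 degrees")
  }
  el <- c(tilt_start, tilt_stop) * deg_per_tilt
  if (min(el) < -20 - 1e-9 || max(el) > 90 + 1e-9) {
    stop("tilt span outside the mechanical range -20..90 degrees")
  }
  if (min_integration < WB_MIN_INTEGRATION) {
    stop("min_integration below the instrument minimum of ",
         WB_MIN_INTEGRATION, " microseconds")
  }
  if (max_integration > WB_MAX_INTEGRATION_CAP) {
    stop("max_integration exceeds the hard cap of ",
         WB_MAX_INTEGRATION_CAP, " microseconds")
  }
  if (min_integration > max_integration) {
    stop("min_integration exceeds max_integration")
  }
  structure(list(pan_start = as.integer(pan_start),
                 pan_stop = as.integer(pan_stop),
                 pan_step_size = as.integer(pan_step_size),
                 tilt_start = as.integer(tilt_start),
                 tilt_stop = as.integer(tilt_stop),
                 tilt_step_size = as.integer(tilt_step_size),
                 max_integration = as.numeric(max_integration),
                 min_integration = as.numeric(min_integration),
                 dark_interval = as.integer(dark_interval),
                 steps_per_revolution = as.integer(steps_per_revolution),
                 gear_ratio = gear_ratio),
            class = "scan_plan")
}

#' Pan positions (stepper steps) of a plan's columns
#' @param plan A [scan_plan()].
#' @return Integer vector of pan steps, one per image column.
#' @export
pan_steps <- function(plan) {
  seq(plan$pan_start, plan$pan_stop, by = plan$pan_step_size)
}

#' Tilt positions (stepper steps) of a plan's rows
#' @param plan A [scan_plan()].
#' @return Integer vector of tilt steps, one per image row.
#' @export
tilt_steps <- function(plan) {
  seq(plan$tilt_start, plan$tilt_stop, by = plan$tilt_step_size)
}

#' Octave integration-time ladder
#'
#' The doubling sequence `min, 2 min, 4 min, ...` of integration times not
#' exceeding `max_integration`. With the default limits (500 microseconds to
#' 30 s) the ratio of the longest permitted to the shortest time is 60,000,
#' the exposure-only dynamic range of a single scan.
#'
#' @param max_integration Ladder ceiling in microseconds.
#' @param min_integration Ladder start in microseconds (default 500).
#' @return Numeric vector of integration times.
#' @export
integration_ladder <- function(max_integration,
                               min_integration = WB_MIN_INTEGRATION) {
  if (max_integration < min_integration) {
    stop("max_integration below min_integration")
  }
  k <- floor(log2(max_integration / min_integration) + 1e-12)
  min_integration * 2^(0:k)
}

#' Per-pixel octave auto-exposure
#'
#' Exposes at integration times starting from the minimum (500 microseconds)
#' and doubling until an exposure saturates in any wavelength or the ceiling
#' is reached, then returns the last non-saturated frame. If even the first
#' (minimum) exposure saturates, that frame is returned with its saturated
#' flag set; if the ladder tops out without saturating, the frame at the
#' largest ladder value not exceeding `max_integration` is returned.
#'
#' @param instrument An [instrument_model()] (or anything honouring the
#'   `expose` contract).
#' @param scene A [scene_model()].
#' @param pose A [gimbal_state()].
#' @param max_integration Per-pixel ceiling in microseconds (<= 30e6).
#' @param min_integration Ladder start (default 500).
#' @return A list with `integration_time` and `frame` (a [raw_frame()]).
#' @export
auto_expose <- function(instrument, scene, pose,
                        max_integration = 2e6,
                        min_integration = WB_MIN_INTEGRATION) {
  if (max_integration < WB_MIN_INTEGRATION ||
      max_integration > WB_MAX_INTEGRATION_CAP) {
    stop("max_integration must be in [", WB_MIN_INTEGRATION, ", ",
         WB_MAX_INTEGRATION_CAP, "]")
  }
  ladder <- integration_ladder(max_integration, min_integration)
  prev <- NULL
  prev_t <- NA_real_
  for (t in ladder) {
    frame <- expose(instrument, scene, pose, t)
    if (frame$saturated) {
      if (is.null(prev)) {
        return(list(integration_time = t, frame = frame))
      }
      return(list(integration_time = prev_t, frame = prev))
    }
    prev <- frame
    prev_t <- t
  }
  list(integration_time = prev_t, frame = prev)
}

#' Pole-skip scan planning
#'
#' A Mercator projection maps pan to image x and tilt to image y, which
#' over-samples azimuth near the poles. For each tilt row at elevation `e`
#' the planner measures only `max(1, round(n_cols * cos(e)))` columns
#' (round-half-up), spread uniformly over the row's column range; the
#' remaining columns are filled by interpolation. At `e = 0` every column is
#' measured.
#'
#' @param plan A [scan_plan()].
#' @return A list, one integer vector of measured column indices per row.
#' @export
plan_rows <- function(plan) {
  n_cols <- length(pan_steps(plan))
  tilts <- tilt_steps(plan)
  deg_per_tilt <- 360 / (plan$steps_per_revolution * plan$gear_ratio[2])
  lapply(tilts, function(ts) {
    e <- ts * deg_per_tilt
    planned_row_columns(n_cols, e)
  })
}

# measured column indices for one row at elevation e (degrees)
planned_row_columns <- function(n_cols, elevation_deg) {
  m <- max(1, round_half_up(n_cols * cos(elevation_deg * pi / 180)))
  m <- min(m, n_cols)
  if (m == n_cols) return(seq_len(n_cols))
  if (m == 1) return(as.integer(round_half_up((1 + n_cols) / 2)))
  unique(as.integer(round_half_up(seq(1, n_cols, length.out = m))))
}

#' Interpolate a sparsely measured row
#'
#' Per-channel linear interpolation in column index between adjacent
#' measured columns; columns outside the measured span copy the nearest
#' measured spectrum. Values should be exposure-comparable (e.g. linearised
#' counts per microsecond), not raw counts, so that pixels measured at
#' different integration times interpolate correctly.
#'
#' @param values Matrix with one row per measured column (columns =
#'   spectral channels), or a vector for a single channel.
#' @param measured_cols Integer column indices of the measured rows,
#'   strictly increasing.
#' @param n_cols Total number of columns in the dense row.
#' @return A dense `n_cols` x channels matrix.
#' @export
interpolate_row <- function(values, measured_cols, n_cols) {
  if (length(measured_cols) < 1L) stop("row has no measured columns")
  if (is.vector(values)) values <- matrix(values, nrow = length(measured_cols))
  if (nrow(values) != length(measured_cols)) {
    stop("values must have one row per measured column")
  }
  if (any(diff(measured_cols) <= 0)) {
    stop("measured_cols must be strictly increasing")
  }
  if (length(measured_cols) == 1L) {
    return(matrix(rep(values[1, ], each = n_cols), nrow = n_cols))
  }
  out <- matrix(NA_real_, nrow = n_cols, ncol = ncol(values))
  xout <- seq_len(n_cols)
  for (j in seq_len(ncol(values))) {
    out[, j] <- stats::approx(measured_cols, values[, j], xout = xout,
                              method = "linear", rule = 2)$y
  }
  out
}

#' Run a whisk-broom scan against a simulated instrument
#'
#' Visits tilt rows in order and the pole-skip-planned measured columns in
#' pan order, auto-exposing each pixel independently. After every
#' `dark_interval` rows (and always at scan end) dark frames are acquired at
#' every integration time used since the previous dark set, so that every
#' integration time present in the cube has at least one matching dark.
#' Skipped (pole-redundant) pixels are filled by per-channel linear
#' interpolation of linearised, exposure-normalised counts and flagged as
#' interpolated. Backlash compensation at the start of each panning pass is
#' recorded as an event log (overshoot by 8 steps, return); the simulated
#' gimbal has no mechanical play, but ports driving real hardware must
#' preserve the behaviour.
#'
#' @param instrument An [instrument_model()].
#' @param scene A [scene_model()].
#' @param plan A [scan_plan()].
#' @param label User label stored in the metadata.
#' @param timestamp ISO-8601 UTC timestamp; defaults to the current time.
#' @return An object of class `scan_cube`: count array
#'   `[rows, cols, photosites]`, per-pixel integration times, flags
#'   (`measured` / `interpolated`), saturation flags, acquisition order, the
#'   dark frame list, the backlash event log and metadata.
#' @export
run_scan <- function(instrument, scene, plan, label = "",
                     timestamp = NULL) {
  stopifnot(inherits(instrument, "instrument_model"),
            inherits(scene, "scene_model"),
            inherits(plan, "scan_plan"))
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  pans <- pan_steps(plan)
  tilts <- tilt_steps(plan)
  n_rows <- length(tilts)
  n_cols <- length(pans)
  n_ph <- instrument$n_photosites
  rows_cols <- plan_rows(plan)

  counts <- array(NA_real_, dim = c(n_rows, n_cols, n_ph))
  itime <- matrix(NA_real_, n_rows, n_cols)
  flag <- matrix(NA_character_, n_rows, n_cols)
  sat <- matrix(FALSE, n_rows, n_cols)
  order_ix <- matrix(NA_integer_, n_rows, n_cols)
  darks <- list()
  events <- data.frame(row = integer(0), type = character(0),
                       steps = integer(0))
  ord <- 0L
  pending_times <- numeric(0)

  take_darks <- function(times) {
    for (t in sort(unique(times))) {
      ord <<- ord + 1L
      df <- dark_position_expose(instrument, t)
      darks[[length(darks) + 1L]] <<-
        list(integration_time = t, counts = df$counts, order = ord)
    }
  }

  for (ri in seq_len(n_rows)) {
    events <- rbind(events,
                    data.frame(row = ri, type = "backlash-overshoot",
                               steps = 8L),
                    data.frame(row = ri, type = "backlash-return",
                               steps = -8L))
    for (ci in rows_cols[[ri]]) {
      pose <- gimbal_state(pans[ci], tilts[ri],
                           steps_per_revolution = plan$steps_per_revolution,
                           gear_ratio = plan$gear_ratio)
      ae <- auto_expose(instrument, scene, pose,
                        max_integration = plan$max_integration,
                        min_integration = plan$min_integration)
      ord <- ord + 1L
      counts[ri, ci, ] <- ae$frame$counts
      itime[ri, ci] <- ae$integration_time
      flag[ri, ci] <- "measured"
      sat[ri, ci] <- ae$frame$saturated
      order_ix[ri, ci] <- ord
      pending_times <- c(pending_times, ae$integration_time)
    }
    if (ri %% plan$dark_interval == 0L || ri == n_rows) {
      take_darks(pending_times)
      pending_times <- numeric(0)
    }
  }
  if (length(pending_times) > 0) take_darks(pending_times)

  cube <- structure(
    list(plan = plan,
         pan_steps = pans, tilt_steps = tilts,
         counts = counts, itime = itime, flag = flag, sat = sat,
         order = order_ix, darks = darks, events = events,
         metadata = list(unit_id = instrument$unit_id, label = label,
                         timestamp = timestamp),
         n_photosites = n_ph,
         saturation_level = instrument$saturation_level,
         window = 1L,
         wl_coefficients = instrument$wavelength_cal$coefficients,
         lin_a = instrument$nonlinearity_a,
         lin_b = instrument$nonlinearity_b),
    class = "scan_cube")

  fill_interpolated(cube)
}

# fill pole-skipped pixels by linear interpolation of linearised
# counts-per-microsecond, synthesising consistent raw frames
fill_interpolated <- function(cube) {
  n_rows <- nrow(cube$itime)
  n_cols <- ncol(cube$itime)
  a <- cube$lin_a
  b <- cube$lin_b
  for (ri in seq_len(n_rows)) {
    mc <- which(cube$flag[ri, ] == "measured")
    missing <- which(is.na(cube$flag[ri, ]))
    if (length(missing) == 0L) next
    if (length(mc) == 0L) stop("row ", ri, " has no measured columns")
    lin_per_us <- t(vapply(mc, function(ci) {
      d <- nearest_dark(cube, cube$itime[ri, ci], cube$order[ri, ci])
      linearise_counts(cube$counts[ri, ci, ], d$counts, a, b) /
        cube$itime[ri, ci]
    }, numeric(cube$n_photosites)))
    dense <- interpolate_row(lin_per_us, mc, n_cols)
    for (ci in missing) {
      near <- mc[which.min(abs(mc - ci))]
      t_star <- cube$itime[ri, near]
      d <- nearest_dark(cube, t_star, cube$order[ri, near])
      signal <- invert_linearisation(dense[ci, ] * t_star, a, b)
      raw <- round(pmin(pmax(d$counts + signal, 0), cube$saturation_level))
      cube$counts[ri, ci, ] <- raw
      cube$itime[ri, ci] <- t_star
      cube$flag[ri, ci] <- "interpolated"
      cube$sat[ri, ci] <- max(raw) >= cube$saturation_level
      cube$order[ri, ci] <- cube$order[ri, near]
    }
  }
  cube
}

# temporally nearest dark frame at a matching integration time
nearest_dark <- function(cube, integration_time, order_index) {
  cand <- Filter(function(d) d$integration_time == integration_time,
                 cube$darks)
  if (length(cand) == 0L) {
    stop("no dark frame at integration time ", integration_time,
         " microseconds")
  }
  dist <- vapply(cand, function(d) abs(d$order - order_index), numeric(1))
  cand[[which.min(dist)]]
}

#' @export
print.scan_cube <- function(x, ...) {
  n_meas <- sum(x$flag == "measured", na.rm = TRUE)
  n_int <- sum(x$flag == "interpolated", na.rm = TRUE)
  cat(sprintf(paste0("<scan_cube: %d x %d pixels (%d measured, %d",
                     " interpolated), %d photosites, %d darks, unit %d>\n"),
              nrow(x$itime), ncol(x$itime), n_meas, n_int,
              x$n_photosites, length(x$darks), x$metadata$unit_id))
  invisible(x)
}

#' Compress a scan cube spectrally
#'
#' Applies boxcar compression ([compress_spectrum()]) to every pixel and
#' dark frame of a cube and records the window in the cube, so downstream
#' radiometry uses the compressed wavelength grid. Compression happens on
#' raw counts, mirroring on-device behaviour.
#'
#' @param cube A `scan_cube`.
#' @param window Positive integer boxcar size.
#' @return The compressed cube.
#' @export
compress_cube <- function(cube, window) {
  stopifnot(inherits(cube, "scan_cube"))
  if (window == 1) return(cube)
  n_rows <- nrow(cube$itime); n_cols <- ncol(cube$itime)
  n_out <- length(compress_spectrum(numeric(cube$n_photosites), window))
  out <- array(NA_real_, dim = c(n_rows, n_cols, n_out))
  for (ri in seq_len(n_rows)) for (ci in seq_len(n_cols)) {
    out[ri, ci, ] <- compress_spectrum(cube$counts[ri, ci, ], window)
  }
  cube$counts <- out
  cube$darks <- lapply(cube$darks, function(d) {
    d$counts <- compress_spectrum(d$counts, window)
    d
  })
  cube$window <- as.integer(window) * cube$window
  cube
}

#' Wavelength grid of a scan cube
#'
#' The unit's wavelength polynomial evaluated over the photosites, boxcar
#' compressed by the cube's compression window.
#'
#' @param cube A `scan_cube`.
#' @return Numeric vector of wavelengths (nm).
#' @export
cube_wavelengths <- function(cube) {
  stopifnot(inherits(cube, "scan_cube"))
  wl <- poly_eval(cube$wl_coefficients,
                  seq_len(cube$n_photosites) - 1)
  compress_spectrum(wl, cube$window)
}
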