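# The two calibration procedures: linearisation-coefficient fitting from an
# integration-time ladder, and spectral-sensitivity estimation from a
# white-standard scan against a reference radiance spectrum. Plus the
# line-oriented calibration_data.txt reader/writer.

#' Default linearisation ladder fractions
#'
#' Sixteen log-spaced fractions of the auto-exposed integration time,
#' spanning 0.005 to 1.5.
#'
#' @return Numeric vector of 16 fractions.
#' @export
default_fractions <- function() {
  exp(seq(log(0.005), log(1.5), length.out = 16))
}

#' Collect a linearisation ladder
#'
#' Auto-exposes once against a stable scene to find the base integration
#' time `T`, then acquires a light frame and a dark frame at each
#' `fraction * T` (rounded to the microsecond and clamped to >= 500). For
#' the most useful ladders the source intensity should put the upper times
#' around 200,000-800,000 microseconds; a warning is recorded if the
#' auto-exposure hits the ladder cap (scene too dim).
#'
#' @param instrument An [instrument_model()].
#' @param scene A stable (time-invariant) [scene_model()].
#' @param pose A [gimbal_state()].
#' @param fractions Fractions of the base time, each in (0, 1.5].
#' @param max_integration Auto-exposure ceiling for the base exposure.
#' @return An object of class `lin_ladder`: `times`, `light` (list of
#'   [raw_frame()]), `dark` (list of [dark_frame()]), `base_time`.
#' @export
collect_linearisation_ladder <- function(instrument, scene, pose,
                                         fractions = default_fractions(),
                                         max_integration = 2e6) {
  if (any(fractions <= 0) || any(fractions > 1.5)) {
    stop("fractions must lie in (0, 1.5]")
  }
  ae <- auto_expose(instrument, scene, pose,
                    max_integration = max_integration)
  base_t <- ae$integration_time
  ladder_top <- max(integration_ladder(max_integration))
  if (base_t >= ladder_top) {
    warning("auto-exposure reached the ladder cap (", base_t,
            " microseconds); the scene may be too dim for a reliable ladder")
  }
  times <- sort(unique(pmax(WB_MIN_INTEGRATION, round(fractions * base_t))))
  light <- lapply(times, function(t) expose(instrument, scene, pose, t))
  dark <- lapply(times, function(t) dark_position_expose(instrument, t))
  structure(list(times = times, light = light, dark = dark,
                 base_time = base_t),
            class = "lin_ladder")
}

#' Fit linearisation coefficients from a ladder
#'
#' Implements the automated linearisation procedure: saturated exposures are
#' removed; each spectral recording is Gaussian-smoothed (`sigma = 3`
#' channels); dark counts are subtracted from light counts; the single
#' wavelength bin with the highest (peak) response is selected; and the
#' linearisation model `c = exp(ln(r - d) * a + b)` is fitted by least
#' squares of `ln(c_expected)` on `ln(r - d)`, where the expected linear
#' counts are proportional to the known integration times. The reported R
#' squared is the coefficient of determination of that log-log regression
#' (observed vs. expected response).
#'
#' Because only the *ratio* of expected counts between exposures is known, b
#' is identified only up to the count scale chosen for `c`: any global gain
#' applied to the counts is absorbed by b. By default the scale is set so
#' that the ladder point nearest the median integration time satisfies
#' `c_expected = (r - d)`, which makes `a = 1, b = 0` the exact no-op for a
#' perfectly linear sensor. Supply `scale` (linear counts per microsecond at
#' the peak bin) to fit b in a specific count unit, e.g. a simulator's
#' ground-truth scale.
#'
#' @param ladder A `lin_ladder` from [collect_linearisation_ladder()].
#' @param scale Optional linear-counts-per-microsecond normalisation.
#' @param sigma Gaussian smoothing sigma in channels (default 3).
#' @return An object of class `linearisation_fit`: `a`, `b`, `r_squared`,
#'   `peak_bin` (1-based), `scale`, and the `ladder` table of
#'   (integration_time, peak light counts, peak dark counts) actually used.
#' @export
fit_linearisation <- function(ladder, scale = NULL, sigma = 3) {
  stopifnot(inherits(ladder, "lin_ladder"))
  usable <- !vapply(ladder$light, function(f) f$saturated, logical(1))
  if (sum(usable) < 4L) {
    stop("fewer than 4 usable (unsaturated) ladder points")
  }
  times <- ladder$times[usable]
  light <- ladder$light[usable]
  dark <- ladder$dark[usable]
  sm_light <- lapply(light, function(f) gaussian_smooth(f$counts, sigma))
  sm_dark <- lapply(dark, function(f) gaussian_smooth(f$counts, sigma))
  diffs <- mapply(function(l, d) l - d, sm_light, sm_dark, SIMPLIFY = FALSE)
  # peak bin from the longest usable exposure's dark-subtracted response
  peak_bin <- which.max(diffs[[length(diffs)]])
  y <- vapply(diffs, function(d) d[peak_bin], numeric(1))
  ok <- y > 0
  if (any(!ok)) {
    warning(sum(!ok), " ladder point(s) with non-positive response at the ",
            "peak bin dropped")
  }
  if (sum(ok) < 4L) stop("fewer than 4 usable ladder points after dropping")
  times <- times[ok]; y <- y[ok]
  if (is.null(scale)) {
    j <- which.min(abs(times - stats::median(times)))
    scale <- y[j] / times[j]
  }
  lx <- log(y)
  ly <- log(scale * times)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  a <- unname(fit$coefficients[2])
  b <- unname(fit$coefficients[1])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  light_peak <- vapply(seq_along(times), function(i) {
    gaussian_smooth(light[ok][[i]]$counts, sigma)[peak_bin]
  }, numeric(1))
  dark_peak <- vapply(seq_along(times), function(i) {
    gaussian_smooth(dark[ok][[i]]$counts, sigma)[peak_bin]
  }, numeric(1))
  structure(list(a = a, b = b, r_squared = r2,
                 peak_bin = as.integer(peak_bin), scale = scale,
                 ladder = data.frame(integration_time = times,
                                     light_peak = light_peak,
                                     dark_peak = dark_peak)),
            class = "linearisation_fit")
}

#' @export
print.linearisation_fit <- function(x, ...) {
  cat(sprintf("<linearisation fit: a = %.6g, b = %.6g, R^2 = %.6f (%d points)>\n",
              x$a, x$b, x$r_squared, nrow(x$ladder)))
  invisible(x)
}

#' Construct a sensitivity curve
#'
#' Per-photosite sensitivity in linear counts per microsecond per radiance
#' unit, on the unit's wavelength grid. `NA` marks photosites where the
#' sensitivity is undefined (reference coverage missing).
#'
#' @param wavelengths Wavelengths in nm, strictly increasing.
#' @param values Sensitivities (>= 0 or NA).
#' @param reference_id Identifier of the reference spectrum used.
#' @param n_pixels Number of standard pixels averaged.
#' @return An object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(wavelengths, values, reference_id = "",
                              n_pixels = NA_integer_) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (any(values < 0, na.rm = TRUE)) stop("sensitivity must be >= 0")
  structure(list(wavelengths = wavelengths, values = values,
                 reference_id = reference_id, n_pixels = n_pixels),
            class = "sensitivity_curve")
}

#' Fit a spectral sensitivity curve from a white-standard scan
#'
#' Averages raw light counts over the pixels that recorded the white
#' standard (which must all share one integration time), averages the dark
#' frames taken before and after the standard at the matching integration
#' time (equal weight), linearises the averaged light minus averaged dark
#' with the supplied coefficients, and divides by the integration time and
#' by the reference radiance interpolated (linearly in wavelength) onto the
#' unit's wavelength grid:
#' `s(lambda) = c(lambda) / (t * Le_ref(lambda))`. Negative results are
#' floored at 0; photosites not covered by the reference are `NA`
#' (undefined).
#'
#' @param cube A `scan_cube` imaging the standard.
#' @param reference A [spectrum()] of kind `radiance`: the calibrated
#'   radiance of the standard under the same illumination.
#' @param linearisation Numeric `c(a, b)` or a `linearisation_fit`.
#' @param pixels Two-column matrix of (row, col) standard-pixel indices;
#'   default all measured, unsaturated pixels.
#' @param reference_id Identifier stored in the curve metadata.
#' @return A [sensitivity_curve()] on the cube's wavelength grid.
#' @export
fit_sensitivity <- function(cube, reference, linearisation,
                            pixels = NULL, reference_id = "reference") {
  stopifnot(inherits(cube, "scan_cube"))
  if (inherits(reference, "wb_spectrum")) {
    if (reference$kind != "radiance") {
      stop("reference must be a radiance spectrum")
    }
  } else stop("reference must be a spectrum object")
  if (inherits(linearisation, "linearisation_fit")) {
    a <- linearisation$a; b <- linearisation$b
  } else {
    a <- linearisation[[1]]; b <- linearisation[[2]]
  }
  if (is.null(pixels)) {
    idx <- which(cube$flag == "measured" & !cube$sat, arr.ind = TRUE)
    pixels <- idx
  }
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L) stop("no standard pixels selected")
  t_used <- unique(cube$itime[pixels])
  if (length(t_used) != 1L) {
    stop("standard pixels span multiple integration times: ",
         paste(sort(t_used), collapse = ", "))
  }
  nchan <- dim(cube$counts)[3]
  avg_light <- colMeans(t(apply(pixels, 1, function(p) {
    cube$counts[p[1], p[2], ]
  })))
  matching <- Filter(function(d) d$integration_time == t_used, cube$darks)
  if (length(matching) == 0L) {
    stop("no dark frame at integration time ", t_used, " microseconds")
  }
  ords <- vapply(matching, `[[`, numeric(1), "order")
  before <- matching[[which.min(ords)]]$counts
  after <- matching[[which.max(ords)]]$counts
  avg_dark <- (before + after) / 2
  c_lin <- linearise_counts(avg_light, avg_dark, a, b)
  wl <- cube_wavelengths(cube)
  le_ref <- stats::approx(reference$wavelengths, reference$values,
                          xout = wl, method = "linear", rule = 1)$y
  s <- c_lin / (t_used * le_ref)
  s[!is.na(s) & s < 0] <- 0
  s[is.na(le_ref) | (!is.na(le_ref) & le_ref <= 0)] <- NA_real_
  sensitivity_curve(wl, s, reference_id = reference_id,
                    n_pixels = nrow(pixels))
}

#' Construct a calibration record
#'
#' The per-unit calibration bundle required before radiance conversion is
#' permitted: wavelength polynomial, linearisation coefficients and spectral
#' sensitivity curve. An optional named light-reducer attenuation profile
#' (scalar or per-photosite) represents the daytime aperture; sensitivity
#' calibration must be repeated (or an attenuation profile applied) whenever
#' a light reducer is fitted.
#'
#' @param unit_id Integer unit identifier.
#' @param wavelength_cal A [wavelength_calibration()].
#' @param lin_a,lin_b Linearisation coefficients.
#' @param sensitivity A [sensitivity_curve()].
#' @param light_reducer Optional list `(name, attenuation)`.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(unit_id, wavelength_cal, lin_a, lin_b,
                               sensitivity, light_reducer = NULL) {
  stopifnot(inherits(wavelength_cal, "wavelength_calibration"),
            inherits(sensitivity, "sensitivity_curve"))
  structure(list(unit_id = as.integer(unit_id),
                 wavelength_cal = wavelength_cal,
                 lin_a = as.numeric(lin_a), lin_b = as.numeric(lin_b),
                 sensitivity = sensitivity,
                 light_reducer = light_reducer),
            class = "calibration_record")
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.9g", v)
  }, character(1))
}

#' Write calibration records to a calibration_data.txt file
#'
#' Line-oriented key=value blocks, one block per unit, so several units can
#' share one file. Keys: `unit`, `wl_coeffs` (comma-separated, lowest order
#' first), `lin_a`, `lin_b`, `sensitivity` (comma-separated per photosite).
#' Blank lines and `#` comments are ignored by the reader.
#'
#' @param records A `calibration_record` or list of them.
#' @param path Output path.
#' @param append Append to an existing file?
#' @return The path, invisibly.
#' @export
write_calibration <- function(records, path, append = FALSE) {
  if (inherits(records, "calibration_record")) records <- list(records)
  lines <- character(0)
  for (rec in records) {
    lines <- c(lines,
               paste0("unit=", rec$unit_id),
               paste0("wl_coeffs=",
                      paste(fmt_num(rec$wavelength_cal$coefficients),
                            collapse = ",")),
               paste0("lin_a=", fmt_num(rec$lin_a)),
               paste0("lin_b=", fmt_num(rec$lin_b)),
               paste0("sensitivity=",
                      paste(fmt_num(rec$sensitivity$values),
                            collapse = ",")),
               "")
  }
  if (append && file.exists(path)) {
    old <- readLines(path, warn = FALSE)
    lines <- c(old, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read calibration records from a calibration_data.txt file
#'
#' @param path File path.
#' @param unit_id If given, return the single matching record (error if
#'   absent); otherwise a list of all records.
#' @param n_photosites Photosite count used to validate the wavelength
#'   polynomial and sensitivity length.
#' @return A `calibration_record` or list of them.
#' @export
read_calibration <- function(path, unit_id = NULL,
                             n_photosites = WB_N_PHOTOSITES) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) {
    stop("malformed calibration line: ", lines[which(bad)[1]])
  }
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  starts <- which(keys == "unit")
  if (length(starts) == 0L) stop("no unit blocks found in ", path)
  ends <- c(starts[-1] - 1L, length(keys))
  records <- lapply(seq_along(starts), function(i) {
    k <- keys[starts[i]:ends[i]]
    v <- vals[starts[i]:ends[i]]
    getv <- function(key) {
      w <- which(k == key)
      if (length(w) == 0L) stop("calibration block missing key '", key, "'")
      v[w[1]]
    }
    sens_vals <- as.numeric(strsplit(getv("sensitivity"), ",")[[1]])
    wl_cal <- wavelength_calibration(
      as.numeric(strsplit(getv("wl_coeffs"), ",")[[1]]),
      n_photosites = length(sens_vals))
    calibration_record(
      unit_id = as.integer(getv("unit")),
      wavelength_cal = wl_cal,
      lin_a = as.numeric(getv("lin_a")),
      lin_b = as.numeric(getv("lin_b")),
      sensitivity = sensitivity_curve(wavelengths(wl_cal), sens_vals))
  })
  if (!is.null(unit_id)) {
    ids <- vapply(records, `[[`, integer(1), "unit_id")
    w <- which(ids == unit_id)
    if (length(w) == 0L) stop("no calibration for unit ", unit_id)
    return(records[[w[1]]])
  }
  records
}

#' Read a reference radiance spectrum from a 2-column CSV
#'
#' Expected columns: `wavelength_nm`, `radiance` (header required).
#'
#' @param path CSV path.
#' @return A [spectrum()] of kind `radiance`.
#' @export
read_reference_radiance <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("reference CSV needs two columns")
  spectrum(df[[1]], df[[2]], kind = "radiance")
}

#' Write/read a linearisation ladder as CSV
#'
#' One row per frame: `integration_time`, `type` (`light` / `dark`), then
#' one column per spectral channel (`c1`, `c2`, ...).
#'
#' @param ladder A `lin_ladder`.
#' @param path CSV path.
#' @return `write_ladder`: the path, invisibly. `read_ladder`: a
#'   `lin_ladder`.
#' @export
write_ladder <- function(ladder, path) {
  stopifnot(inherits(ladder, "lin_ladder"))
  n <- length(ladder$times)
  mat <- rbind(t(vapply(ladder$light, `[[`, ladder$light[[1]]$counts,
                        "counts")),
               t(vapply(ladder$dark, `[[`, ladder$dark[[1]]$counts,
                        "counts")))
  df <- data.frame(integration_time = rep(ladder$times, 2),
                   type = rep(c("light", "dark"), each = n))
  df <- cbind(df, as.data.frame(mat))
  names(df)[-(1:2)] <- paste0("c", seq_len(ncol(mat)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ladder
#' @param saturation_level ADC ceiling used to re-derive saturation flags.
#' @export
read_ladder <- function(path, saturation_level = WB_SATURATION_LEVEL) {
  df <- utils::read.csv(path)
  lights <- df[df$type == "light", , drop = FALSE]
  darks <- df[df$type == "dark", , drop = FALSE]
  o <- order(lights$integration_time)
  lights <- lights[o, , drop = FALSE]
  darks <- darks[order(darks$integration_time), , drop = FALSE]
  times <- lights$integration_time
  if (!identical(as.numeric(times), as.numeric(darks$integration_time))) {
    stop("ladder light and dark integration times do not match")
  }
  ccols <- grep("^c[0-9]+$", names(df))
  structure(list(
    times = as.numeric(times),
    light = lapply(seq_len(nrow(lights)), function(i) {
      raw_frame(as.numeric(lights[i, ccols]), times[i],
                saturation_level = saturation_level)
    }),
    dark = lapply(seq_len(nrow(darks)), function(i) {
      dark_frame(as.numeric(darks[i, ccols]), times[i])
    }),
    base_time = max(times)),
    class = "lin_ladder")
}
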