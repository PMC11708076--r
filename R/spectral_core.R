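# Foundational spectral data types and wavelength / compression / smoothing
# maths shared by the instrument model, acquisition logic, calibration and
# rendering code.

#' Default number of photosites on the detector
#'
#' The detector family this package models has 288 photosites; every
#' operation is nonetheless length-generic.
#' @export
WB_N_PHOTOSITES <- 288L

#' Minimum integration time (microseconds)
#' @export
WB_MIN_INTEGRATION <- 500

#' Default ADC saturation level (counts)
#'
#' The ceiling is configurable everywhere; 65535 (16-bit scale) is only a
#' consistent default for the simulator and the exposure logic.
#' @export
WB_SATURATION_LEVEL <- 65535

#' Construct a raw spectrometer frame
#'
#' One readout of the detector: per-photosite ADC counts together with the
#' integration time that produced them. The `saturated` flag is derived, not
#' supplied: a frame is saturated exactly when any photosite is at or above
#' the saturation level.
#'
#' @param counts Numeric vector of non-negative per-photosite counts.
#' @param integration_time Integration time in microseconds (>= 500).
#' @param saturation_level ADC ceiling in counts.
#' @return An object of class `raw_frame` with fields `counts`,
#'   `integration_time`, `saturation_level` and `saturated`.
#' @export
raw_frame <- function(counts, integration_time,
                      saturation_level = WB_SATURATION_LEVEL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("counts must be non-empty")
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and finite")
  }
  integration_time <- as.numeric(integration_time)
  if (length(integration_time) != 1L || !is.finite(integration_time) ||
      integration_time < WB_MIN_INTEGRATION) {
    stop("integration_time must be a single value >= ",
         WB_MIN_INTEGRATION, " microseconds")
  }
  structure(
    list(counts = counts,
         integration_time = integration_time,
         saturation_level = saturation_level,
         saturated = max(counts) >= saturation_level),
    class = "raw_frame")
}

#' Construct a dark frame
#'
#' A readout taken with the detector shielded from light (the gimbal parks
#' the spectrometer inside its housing). Carries the same per-photosite
#' length contract as [raw_frame()].
#'
#' @param counts Per-photosite dark counts.
#' @param integration_time Integration time in microseconds (>= 500).
#' @return An object of class `dark_frame`.
#' @export
dark_frame <- function(counts, integration_time) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("counts must be non-empty")
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and finite")
  }
  integration_time <- as.numeric(integration_time)
  if (length(integration_time) != 1L || !is.finite(integration_time) ||
      integration_time < WB_MIN_INTEGRATION) {
    stop("integration_time must be a single value >= ",
         WB_MIN_INTEGRATION, " microseconds")
  }
  structure(list(counts = counts, integration_time = integration_time),
            class = "dark_frame")
}

# Horner-scheme polynomial evaluation, coefficients lowest order first.
poly_eval <- function(coefficients, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) {
    out <- out * x + coefficients[[k]]
  }
  out
}

#' Wavelength calibration for a spectrometer unit
#'
#' Each detector ships with per-unit polynomial coefficients mapping the
#' photosite index (0-based, following the manufacturer's convention) to a
#' wavelength in nanometres. Up to degree 5 (6 coefficients) is accepted;
#' shorter vectors are zero-padded. The implied wavelength sequence must be
#' strictly increasing over the photosite range, which is validated here, at
#' load time.
#'
#' @param coefficients Polynomial coefficients, lowest order first (max 6).
#' @param n_photosites Number of photosites the calibration covers.
#' @return An object of class `wavelength_calibration`.
#' @export
wavelength_calibration <- function(coefficients,
                                   n_photosites = WB_N_PHOTOSITES) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || length(coefficients) > 6L) {
    stop("between 1 and 6 polynomial coefficients required")
  }
  if (anyNA(coefficients)) stop("coefficients must be finite")
  coefficients <- c(coefficients, rep(0, 6L - length(coefficients)))
  n_photosites <- as.integer(n_photosites)
  wl <- poly_eval(coefficients, seq_len(n_photosites) - 1)
  if (any(diff(wl) <= 0)) {
    stop("wavelength calibration is not strictly increasing over photosites")
  }
  if (min(wl) < 250 || max(wl) > 1000) {
    warning("wavelength range ", round(min(wl)), "-", round(max(wl)),
            " nm is outside the expected ~320-880 nm envelope")
  }
  structure(list(coefficients = coefficients, n_photosites = n_photosites),
            class = "wavelength_calibration")
}

#' Wavelength of one or more photosites
#'
#' Evaluates the unit's wavelength polynomial at the given 0-based photosite
#' indices.
#'
#' @param index Integer photosite index or vector of indices, 0-based.
#' @param cal A [wavelength_calibration()].
#' @return Wavelengths in nm.
#' @export
wavelength_for_photosite <- function(index, cal) {
  stopifnot(inherits(cal, "wavelength_calibration"))
  index <- as.numeric(index)
  if (any(index < 0) || any(index >= cal$n_photosites)) {
    stop("photosite index out of range 0..", cal$n_photosites - 1L)
  }
  poly_eval(cal$coefficients, index)
}

#' Full wavelength vector of a calibration
#'
#' @param cal A [wavelength_calibration()].
#' @return Numeric vector of length `n_photosites`, strictly increasing.
#' @export
wavelengths <- function(cal) {
  wavelength_for_photosite(seq_len(cal$n_photosites) - 1L, cal)
}

#' Construct a spectrum
#'
#' A wavelength-indexed vector of magnitudes. `kind` records what the values
#' mean; radiance is absolute spectral radiance Le in W sr^-1 m^-2 nm^-1.
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param values Per-wavelength magnitudes (same length).
#' @param kind One of `"raw-linear-counts"`, `"radiance"`,
#'   `"reflectance-percent"`, `"sensitivity"`.
#' @return An object of class `wb_spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("radiance", "raw-linear-counts",
                              "reflectance-percent", "sensitivity")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (kind %in% c("radiance", "sensitivity") &&
      any(values < 0, na.rm = TRUE)) {
    stop(kind, " values must be non-negative")
  }
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "wb_spectrum")
}

#' @export
print.wb_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d channels, %.1f-%.1f nm>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Linearise raw counts
#'
#' Applies the sensor linearisation model \code{c = exp(ln(r - d) * a + b)}
#' per photosite, where \code{r} is the raw count at integration time t and
#' \code{d} the dark count at the same integration time. Photosites where
#' \code{r - d <= 0}
#' (negative noise excursions at low light) map to linear count 0 rather
#' than erroring. With `a = 1, b = 0` this is plain dark subtraction.
#'
#' @param raw A [raw_frame()] or numeric vector of raw counts.
#' @param dark A [dark_frame()] or numeric vector of dark counts.
#' @param a,b Linearisation coefficients.
#' @param allow_time_mismatch If `FALSE` (default) and both arguments are
#'   frames, differing integration times are an error: the model requires
#'   dark counts at the *same* integration time.
#' @return Numeric vector of linear counts.
#' @export
linearise_counts <- function(raw, dark, a, b, allow_time_mismatch = FALSE) {
  if (inherits(raw, "raw_frame") && inherits(dark, "dark_frame") &&
      !allow_time_mismatch &&
      raw$integration_time != dark$integration_time) {
    stop("raw and dark frames have different integration times (",
         raw$integration_time, " vs ", dark$integration_time,
         " microseconds)")
  }
  r <- if (inherits(raw, "raw_frame")) raw$counts else as.numeric(raw)
  d <- if (inherits(dark, "dark_frame")) dark$counts else as.numeric(dark)
  if (length(r) != length(d)) {
    stop("raw and dark frames have mismatched lengths (",
         length(r), " vs ", length(d), ")")
  }
  if (length(a) != 1L || length(b) != 1L || !is.finite(a) || !is.finite(b)) {
    stop("a and b must be single finite values")
  }
  diff <- r - d
  out <- numeric(length(diff))
  pos <- diff > 0
  out[pos] <- exp(log(diff[pos]) * a + b)
  out
}

#' Boxcar spectral compression
#'
#' Averages consecutive non-overlapping windows of `window` neighbouring
#' channels, reducing spectral data volume (window 2 halves the number of
#' channels with minimal loss of effective resolution given the detector's
#' ~9 nm FWHM). A trailing partial window is averaged over its actual
#' members, so the output length is `ceiling(n / window)`; `window = 1` is
#' the identity.
#'
#' @param values Numeric vector (per-photosite data, or wavelengths).
#' @param window Positive integer boxcar size.
#' @return Compressed numeric vector.
#' @export
compress_spectrum <- function(values, window) {
  if (length(window) != 1L || is.na(window) || window < 1 ||
      window != floor(window)) {
    stop("window must be a positive integer")
  }
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(values))
  n <- length(values)
  groups <- (seq_len(n) - 1L) %/% window
  as.numeric(tapply(as.numeric(values), groups, mean))
}

#' Gaussian smoothing over photosite index
#'
#' Discrete Gaussian convolution with the stated standard deviation (in
#' photosite units). The kernel is truncated at 4 sigma and renormalised to
#' sum to one, so constants are conserved exactly. Boundaries are handled by
#' reflection, which preserves the local mean near the spectrum edges.
#' `sigma = 0` is the identity.
#'
#' @param values Numeric vector.
#' @param sigma Gaussian standard deviation in channels, >= 0.
#' @return Smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(values, sigma) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative value")
  }
  values <- as.numeric(values)
  if (sigma == 0) return(values)
  n <- length(values)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  if (r >= n) {
    stop("signal too short (", n, ") for smoothing radius ", r)
  }
  kernel <- stats::dnorm(seq(-r, r), sd = sigma)
  kernel <- kernel / sum(kernel)
  padded <- c(values[r:1], values, values[n:(n - r + 1L)])
  sm <- stats::filter(padded, kernel, sides = 2)
  as.numeric(sm[(r + 1L):(r + n)])
}

# round-half-up, used by the pole-skip planner (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)
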