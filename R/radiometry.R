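# Radiometric back end: converts calibrated scan cubes to absolute spectral
# radiance, relative reflectance, preview images (sRGB, extended-range,
# saturation, NDVI) and quantal cone-catch channels.

#' CIE 1931 2-degree colour-matching functions
#'
#' Analytic multi-lobe Gaussian approximation to the standard observer
#' (piecewise-sigma Gaussian fit; maximum error well below the radiometric
#' tolerances of this package). Used for XYZ integration when rendering.
#'
#' @param wl Wavelengths in nm.
#' @return Matrix with columns `x`, `y`, `z`.
#' @export
cie1931_cmf <- function(wl) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  x <- 1.056 * g(wl, 599.8, 37.9, 31.0) +
    0.362 * g(wl, 442.0, 16.0, 26.7) -
    0.065 * g(wl, 501.1, 20.4, 26.2)
  y <- 0.821 * g(wl, 568.8, 46.9, 40.5) +
    0.286 * g(wl, 530.9, 16.3, 31.1)
  z <- 1.217 * g(wl, 437.0, 11.8, 36.0) +
    0.681 * g(wl, 459.0, 26.0, 13.8)
  cbind(x = pmax(x, 0), y = pmax(y, 0), z = pmax(z, 0))
}

#' Trapezoid integration weights for a wavelength grid
#'
#' Per-sample delta-lambda weights such that `sum(f * w)` is the trapezoid
#' integral of `f` over the (possibly non-uniform) grid.
#'
#' @param wl Strictly increasing wavelengths.
#' @return Numeric weight vector.
#' @export
trapezoid_weights <- function(wl) {
  n <- length(wl)
  if (n < 2L) stop("need at least two wavelengths")
  w <- numeric(n)
  w[1] <- (wl[2] - wl[1]) / 2
  w[n] <- (wl[n] - wl[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (wl[3:n] - wl[1:(n - 2)]) / 2
  w
}

#' Convert a scan cube to absolute spectral radiance
#'
#' Per pixel: `Le(lambda) = linearise(raw, matched dark, a, b) /
#' (t * s(lambda))` in W sr^-1 m^-2 nm^-1, using the temporally nearest dark
#' frame at the pixel's integration time and the unit's sensitivity curve.
#' Photosites with undefined (NA) or non-positive sensitivity are masked
#' (`NA`). Saturated and interpolated flags are carried through.
#'
#' @param cube A `scan_cube`.
#' @param cal A complete [calibration_record()].
#' @return An object of class `radiance_cube`: `wavelengths`, the `le` array
#'   `[rows, cols, channels]`, and `sat` / `interp` flag matrices.
#' @export
cube_to_radiance <- function(cube, cal) {
  stopifnot(inherits(cube, "scan_cube"),
            inherits(cal, "calibration_record"))
  wl <- cube_wavelengths(cube)
  s <- cal$sensitivity$values
  if (length(s) == cube$n_photosites && cube$window > 1L) {
    s <- compress_spectrum(s, cube$window)
  }
  if (length(s) != length(wl)) {
    stop("sensitivity curve length (", length(s),
         ") does not match the cube's spectral channels (", length(wl), ")")
  }
  if (!is.null(cal$light_reducer)) {
    att <- rep_len(as.numeric(cal$light_reducer$attenuation), length(s))
    s <- s * att
  }
  mask <- is.na(s) | s <= 0
  n_rows <- nrow(cube$itime); n_cols <- ncol(cube$itime)
  le <- array(NA_real_, dim = c(n_rows, n_cols, length(wl)))
  for (ri in seq_len(n_rows)) for (ci in seq_len(n_cols)) {
    t_px <- cube$itime[ri, ci]
    if (is.na(t_px)) next
    d <- nearest_dark(cube, t_px, cube$order[ri, ci])
    c_lin <- linearise_counts(cube$counts[ri, ci, ], d$counts,
                              cal$lin_a, cal$lin_b)
    v <- c_lin / (t_px * s)
    v[mask] <- NA_real_
    le[ri, ci, ] <- v
  }
  structure(list(wavelengths = wl, le = le,
                 sat = cube$sat,
                 interp = cube$flag == "interpolated",
                 measured = cube$flag == "measured",
                 metadata = cube$metadata),
            class = "radiance_cube")
}

#' Extract one pixel's radiance spectrum
#'
#' @param rcube A `radiance_cube`.
#' @param row,col Pixel indices (1-based).
#' @return A [spectrum()] of kind `radiance` (small negative noise
#'   excursions clipped to 0 for the spectrum container; use
#'   `rcube$le[row, col, ]` for the raw values).
#' @export
radiance_at <- function(rcube, row, col) {
  stopifnot(inherits(rcube, "radiance_cube"))
  v <- rcube$le[row, col, ]
  spectrum(rcube$wavelengths, pmax(v, 0), kind = "radiance")
}

#' Convert a radiance cube to relative reflectance
#'
#' `R(lambda) = 100 * standard_reflectance * Le_pixel / Le_standard`, i.e.
#' percent relative to a chosen in-scene grey/white standard pixel. The
#' default `standard_reflectance = 1` gives purely relative reflectance;
#' supply the standard's known reflectance (e.g. 0.99 for a Spectralon
#' standard) for absolute scaling. Channels where the standard's radiance is
#' ~0 are masked.
#'
#' @param rcube A `radiance_cube`.
#' @param standard_pixel `c(row, col)` of the standard pixel, which must be
#'   measured (not interpolated) and unsaturated.
#' @param standard_reflectance Known reflectance of the standard (fraction).
#' @return An object of class `reflectance_cube` with a `values` array in
#'   percent.
#' @export
to_reflectance <- function(rcube, standard_pixel, standard_reflectance = 1) {
  stopifnot(inherits(rcube, "radiance_cube"))
  r <- standard_pixel[1]; c <- standard_pixel[2]
  if (isTRUE(rcube$sat[r, c])) {
    stop("standard pixel (", r, ", ", c, ") is saturated")
  }
  if (!isTRUE(rcube$measured[r, c])) {
    stop("standard pixel (", r, ", ", c, ") is not a measured pixel")
  }
  le_std <- rcube$le[r, c, ]
  thr <- 1e-6 * max(le_std, na.rm = TRUE)
  guard <- is.na(le_std) | le_std <= thr
  dims <- dim(rcube$le)
  vals <- array(NA_real_, dims)
  for (ri in seq_len(dims[1])) for (ci in seq_len(dims[2])) {
    v <- 100 * standard_reflectance * rcube$le[ri, ci, ] / le_std
    v[guard] <- NA_real_
    vals[ri, ci, ] <- v
  }
  structure(list(wavelengths = rcube$wavelengths, values = vals,
                 sat = rcube$sat, interp = rcube$interp,
                 standard_pixel = c(r, c),
                 standard_reflectance = standard_reflectance),
            class = "reflectance_cube")
}

# pixels x channels matrix of non-negative radiance (NA -> 0)
flatten_le <- function(rcube) {
  dims <- dim(rcube$le)
  m <- matrix(rcube$le, nrow = dims[1] * dims[2], ncol = dims[3])
  m[is.na(m)] <- 0
  pmax(m, 0)
}

srgb_matrix <- function() {
  matrix(c(3.2406, -1.5372, -0.4986,
           -0.9689, 1.8758, 0.0415,
           0.0557, -0.2040, 1.0570),
         nrow = 3, byrow = TRUE)
}

srgb_transfer <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Render an sRGB preview of a radiance cube
#'
#' Integrates Le against the CIE 1931 2-degree colour-matching functions on
#' the cube's wavelength grid (trapezoid weights), applies the standard
#' XYZ -> linear sRGB matrix balanced to an equal-energy white (each matrix
#' row normalised to unit sum, so spectrally flat radiance renders neutral
#' grey), scales so the cube's 99.5th-percentile luminance maps to white
#' (keeping single bright sources from crushing night scenes), applies the
#' sRGB transfer curve and clips.
#'
#' @param rcube A `radiance_cube`.
#' @param percentile Display normalisation quantile of luminance.
#' @return Integer array `[rows, cols, 3]` with values in 0..255.
#' @export
render_srgb <- function(rcube, percentile = 0.995) {
  stopifnot(inherits(rcube, "radiance_cube"))
  wl <- rcube$wavelengths
  cmf <- cie1931_cmf(wl) * trapezoid_weights(wl)
  m <- flatten_le(rcube)
  xyz <- m %*% cmf
  mn <- srgb_matrix() / rowSums(srgb_matrix())
  lin <- xyz %*% t(mn)
  anchor <- stats::quantile(xyz[, 2], percentile, na.rm = TRUE, names = FALSE)
  if (!is.finite(anchor) || anchor <= 0) {
    lin[] <- 0
  } else {
    lin <- lin / anchor
  }
  v <- srgb_transfer(pmin(pmax(lin, 0), 1))
  dims <- dim(rcube$le)
  out <- array(0L, dim = c(dims[1], dims[2], 3L))
  for (k in 1:3) out[, , k] <- as.integer(round(255 * v[, k]))
  out
}

# band-integrated radiance per pixel
band_integral <- function(rcube, band) {
  wl <- rcube$wavelengths
  w <- trapezoid_weights(wl) * (wl >= band[1] & wl <= band[2])
  m <- flatten_le(rcube)
  as.numeric(m %*% w)
}

#' Render an extended-spectral-range preview
#'
#' Reassigns the display channels to out-of-gamut bands: R = band-integrated
#' radiance over the near-infrared band, G = the CIE Y integral, B =
#' band-integrated radiance over the ultraviolet band. Each channel is
#' normalised by its own 99.5th-percentile value (the bands' absolute scales
#' are incommensurate) and passed through the sRGB transfer curve.
#'
#' @param rcube A `radiance_cube`.
#' @param uv,nir Band edges in nm.
#' @param percentile Display normalisation quantile, per channel.
#' @return Integer array `[rows, cols, 3]`, 0..255.
#' @export
render_extended <- function(rcube, uv = c(320, 400), nir = c(750, 850),
                            percentile = 0.995) {
  stopifnot(inherits(rcube, "radiance_cube"))
  wl <- rcube$wavelengths
  ybar <- cie1931_cmf(wl)[, "y"] * trapezoid_weights(wl)
  chans <- cbind(band_integral(rcube, nir),
                 as.numeric(flatten_le(rcube) %*% ybar),
                 band_integral(rcube, uv))
  dims <- dim(rcube$le)
  out <- array(0L, dim = c(dims[1], dims[2], 3L))
  for (k in 1:3) {
    anchor <- stats::quantile(chans[, k], percentile, na.rm = TRUE,
                              names = FALSE)
    v <- if (!is.finite(anchor) || anchor <= 0) {
      rep(0, nrow(chans))
    } else {
      srgb_transfer(pmin(pmax(chans[, k] / anchor, 0), 1))
    }
    out[, , k] <- as.integer(round(255 * v))
  }
  out
}

#' Saturation mask
#'
#' TRUE exactly where the stored frame's saturated flag is set (pixels that
#' clipped even at the minimum integration time).
#'
#' @param cube A `scan_cube` or `radiance_cube`.
#' @return Logical matrix.
#' @export
render_saturation_mask <- function(cube) {
  stopifnot(inherits(cube, "scan_cube") || inherits(cube, "radiance_cube"))
  cube$sat
}

#' Render a normalized difference vegetation index image
#'
#' `NDVI = (NIR - Red) / (NIR + Red)` per pixel from band-integrated
#' radiance; 0/0 maps to 0. Always in `[-1, 1]`.
#'
#' @param rcube A `radiance_cube`.
#' @param red,nir Band edges in nm.
#' @return Numeric matrix in `[-1, 1]`.
#' @export
render_ndvi <- function(rcube, red = c(620, 700), nir = c(750, 850)) {
  stopifnot(inherits(rcube, "radiance_cube"))
  r <- band_integral(rcube, red)
  n <- band_integral(rcube, nir)
  denom <- n + r
  v <- ifelse(denom > 0, (n - r) / denom, 0)
  dims <- dim(rcube$le)
  matrix(v, dims[1], dims[2])
}

#' Read a receptor sensitivity table (sensitivity_data.csv format)
#'
#' First column `wavelength_nm`, subsequent named receptor sensitivity
#' columns.
#'
#' @param path CSV path.
#' @return An object of class `receptor_set`: `wavelengths` and a named
#'   `values` matrix.
#' @export
read_receptors <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("receptor CSV needs a wavelength column and at ",
                          "least one receptor column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("receptor sensitivities must be >= 0")
  structure(list(wavelengths = as.numeric(df[[1]]), values = vals),
            class = "receptor_set")
}

#' Construct a receptor set from vectors
#'
#' @param wavelengths Wavelengths in nm.
#' @param ... Named numeric vectors of receptor sensitivities.
#' @return A `receptor_set`.
#' @export
receptor_set <- function(wavelengths, ...) {
  vals <- cbind(...)
  if (is.null(colnames(vals))) stop("receptors must be named")
  if (any(vals < 0, na.rm = TRUE)) stop("receptor sensitivities must be >= 0")
  structure(list(wavelengths = as.numeric(wavelengths), values = vals),
            class = "receptor_set")
}

#' Quantal cone-catch images
#'
#' For each receptor i, per pixel:
#' `Q_i = sum_lambda Le(lambda) * lambda * S_i(lambda) * dlambda`
#' (trapezoid weights on the cube's grid). The `lambda` factor converts
#' energy units to relative quantal units; constant factors (h, c) are
#' dropped since only relative catches are output. Receptors are resampled
#' onto the cube grid by linear interpolation and are zero outside their
#' tabulated support.
#'
#' @param rcube A `radiance_cube`.
#' @param receptors A `receptor_set`.
#' @return Named list of numeric matrices, one per receptor.
#' @export
cone_catch <- function(rcube, receptors) {
  stopifnot(inherits(rcube, "radiance_cube"),
            inherits(receptors, "receptor_set"))
  wl <- rcube$wavelengths
  w <- trapezoid_weights(wl)
  m <- flatten_le(rcube)
  dims <- dim(rcube$le)
  out <- list()
  for (name in colnames(receptors$values)) {
    s <- stats::approx(receptors$wavelengths, receptors$values[, name],
                       xout = wl, method = "linear", rule = 1)$y
    s[is.na(s)] <- 0
    if (all(s == 0)) {
      stop("receptor '", name,
           "' has no wavelength overlap with the cube grid")
    }
    q <- as.numeric(m %*% (wl * s * w))
    out[[name]] <- matrix(q, dims[1], dims[2])
  }
  out
}

#' Scene peak-to-peak dynamic ratio
#'
#' Ratio of the highest per-pixel spectral peak to the lowest per-pixel
#' spectral peak over the measured, unsaturated pixels of a radiance cube
#' (interpolated pixels carry no independent information and saturated
#' pixels carry no valid radiance, so both are excluded). A non-positive
#' minimum is reported as infinite with a warning.
#'
#' @param rcube A `radiance_cube`.
#' @return The ratio (possibly `Inf`).
#' @export
scene_peak_ratio <- function(rcube) {
  stopifnot(inherits(rcube, "radiance_cube"))
  eligible <- which(rcube$measured & !rcube$sat)
  if (length(eligible) < 2L) stop("need at least 2 measured pixels")
  dims <- dim(rcube$le)
  m <- matrix(rcube$le, nrow = dims[1] * dims[2], ncol = dims[3])
  peaks <- apply(m[eligible, , drop = FALSE], 1, max, na.rm = TRUE)
  lo <- min(peaks)
  if (lo <= 0) {
    warning("lowest spectral peak is <= 0; ratio reported as infinite")
    return(Inf)
  }
  max(peaks) / lo
}

#' Export a spectrum to a 2-column CSV
#'
#' Writes `wavelength_nm,value` rows preceded by a comment naming the kind
#' (radiance or reflectance), mirroring the GUI's spectrum export.
#'
#' @param spec A [spectrum()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "wb_spectrum"))
  lines <- c(paste0("# kind: ", spec$kind),
             "wavelength_nm,value",
             sprintf("%.9g,%.9g", spec$wavelengths, spec$values))
  writeLines(lines, path)
  invisible(path)
}
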