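# Plain-text scan file format (version 1) and its lossless reader/writer.
# Layout: a "wbscan <version>" magic line, key: value header lines up to
# "end_header", then one record per dark frame (D ...) and one per pixel
# (P ...). Counts are integers; derived floats use 9 significant digits.

SCAN_FORMAT_VERSION <- 1L

scan_header_keys <- c(
  "unit_id", "label", "timestamp",
  "pan_start", "pan_stop", "pan_step_size",
  "tilt_start", "tilt_stop", "tilt_step_size",
  "max_integration", "min_integration", "dark_interval",
  "steps_per_revolution", "gear_ratio_pan", "gear_ratio_tilt",
  "n_rows", "n_cols", "n_channels", "n_photosites",
  "compression_window", "saturation_level",
  "wl_coeffs", "lin_a", "lin_b")

#' Build a scan file header from a cube
#'
#' Collects the format version, unit id, label, timestamp, plan parameters,
#' compression window and the calibration snapshot (wavelength coefficients
#' and linearisation coefficients) that accompany the raw data in a scan
#' file.
#'
#' @param cube A `scan_cube`.
#' @return An object of class `scan_file_header` (a named list).
#' @export
scan_header <- function(cube) {
  stopifnot(inherits(cube, "scan_cube"))
  plan <- cube$plan
  structure(list(
    version = SCAN_FORMAT_VERSION,
    unit_id = cube$metadata$unit_id,
    label = cube$metadata$label,
    timestamp = cube$metadata$timestamp,
    pan_start = plan$pan_start, pan_stop = plan$pan_stop,
    pan_step_size = plan$pan_step_size,
    tilt_start = plan$tilt_start, tilt_stop = plan$tilt_stop,
    tilt_step_size = plan$tilt_step_size,
    max_integration = plan$max_integration,
    min_integration = plan$min_integration,
    dark_interval = plan$dark_interval,
    steps_per_revolution = plan$steps_per_revolution,
    gear_ratio_pan = plan$gear_ratio[1],
    gear_ratio_tilt = plan$gear_ratio[2],
    n_rows = nrow(cube$itime), n_cols = ncol(cube$itime),
    n_channels = dim(cube$counts)[3],
    n_photosites = cube$n_photosites,
    compression_window = cube$window,
    saturation_level = cube$saturation_level,
    wl_coeffs = cube$wl_coefficients,
    lin_a = cube$lin_a, lin_b = cube$lin_b),
    class = "scan_file_header")
}

fmt_counts <- function(x) paste(sprintf("%.10g", x), collapse = " ")

#' Write a scan cube to a text scan file
#'
#' Lossless, deterministic serialisation: header block, then one `D` record
#' per dark frame (acquisition order, integration time, counts) in
#' acquisition order, then one `P` record per pixel (row, col, flag
#' M/I, saturated 0/1, acquisition order, integration time, counts) in
#' row-major order.
#'
#' @param cube A `scan_cube`.
#' @param path Output path.
#' @param header Optional [scan_header()]; derived from the cube by default.
#' @return The path, invisibly.
#' @export
write_scan <- function(cube, path, header = NULL) {
  stopifnot(inherits(cube, "scan_cube"))
  if (is.null(header)) header <- scan_header(cube)
  stopifnot(inherits(header, "scan_file_header"))
  lines <- c(paste("wbscan", header$version))
  for (key in scan_header_keys) {
    val <- header[[key]]
    val_str <- if (key %in% c("label", "timestamp")) {
      as.character(val)
    } else if (key == "wl_coeffs") {
      paste(sprintf("%.9g", val), collapse = ",")
    } else if (key %in% c("lin_a", "lin_b", "max_integration",
                          "min_integration", "gear_ratio_pan",
                          "gear_ratio_tilt", "saturation_level")) {
      sprintf("%.9g", val)
    } else {
      sprintf("%d", as.integer(val))
    }
    lines <- c(lines, paste0(key, ": ", val_str))
  }
  lines <- c(lines, "end_header")
  for (d in cube$darks) {
    lines <- c(lines, paste("D", d$order, sprintf("%.10g", d$integration_time),
                            fmt_counts(d$counts)))
  }
  n_rows <- nrow(cube$itime); n_cols <- ncol(cube$itime)
  pix <- character(n_rows * n_cols)
  k <- 0L
  for (ri in seq_len(n_rows)) for (ci in seq_len(n_cols)) {
    k <- k + 1L
    fl <- if (identical(cube$flag[ri, ci], "interpolated")) "I" else "M"
    pix[k] <- paste("P", ri, ci, fl, as.integer(cube$sat[ri, ci]),
                    cube$order[ri, ci],
                    sprintf("%.10g", cube$itime[ri, ci]),
                    fmt_counts(cube$counts[ri, ci, ]))
  }
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(c(lines, pix), con, sep = "\n")
  invisible(path)
}

#' Read a scan file
#'
#' Inverse of [write_scan()]. Unknown header keys are ignored with a
#' warning (forward compatibility); a version other than 1 or a truncated
#' pixel grid is an error.
#'
#' @param path Scan file path.
#' @return A list with elements `cube` (a `scan_cube`) and `header` (a
#'   `scan_file_header`).
#' @export
read_scan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("scan file ", path, " is empty")
  magic <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(magic) != 2L || magic[1] != "wbscan") {
    stop("not a wbscan file: ", path)
  }
  version <- suppressWarnings(as.integer(magic[2]))
  if (is.na(version) || version != SCAN_FORMAT_VERSION) {
    stop("unsupported scan file version '", magic[2], "' (expected ",
         SCAN_FORMAT_VERSION, ")")
  }
  hdr_end <- which(lines == "end_header")[1]
  if (is.na(hdr_end)) stop("scan file has no end_header line")
  hdr <- list(version = version)
  for (ln in lines[2:(hdr_end - 1L)]) {
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) stop("malformed header line: ", ln)
    key <- substr(ln, 1L, colon - 1L)
    val <- sub("^ ", "", substr(ln, colon + 1L, nchar(ln)))
    if (!key %in% scan_header_keys) {
      warning("ignoring unknown scan header key '", key, "'")
      next
    }
    hdr[[key]] <- if (key %in% c("label", "timestamp")) {
      val
    } else if (key == "wl_coeffs") {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else {
      as.numeric(val)
    }
  }
  missing_keys <- setdiff(scan_header_keys, c(names(hdr), "label"))
  if (length(missing_keys) > 0L) {
    stop("scan header missing key(s): ", paste(missing_keys, collapse = ", "))
  }
  if (is.null(hdr$label)) hdr$label <- ""
  class(hdr) <- "scan_file_header"

  n_rows <- as.integer(hdr$n_rows)
  n_cols <- as.integer(hdr$n_cols)
  n_chan <- as.integer(hdr$n_channels)
  plan <- scan_plan(hdr$pan_start, hdr$pan_stop, hdr$pan_step_size,
                    hdr$tilt_start, hdr$tilt_stop, hdr$tilt_step_size,
                    max_integration = hdr$max_integration,
                    min_integration = hdr$min_integration,
                    dark_interval = hdr$dark_interval,
                    steps_per_revolution = hdr$steps_per_revolution,
                    gear_ratio = c(hdr$gear_ratio_pan, hdr$gear_ratio_tilt))

  counts <- array(NA_real_, dim = c(n_rows, n_cols, n_chan))
  itime <- matrix(NA_real_, n_rows, n_cols)
  flag <- matrix(NA_character_, n_rows, n_cols)
  sat <- matrix(FALSE, n_rows, n_cols)
  order_ix <- matrix(NA_integer_, n_rows, n_cols)
  darks <- list()
  warned_extra <- FALSE
  for (ln in lines[(hdr_end + 1L):length(lines)]) {
    if (!nzchar(ln)) next
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (parts[1] == "D") {
      if (length(parts) < 3L + n_chan) stop("truncated dark record: ", ln)
      if (length(parts) > 3L + n_chan && !warned_extra) {
        warning("ignoring unknown trailing fields in scan records")
        warned_extra <- TRUE
      }
      darks[[length(darks) + 1L]] <- list(
        integration_time = as.numeric(parts[3]),
        counts = as.numeric(parts[4:(3L + n_chan)]),
        order = as.integer(parts[2]))
    } else if (parts[1] == "P") {
      if (length(parts) < 7L + n_chan) stop("truncated pixel record: ", ln)
      if (length(parts) > 7L + n_chan && !warned_extra) {
        warning("ignoring unknown trailing fields in scan records")
        warned_extra <- TRUE
      }
      ri <- as.integer(parts[2]); ci <- as.integer(parts[3])
      if (is.na(ri) || is.na(ci) || ri < 1L || ri > n_rows ||
          ci < 1L || ci > n_cols) {
        stop("pixel record out of grid range: ", ln)
      }
      flag[ri, ci] <- if (parts[4] == "I") "interpolated" else "measured"
      sat[ri, ci] <- parts[5] == "1"
      order_ix[ri, ci] <- as.integer(parts[6])
      itime[ri, ci] <- as.numeric(parts[7])
      counts[ri, ci, ] <- as.numeric(parts[8:(7L + n_chan)])
    } else {
      stop("unrecognised record type '", parts[1], "' in ", path)
    }
  }
  missing_px <- which(is.na(itime), arr.ind = TRUE)
  if (nrow(missing_px) > 0L) {
    stop("scan file is missing pixel(s): ",
         paste(sprintf("(%d,%d)", missing_px[, 1], missing_px[, 2]),
               collapse = ", "))
  }
  cube <- structure(
    list(plan = plan,
         pan_steps = pan_steps(plan), tilt_steps = tilt_steps(plan),
         counts = counts, itime = itime, flag = flag, sat = sat,
         order = order_ix, darks = darks,
         events = data.frame(row = integer(0), type = character(0),
                             steps = integer(0)),
         metadata = list(unit_id = as.integer(hdr$unit_id),
                         label = hdr$label, timestamp = hdr$timestamp),
         n_photosites = as.integer(hdr$n_photosites),
         saturation_level = hdr$saturation_level,
         window = as.integer(hdr$compression_window),
         wl_coefficients = hdr$wl_coeffs,
         lin_a = hdr$lin_a, lin_b = hdr$lin_b),
    class = "scan_cube")
  list(cube = cube, header = hdr)
}
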