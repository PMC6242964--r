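#' Calibrated fluorescence movie
#'
#' A 3-D intensity stack with physical calibration. Data are stored as an
#' array with dimensions `(rows, cols, frames)`; pixel values are finite and
#' nonnegative.
#'
#' @param data numeric array `(rows, cols, frames)`, or a matrix for a
#'   single-frame movie.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @param channel free-text channel label (e.g. `"BDNF-pHluorin"`,
#'   `"FM4-64"`).
#' @return An object of class `dcv_movie`.
#' @export
dcv_movie <- function(data, pixel_size, frame_interval, channel = "") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a (rows, cols, frames) array")
  if (dim(data)[3] < 1L) stop("movie must have >= 1 frame")
  if (any(!is.finite(data))) stop("movie intensities must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel = as.character(channel)),
            class = "dcv_movie")
}

#' @export
print.dcv_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dcv_movie '%s': %d x %d px, %d frames (%.3g um/px, %.3g s/frame)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Pixel-wise time average of a movie
#'
#' @param movie a [dcv_movie()].
#' @return Numeric matrix `(rows, cols)`.
#' @export
time_average <- function(movie) {
  stopifnot(inherits(movie, "dcv_movie"))
  rowMeans(movie$data, dims = 2L)
}

#' Write a movie as a multi-page 16-bit TIFF with a JSON calibration sidecar
#'
#' Intensities are scaled into the 16-bit range by `scale` (counts per
#' intensity unit) and clipped; the scale and calibration are recorded in
#' `<path>.json` so [read_movie_tiff()] can restore physical units.
#'
#' @param movie a [dcv_movie()].
#' @param path output TIFF path.
#' @param scale counts per intensity unit (default chosen so the movie
#'   maximum maps to ~90% of the 16-bit range).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "dcv_movie"))
  mx <- max(movie$data)
  if (is.null(scale)) scale <- if (mx > 0) 0.9 * 65535 / mx else 1
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(pmax(movie$data[, , f] * scale, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size,
         frame_interval_s = movie$frame_interval,
         channel = movie$channel, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; calibration is taken from `<path>.json` when
#'   present, else from the arguments.
#' @param pixel_size,frame_interval,channel fallback calibration when no
#'   sidecar exists.
#' @return A [dcv_movie()].
#' @export
read_movie_tiff <- function(path, pixel_size = 1, frame_interval = 1,
                            channel = "") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1 / 65535
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size <- meta$pixel_size_um
    frame_interval <- meta$frame_interval_s
    channel <- meta$channel
    scale <- 1 / meta$intensity_scale
  }
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535 * scale
  dcv_movie(arr, pixel_size, frame_interval, channel)
}

#' Per-ROI intensity trace
#'
#' A per-frame intensity time series attached to a protocol schedule. Raw
#' traces hold mean ROI intensities; normalized traces hold delta-F/F0
#' values with `f0` recording the baseline mean that was divided out.
#'
#' @param values numeric per-frame intensities.
#' @param schedule a [protocol_schedule()] the trace covers.
#' @param roi_id identifier of the source ROI.
#' @param normalized logical; `TRUE` for delta-F/F0 traces.
#' @param f0 baseline mean intensity (set by [normalize_trace()]).
#' @return An object of class `dcv_trace`.
#' @export
dcv_trace <- function(values, schedule, roi_id = NA_integer_,
                      normalized = FALSE, f0 = NA_real_) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  values <- as.numeric(values)
  if (length(values) < n_frames(schedule))
    stop("trace length (", length(values),
         ") does not cover the schedule (", n_frames(schedule), " frames)")
  if (any(!is.finite(values))) stop("trace values must be finite")
  structure(list(values = values, schedule = schedule, roi_id = roi_id,
                 normalized = isTRUE(normalized), f0 = f0),
            class = "dcv_trace")
}

#' @export
print.dcv_trace <- function(x, ...) {
  cat(sprintf("dcv_trace roi=%s, %d frames @ %.3g s, %s\n",
              as.character(x$roi_id), length(x$values),
              x$schedule$frame_interval,
              if (x$normalized) sprintf("delta-F/F0 (f0 = %.4g)", x$f0)
              else "raw intensity"))
  invisible(x)
}

#' Frame times of a trace
#'
#' @param trace a [dcv_trace()].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "dcv_trace"))
  (seq_along(trace$values) - 1) * trace$schedule$frame_interval
}

#' Write traces to CSV
#'
#' One row per (roi, frame) with columns `frame`, `time_s`, `value`,
#' `roi_id`, `label` (the ground-truth or assigned label, `NA` if none).
#'
#' @param traces a list of [dcv_trace()] objects.
#' @param path output CSV path.
#' @param labels optional character vector, one label per trace.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, labels = NULL) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(frame = seq_along(tr$values), time_s = trace_times(tr),
               value = tr$values,
               roi_id = if (is.na(tr$roi_id)) i else tr$roi_id,
               label = if (is.null(labels)) NA_character_ else labels[[i]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
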