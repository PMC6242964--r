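#' Candidate synaptic punctum
#'
#' A circular ROI around a local intensity maximum in the synapse-label
#' channel, with its local-background statistics and synaptic call. The
#' call follows the 2-sigma rule: the ROI is synaptic if its mean signal
#' exceeds the local-background mean by more than two standard deviations
#' of the background pixel values, background statistics being pooled over
#' two equally sized ROIs placed adjacent to the punctum.
#'
#' @param row,col 1-based pixel centre.
#' @param radius ROI radius in pixels (> 0).
#' @param signal_mean mean intensity inside the ROI.
#' @param background_mean,background_sigma local-background statistics
#'   (`NA` until [call_synaptic()] runs).
#' @param is_synaptic logical call (`NA` until called, or when background
#'   ROIs cannot be placed).
#' @return An object of class `punctum`.
#' @export
punctum <- function(row, col, radius = 3, signal_mean = NA_real_,
                    background_mean = NA_real_,
                    background_sigma = NA_real_, is_synaptic = NA) {
  if (radius <= 0) stop("radius must be > 0")
  structure(list(row = row, col = col, radius = radius,
                 signal_mean = signal_mean,
                 background_mean = background_mean,
                 background_sigma = background_sigma,
                 is_synaptic = is_synaptic),
            class = "punctum")
}

# Logical disc mask indices around (row, col) within an nr x nc image.
disc_pixels <- function(row, col, radius, nr, nc) {
  rr <- max(1, floor(row - radius)):min(nr, ceiling(row + radius))
  cc <- max(1, floor(col - radius)):min(nc, ceiling(col + radius))
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - row)^2 + (g$col - col)^2 <= radius^2, , drop = FALSE]
  g
}

roi_mean <- function(image, row, col, radius) {
  px <- disc_pixels(row, col, radius, nrow(image), ncol(image))
  mean(image[cbind(px$row, px$col)])
}

#' Detect candidate puncta in a synapse-label image
#'
#' Local-maximum detection after light Gaussian smoothing: maxima above
#' `candidate_threshold` are kept, then greedily suppressed so surviving
#' candidates are separated by at least `min_distance` pixels (brighter
#' candidates win). Candidates are returned sorted by descending ROI mean
#' signal, ties broken by (row, col).
#'
#' @param image 2-D numeric matrix, a single frame or (typically) the
#'   [time_average()] of the synapse channel; finite and nonnegative.
#' @param min_distance minimum centre separation in pixels.
#' @param candidate_threshold absolute intensity threshold for maxima; by
#'   default `median(image) + 4 * mad(image)` — a robust background
#'   estimate that is insensitive to how much of the field the puncta
#'   cover.
#' @param radius ROI radius assigned to each candidate (px).
#' @param smooth_sigma Gaussian pre-smoothing sd in px (0 disables).
#' @return A list of [punctum()] candidates (synaptic call not yet made).
#' @export
detect_puncta <- function(image, min_distance = 4, candidate_threshold = NULL,
                          radius = 3, smooth_sigma = 1) {
  if (length(image) == 0) stop("empty image")
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  if (any(!is.finite(image))) stop("image must be finite")
  if (is.null(candidate_threshold)) {
    spread <- stats::mad(image)
    if (spread == 0) spread <- stats::sd(image)
    candidate_threshold <- stats::median(image) + 4 * spread
  }
  sm <- image
  if (smooth_sigma > 0) {
    # EBImage works in (x, y) = (col, row); transpose in and out
    sm <- t(EBImage::gblur(t(image), sigma = smooth_sigma))
  }
  # local maxima: pixels equal to the disc-dilated (max-filtered) image
  brush_size <- 2L * ceiling(min_distance / 2) + 1L
  mx <- t(EBImage::dilate(t(sm), EBImage::makeBrush(brush_size, "disc")))
  cand <- which(sm >= mx & sm > candidate_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list())
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
    if (all(d2 >= min_distance^2)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- unname(cand[i, 1]); cc <- unname(cand[i, 2])
    punctum(r, cc, radius = radius,
            signal_mean = roi_mean(image, r, cc, radius))
  })
  sm_vals <- vapply(out, `[[`, numeric(1), "signal_mean")
  rows <- vapply(out, `[[`, numeric(1), "row")
  cols <- vapply(out, `[[`, numeric(1), "col")
  out[order(-sm_vals, rows, cols)]
}

# Candidate offsets for the two background ROIs: along rows, then columns,
# then the two diagonals.
background_offsets <- function(step) {
  list(rbind(c(-step, 0), c(step, 0)),
       rbind(c(0, -step), c(0, step)),
       rbind(c(-step, -step), c(step, step)),
       rbind(c(-step, step), c(step, -step)))
}

#' Make the synaptic call for a punctum by the local-background 2-sigma rule
#'
#' Places two equally sized background ROIs of the punctum's radius at
#' +/- 2.5 radii along the row axis (falling back to the column axis, then
#' the diagonals, if either would leave the image or overlap another
#' candidate), pools their pixel values into `background_mean` and
#' `background_sigma` (pixel-value sd), and sets
#' `is_synaptic = signal_mean > background_mean + 2 * background_sigma`.
#'
#' @param p a [punctum()].
#' @param image 2-D matrix the punctum was detected in.
#' @param others optional list of other candidate [punctum()]s the
#'   background ROIs must not overlap.
#' @return The punctum with background statistics and `is_synaptic` set;
#'   if no placement fits, `is_synaptic` stays `NA` (flagged, not called).
#' @export
call_synaptic <- function(p, image, others = list()) {
  stopifnot(inherits(p, "punctum"))
  nr <- nrow(image); nc <- ncol(image)
  step <- 2.5 * p$radius
  ok_pos <- function(row, col) {
    if (row - p$radius < 1 || row + p$radius > nr ||
        col - p$radius < 1 || col + p$radius > nc) return(FALSE)
    for (o in others) {
      if (o$row == p$row && o$col == p$col) next
      if ((o$row - row)^2 + (o$col - col)^2 < (o$radius + p$radius)^2)
        return(FALSE)
    }
    TRUE
  }
  for (offs in background_offsets(step)) {
    pos <- sweep(offs, 2, c(p$row, p$col), `+`)
    if (ok_pos(pos[1, 1], pos[1, 2]) && ok_pos(pos[2, 1], pos[2, 2])) {
      px <- rbind(disc_pixels(pos[1, 1], pos[1, 2], p$radius, nr, nc),
                  disc_pixels(pos[2, 1], pos[2, 2], p$radius, nr, nc))
      vals <- image[cbind(px$row, px$col)]
      p$background_mean <- mean(vals)
      p$background_sigma <- stats::sd(vals)
      if (is.na(p$signal_mean))
        p$signal_mean <- roi_mean(image, p$row, p$col, p$radius)
      p$is_synaptic <- p$signal_mean >
        p$background_mean + 2 * p$background_sigma
      return(p)
    }
  }
  p  # too close to the border: flagged (is_synaptic stays NA), not called
}

#' Extract the raw intensity trace of a punctum from a movie
#'
#' Per-frame mean intensity over the punctum's circular ROI mask.
#'
#' @param movie a [dcv_movie()].
#' @param p a [punctum()] lying inside every frame.
#' @param schedule a [protocol_schedule()] to attach; by default a trivial
#'   schedule spanning the movie is built from the movie's frame interval.
#' @param roi_id identifier stored on the trace.
#' @return A raw [dcv_trace()] of length `n_frames(movie)`.
#' @export
extract_trace <- function(movie, p, schedule = NULL, roi_id = NA_integer_) {
  stopifnot(inherits(movie, "dcv_movie"), inherits(p, "punctum"))
  d <- dim(movie$data)
  px <- disc_pixels(p$row, p$col, p$radius, d[1], d[2])
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  idx <- (px$col - 1L) * d[1] + px$row
  values <- colMeans(flat[idx, , drop = FALSE])
  if (is.null(schedule)) {
    nf <- d[3]
    schedule <- protocol_schedule(
      baseline = c(1, max(2, nf %/% 5)),
      stimulation = c(max(2, nf %/% 5), max(3, 2 * (nf %/% 5))),
      rest = c(max(3, 2 * (nf %/% 5)), max(4, 3 * (nf %/% 5))),
      nh4cl = c(max(4, 3 * (nf %/% 5)), max(5, 4 * (nf %/% 5))),
      washout = c(max(5, 4 * (nf %/% 5)), nf + 1),
      frame_interval = movie$frame_interval)
  }
  dcv_trace(values, schedule, roi_id = roi_id)
}

#' Detect, call, and tabulate synaptic ROIs from a synapse-label movie
#'
#' Convenience wrapper: time-averages the synapse channel, runs
#' [detect_puncta()] and [call_synaptic()] for each candidate, and returns
#' a tidy table.
#'
#' @param synapse_movie a [dcv_movie()] of the synapse-label channel.
#' @inheritParams detect_puncta
#' @return A data.frame with columns `roi_id`, `row`, `col`, `radius`,
#'   `signal_mean`, `background_mean`, `background_sigma`, `is_synaptic`.
#' @export
detect_synaptic_rois <- function(synapse_movie, min_distance = 4,
                                 candidate_threshold = NULL, radius = 3,
                                 smooth_sigma = 1) {
  img <- time_average(synapse_movie)
  cands <- detect_puncta(img, min_distance = min_distance,
                         candidate_threshold = candidate_threshold,
                         radius = radius, smooth_sigma = smooth_sigma)
  called <- lapply(cands, call_synaptic, image = img, others = cands)
  puncta_table(called)
}

#' Tabulate a list of puncta
#'
#' @param puncta list of [punctum()] objects.
#' @return data.frame, one row per punctum.
#' @export
puncta_table <- function(puncta) {
  if (!length(puncta))
    return(data.frame(roi_id = integer(0), row = numeric(0),
                      col = numeric(0), radius = numeric(0),
                      signal_mean = numeric(0), background_mean = numeric(0),
                      background_sigma = numeric(0), is_synaptic = logical(0)))
  data.frame(roi_id = seq_along(puncta),
             row = vapply(puncta, `[[`, numeric(1), "row"),
             col = vapply(puncta, `[[`, numeric(1), "col"),
             radius = vapply(puncta, `[[`, numeric(1), "radius"),
             signal_mean = vapply(puncta, `[[`, numeric(1), "signal_mean"),
             background_mean = vapply(puncta, `[[`, numeric(1),
                                      "background_mean"),
             background_sigma = vapply(puncta, `[[`, numeric(1),
                                       "background_sigma"),
             is_synaptic = vapply(puncta, function(p)
               as.logical(p$is_synaptic), logical(1)))
}
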