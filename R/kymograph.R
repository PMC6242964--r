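#' Axon path for kymograph construction
#'
#' An ordered polyline in pixel coordinates, soma first (so increasing
#' arc length is the anterograde direction), with a transverse averaging
#' width.
#'
#' @param vertices numeric matrix of `(row, col)` vertices (>= 2, ordered
#'   soma -> distal, consecutive vertices distinct).
#' @param width transverse width in pixels over which intensity is
#'   max-projected (odd integer, default 3).
#' @param pixel_size um per pixel, used for the arc-length lookup.
#' @return An object of class `axon_path` with precomputed cumulative
#'   arc length (`arc_px`) per vertex.
#' @export
axon_path <- function(vertices, width = 3, pixel_size = 1) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2) stop("axon path needs >= 2 vertices")
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("consecutive vertices must be distinct")
  structure(list(vertices = vertices, width = as.integer(width),
                 pixel_size = pixel_size,
                 arc_px = c(0, cumsum(seg_len))),
            class = "axon_path")
}

#' Total path length in micrometres
#' @param path an [axon_path()].
#' @return Numeric scalar.
#' @export
path_length_um <- function(path) {
  stopifnot(inherits(path, "axon_path"))
  max(path$arc_px) * path$pixel_size
}

# (row, col) point and unit normal at arc-length position s (px).
path_point <- function(path, s) {
  i <- findInterval(s, path$arc_px, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(path$vertices) - 1L)
  p0 <- path$vertices[i, , drop = FALSE]
  p1 <- path$vertices[i + 1L, , drop = FALSE]
  seg_len <- path$arc_px[i + 1L] - path$arc_px[i]
  f <- (s - path$arc_px[i]) / seg_len
  pt <- p0 + f * (p1 - p0)
  tang <- (p1 - p0) / seg_len
  list(point = pt, normal = cbind(-tang[, 2], tang[, 1]))
}

bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr); col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Build a kymograph along an axon path
#'
#' Samples the path at `position_step` um intervals; each kymograph pixel
#' `(frame, position)` is the maximum movie intensity over the transverse
#' width (bilinear interpolation) at that arc-length position —
#' max-projection preserves punctate vesicle signal.
#'
#' @param movie a single-channel [dcv_movie()].
#' @param path an [axon_path()]; its `pixel_size` is overridden by the
#'   movie's.
#' @param position_step position bin size in um (default: one pixel).
#' @return An object of class `kymograph`: `data` (frames x position
#'   bins), `position_step` (um), `frame_interval` (s), `positions_um`
#'   (bin centres).
#' @export
build_kymograph <- function(movie, path, position_step = NULL) {
  stopifnot(inherits(movie, "dcv_movie"), inherits(path, "axon_path"))
  path$pixel_size <- movie$pixel_size
  if (is.null(position_step)) position_step <- movie$pixel_size
  total_um <- path_length_um(path)
  n_bins <- ceiling(total_um / position_step)
  if (n_bins < 2) stop("degenerate path: fewer than 2 position bins")
  pos_um <- (seq_len(n_bins) - 0.5) * position_step
  s_px <- pmin(pos_um / movie$pixel_size, max(path$arc_px))
  pp <- path_point(path, s_px)
  offs <- seq(-(path$width - 1) / 2, (path$width - 1) / 2)
  nf <- dim(movie$data)[3]
  kymo <- matrix(0, nf, n_bins)
  for (f in seq_len(nf)) {
    img <- movie$data[, , f]
    prof <- matrix(-Inf, length(offs), n_bins)
    for (k in seq_along(offs))
      prof[k, ] <- bilinear(img, pp$point[, 1] + offs[k] * pp$normal[, 1],
                            pp$point[, 2] + offs[k] * pp$normal[, 2])
    kymo[f, ] <- apply(prof, 2, max)
  }
  structure(list(data = kymo, position_step = position_step,
                 frame_interval = movie$frame_interval,
                 positions_um = pos_um),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d bins (%.3g um/bin, %.3g s/frame)\n",
              nrow(x$data), ncol(x$data), x$position_step,
              x$frame_interval))
  invisible(x)
}

#' One vesicle trajectory in (time, position) space
#'
#' @param frames strictly increasing integer frame indices.
#' @param positions_um positions along the axon (um), one per frame.
#' @param frame_interval seconds per frame.
#' @return An object of class `kymograph_track` (metrics unset until
#'   [track_metrics()]).
#' @export
kymograph_track <- function(frames, positions_um, frame_interval) {
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  if (length(frames) != length(positions_um))
    stop("frames and positions_um must have equal length")
  structure(list(frames = as.integer(frames),
                 positions_um = as.numeric(positions_um),
                 frame_interval = frame_interval,
                 total_travel_length_um = NA_real_,
                 average_speed_um_s = NA_real_,
                 direction = NA_character_),
            class = "kymograph_track")
}

# 1-D sub-bin localization: 3-point parabolic interpolation around a peak.
parabolic_refine <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

# Per-row peak positions (in fractional bins) above a robust
# median + k*mad row background. A noiseless row has mad 0; then any
# spot rising halfway above the background is accepted.
row_peaks <- function(y, k_sigma, min_distance = 3) {
  med <- stats::median(y)
  spread <- stats::mad(y)
  thr <- if (spread > 0) med + k_sigma * spread
         else med + 0.5 * (max(y) - med)
  if (!is.finite(thr)) return(numeric(0))
  n <- length(y)
  is_max <- y > thr &
    y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  idx <- which(is_max)
  if (!length(idx)) return(numeric(0))
  # suppress maxima closer than min_distance (brighter wins)
  idx <- idx[order(-y[idx])]
  kept <- integer(0)
  for (i in idx) if (!length(kept) || all(abs(kept - i) >= min_distance))
    kept <- c(kept, i)
  sort(vapply(kept, function(i) parabolic_refine(y, i), numeric(1)))
}

#' Extract vesicle tracks from a kymograph
#'
#' Per-frame 1-D peak detection (row mean + `k_sigma` sd thresholding with
#' 3-point parabolic sub-bin refinement) followed by greedy
#' nearest-neighbour linking across consecutive frames with jumps limited
#' to `link_max_jump` bins; ties are broken by the smallest jump, then the
#' leftmost position. Unmatched detections start new tracks; tracks
#' shorter than `min_duration_frames` are dropped. Crossing trajectories
#' may swap identities at the crossing (documented limitation).
#'
#' @param kymo a [kymograph].
#' @param min_duration_frames minimum track length in frames (default 10).
#' @param link_max_jump maximum per-frame jump in bins (default 5).
#' @param k_sigma per-row detection threshold multiplier (default 4).
#' @param max_gap frames a track may coast without a detection before it
#'   is terminated (default 2).
#' @return A list of [kymograph_track()]s with metrics computed.
#' @export
extract_tracks <- function(kymo, min_duration_frames = 10,
                           link_max_jump = 5, k_sigma = 4, max_gap = 2) {
  stopifnot(inherits(kymo, "kymograph"))
  nf <- nrow(kymo$data)
  det <- lapply(seq_len(nf), function(f)
    row_peaks(kymo$data[f, ], k_sigma))
  active <- list()   # each: list(frames, bins, last_frame)
  done <- list()
  for (f in seq_len(nf)) {
    peaks <- det[[f]]
    assigned <- rep(FALSE, length(peaks))
    if (length(active)) {
      last_bins <- vapply(active, function(tr) tr$bins[length(tr$bins)],
                          numeric(1))
      used_tr <- rep(FALSE, length(active))
      # candidate links ordered by jump size, then leftmost peak
      links <- expand.grid(tr = seq_along(active), pk = seq_along(peaks))
      if (nrow(links)) {
        links$jump <- abs(last_bins[links$tr] - peaks[links$pk])
        links <- links[links$jump <= link_max_jump, , drop = FALSE]
        links <- links[order(links$jump, peaks[links$pk]), , drop = FALSE]
        for (j in seq_len(nrow(links))) {
          tr <- links$tr[j]; pk <- links$pk[j]
          if (used_tr[tr] || assigned[pk]) next
          active[[tr]]$frames <- c(active[[tr]]$frames, f)
          active[[tr]]$bins <- c(active[[tr]]$bins, peaks[pk])
          active[[tr]]$last_frame <- f
          used_tr[tr] <- TRUE
          assigned[pk] <- TRUE
        }
      }
      ended <- which(!used_tr &
                       f - vapply(active, `[[`, numeric(1), "last_frame") >
                         max_gap)
      if (length(ended)) {
        done <- c(done, active[ended])
        active <- active[-ended]
      }
    }
    for (pk in which(!assigned))
      active <- c(active, list(list(frames = f, bins = peaks[pk],
                                    last_frame = f)))
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$frames) >= min_duration_frames, done)
  lapply(done, function(tr)
    track_metrics(kymograph_track(
      tr$frames, (tr$bins - 0.5) * kymo$position_step,
      kymo$frame_interval)))
}

#' Compute travel length, speed and direction of a track
#'
#' `total_travel_length_um` is the sum of absolute per-frame
#' displacements (always >= the net displacement, with equality only for
#' monotone motion); `average_speed_um_s` divides it by the track
#' duration, pauses included. Direction is `stationary` when the absolute
#' net displacement is below `stationary_threshold_um`, else
#' `anterograde` for positive net displacement along the path's
#' soma -> distal vertex order, `retrograde` otherwise.
#'
#' @param track a [kymograph_track()] with >= 2 points.
#' @param stationary_threshold_um net-displacement threshold (default
#'   0.5 um).
#' @return The track with metrics filled in.
#' @export
track_metrics <- function(track, stationary_threshold_um = 0.5) {
  stopifnot(inherits(track, "kymograph_track"))
  if (length(track$frames) < 2) stop("track needs >= 2 points")
  steps <- diff(track$positions_um)
  net <- sum(steps)
  track$total_travel_length_um <- sum(abs(steps))
  dur <- (track$frames[length(track$frames)] - track$frames[1]) *
    track$frame_interval
  track$average_speed_um_s <- track$total_travel_length_um / dur
  track$direction <- if (abs(net) < stationary_threshold_um) "stationary"
                     else if (net > 0) "anterograde" else "retrograde"
  track
}

#' @export
print.kymograph_track <- function(x, ...) {
  cat(sprintf(
    "kymograph_track: %d frames, length %.2f um, speed %.2f um/s, %s\n",
    length(x$frames), x$total_travel_length_um, x$average_speed_um_s,
    x$direction))
  invisible(x)
}

#' Tabulate per-track transport metrics
#'
#' @param tracks list of [kymograph_track()]s (metrics computed).
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `total_travel_length_um`, `average_speed_um_s`, `direction`.
#' @export
tracks_table <- function(tracks) {
  if (!length(tracks))
    return(data.frame(track_id = integer(0), n_frames = integer(0),
                      total_travel_length_um = numeric(0),
                      average_speed_um_s = numeric(0),
                      direction = character(0)))
  data.frame(
    track_id = seq_along(tracks),
    n_frames = vapply(tracks, function(t) length(t$frames), integer(1)),
    total_travel_length_um = vapply(tracks, `[[`, numeric(1),
                                    "total_travel_length_um"),
    average_speed_um_s = vapply(tracks, `[[`, numeric(1),
                                "average_speed_um_s"),
    direction = vapply(tracks, `[[`, character(1), "direction"))
}
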