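# Render an isotropic 2-D Gaussian spot (peak height `amp`) into `img`.
add_gaussian_spot <- function(img, row, col, sigma, amp) {
  r <- ceiling(4 * sigma)
  rows <- max(1, floor(row - r)):min(nrow(img), ceiling(row + r))
  cols <- max(1, floor(col - r)):min(ncol(img), ceiling(col + r))
  if (!length(rows) || !length(cols)) return(img)
  g <- amp * exp(-(outer((rows - row)^2, (cols - col)^2, "+")) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

# Stimulation- and NH4Cl-locked delta-F/F0 time course for one ROI of a
# release movie: saturating rise during each window, exponential decay
# after it. Amplitudes a_stim/a_nh4cl are the asymptotic window responses.
roi_protocol_dff <- function(schedule, a_stim, a_nh4cl,
                             stim_tau = 5, nh4cl_tau = 10, decay_tau = 20) {
  dt <- schedule$frame_interval
  t <- (seq_len(n_frames(schedule)) - 1) * dt
  comp <- function(win, a, tau) {
    t0 <- (win[1] - 1) * dt
    t1 <- (win[2] - 1) * dt
    peak <- a * (1 - exp(-(t1 - t0) / tau))
    ifelse(t < t0, 0,
           ifelse(t < t1, a * (1 - exp(-(t - t0) / tau)),
                  peak * exp(-(t - t1) / decay_tau)))
  }
  comp(schedule$stimulation, a_stim, stim_tau) +
    comp(schedule$nh4cl, a_nh4cl, nh4cl_tau)
}

#' Generate a two-channel synthetic release movie with ground truth
#'
#' Renders punctate synaptic ROIs on a noisy background. The reporter
#' (pHluorin) channel shows, per ROI, a stimulation-locked transient and a
#' global NH4Cl-locked de-quench to the ROI's total-expression level; the
#' synapse-label (FM-dye) channel shows static Gaussian puncta at the same
#' positions. Both channels share calibration. Camera noise follows the
#' Poisson-Gaussian model.
#'
#' @param rois data.frame with one row per planted punctum: columns `row`,
#'   `col` (pixel centres), `a_stim` (asymptotic stimulation-locked
#'   delta-F/F0 amplitude), `a_nh4cl` (NH4Cl/total-expression amplitude),
#'   and optionally `f0` (resting reporter brightness, default 50) and
#'   `fm_amplitude` (synapse-channel punctum height, default 100). Zero
#'   rows give a pure-background reporter channel.
#' @param schedule a [protocol_schedule()].
#' @param noise a [noise_model()]; `background_level` is the camera
#'   background of both channels.
#' @param frame_dim `c(rows, cols)` image size.
#' @param punctum_sigma Gaussian spot sd in pixels.
#' @param pixel_size,`...` calibration passed to [dcv_movie()].
#' @param frame_interval seconds per frame; defaults to the schedule's.
#' @return A list with `reporter` and `synapse` ([dcv_movie()]s) and
#'   `ground_truth`: the `rois` table augmented with the effective window
#'   peaks and the expected release ratio
#'   `I1/(I1+I2)`, plus `warnings` (e.g. overlapping puncta) and the
#'   generation parameters.
#' @export
generate_timelapse_movie <- function(rois, schedule, noise = noise_model(),
                                     frame_dim = c(64, 64),
                                     punctum_sigma = 2, pixel_size = 0.16,
                                     frame_interval = NULL) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  if (is.null(frame_interval)) frame_interval <- schedule$frame_interval
  nf <- n_frames(schedule)
  nr <- frame_dim[1]; nc <- frame_dim[2]
  n_roi <- if (is.null(rois) || nrow(rois) == 0) 0L else nrow(rois)
  warnings <- character(0)
  if (n_roi > 0) {
    if (any(rois$row < 1 | rois$row > nr | rois$col < 1 | rois$col > nc))
      stop("punctum positions must lie inside the frame")
    if (is.null(rois$f0)) rois$f0 <- 50
    if (is.null(rois$fm_amplitude)) rois$fm_amplitude <- 100
    if (n_roi > 1) {
      d <- as.matrix(stats::dist(rois[, c("row", "col")]))
      diag(d) <- Inf
      # nominal punctum radius taken as 2*sigma
      close_pairs <- which(d < 2 * (2 * punctum_sigma), arr.ind = TRUE)
      close_pairs <- close_pairs[close_pairs[, 1] < close_pairs[, 2], ,
                                 drop = FALSE]
      if (nrow(close_pairs) > 0)
        warnings <- c(warnings, sprintf(
          "puncta %d and %d overlap (closer than 2x punctum radius)",
          close_pairs[, 1], close_pairs[, 2]))
    }
  }

  reporter <- array(0, c(nr, nc, nf))
  synapse <- array(0, c(nr, nc, nf))
  gt <- NULL
  if (n_roi > 0) {
    dffs <- lapply(seq_len(n_roi), function(i)
      roi_protocol_dff(schedule, rois$a_stim[i], rois$a_nh4cl[i]))
    fm_frame <- matrix(0, nr, nc)
    for (i in seq_len(n_roi))
      fm_frame <- add_gaussian_spot(fm_frame, rois$row[i], rois$col[i],
                                    punctum_sigma, rois$fm_amplitude[i])
    for (f in seq_len(nf)) {
      img <- matrix(0, nr, nc)
      for (i in seq_len(n_roi))
        img <- add_gaussian_spot(img, rois$row[i], rois$col[i],
                                 punctum_sigma,
                                 rois$f0[i] * (1 + dffs[[i]][f]))
      reporter[, , f] <- img
      synapse[, , f] <- fm_frame
    }
    dt <- schedule$frame_interval
    stim_dur <- diff(schedule$stimulation) * dt
    nh4cl_dur <- diff(schedule$nh4cl) * dt
    peak_stim <- rois$a_stim * (1 - exp(-stim_dur / 5))
    peak_nh4cl <- rois$a_nh4cl * (1 - exp(-nh4cl_dur / 10))
    gt <- cbind(rois,
                data.frame(roi_id = seq_len(n_roi),
                           peak_stim = peak_stim, peak_nh4cl = peak_nh4cl,
                           expected_ratio = peak_stim /
                             (peak_stim + peak_nh4cl)))
  }
  reporter <- apply_camera_noise(reporter, noise, seed_offset = 0L)
  synapse <- apply_camera_noise(synapse, noise, seed_offset = 1L)
  reporter[reporter < 0] <- 0
  synapse[synapse < 0] <- 0
  list(reporter = dcv_movie(reporter, pixel_size, frame_interval,
                            "reporter"),
       synapse = dcv_movie(synapse, pixel_size, frame_interval, "synapse"),
       ground_truth = list(rois = gt, warnings = warnings,
                           punctum_sigma = punctum_sigma,
                           schedule = schedule, noise = noise))
}

#' Kinematic specification for vesicle transport simulation
#'
#' Vesicles follow a per-frame Markov run/pause/reverse process along a 1-D
#' axon coordinate: each frame a vesicle pauses with `pause_probability`,
#' reverses direction (resampling its speed) with `reversal_probability`,
#' and otherwise advances at its current run speed. Run speeds are drawn
#' from a normal distribution truncated at zero.
#'
#' @param n_vesicles number of vesicles (>= 0).
#' @param speed_mean,speed_sd run-speed distribution, um/s (mean >= 0,
#'   sd >= 0).
#' @param pause_probability,reversal_probability per-frame probabilities in
#'   `[0, 1]`.
#' @param direction_mix fraction of vesicles starting anterograde
#'   (increasing axon coordinate), in `[0, 1]`.
#' @param axon_length_um axon length in micrometres (> 0).
#' @return An object of class `transport_spec`.
#' @export
transport_spec <- function(n_vesicles = 10, speed_mean = 1, speed_sd = 0.2,
                           pause_probability = 0.1,
                           reversal_probability = 0.02,
                           direction_mix = 0.5, axon_length_um = 20) {
  probs <- c(pause_probability, reversal_probability, direction_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (speed_mean < 0 || speed_sd < 0) stop("speeds must be >= 0")
  if (n_vesicles < 0) stop("n_vesicles must be >= 0")
  if (axon_length_um <= 0) stop("axon_length_um must be > 0")
  structure(list(n_vesicles = as.integer(n_vesicles),
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 pause_probability = pause_probability,
                 reversal_probability = reversal_probability,
                 direction_mix = direction_mix,
                 axon_length_um = axon_length_um),
            class = "transport_spec")
}

rtrunc_speed <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- stats::rnorm(n, mean, sd)
  while (any(v < 0)) v[v < 0] <- stats::rnorm(sum(v < 0), mean, sd)
  v
}

#' Simulate an axonal transport movie with ground-truth tracks
#'
#' Vesicles are rendered as diffraction-like Gaussian spots moving along a
#' straight horizontal axon by the run/pause/reverse process of
#' [transport_spec()]; positions reflect at the axon ends. Ground truth
#' carries every vesicle's per-frame position (um along the axon), so the
#' kymograph/tracking pipeline can be scored without re-reading generator
#' internals.
#'
#' @param spec a [transport_spec()].
#' @param n_movie_frames number of frames.
#' @param noise a [noise_model()].
#' @param pixel_size um per pixel; `frame_interval` s per frame (10 Hz
#'   default).
#' @param spot_amplitude peak spot intensity; `spot_sigma` spot sd in px.
#' @param margin_px blank margin around the axon.
#' @return A list with `movie` (a [dcv_movie()]), `path` (the
#'   [axon_path()] used, soma at the left end), and `ground_truth`: a list
#'   of [kymograph_track()]s (one per vesicle, with metrics computed from
#'   the true positions) plus the per-frame position matrix and the
#'   per-frame moving/speed states.
#' @export
generate_transport_movie <- function(spec, n_movie_frames = 100,
                                     noise = noise_model(),
                                     pixel_size = 0.1, frame_interval = 0.1,
                                     spot_amplitude = 50, spot_sigma = 1.5,
                                     margin_px = 6) {
  stopifnot(inherits(spec, "transport_spec"))
  n <- spec$n_vesicles
  len_px <- ceiling(spec$axon_length_um / pixel_size)
  nr <- 2L * margin_px + 1L
  nc <- len_px + 2L * margin_px
  row0 <- margin_px + 1L

  pos <- matrix(0, n_movie_frames, max(n, 1))  # um along axon
  moving <- matrix(FALSE, n_movie_frames, max(n, 1))
  L <- spec$axon_length_um
  if (n > 0) {
    sim <- withr::with_seed(noise$seed, {
      p0 <- stats::runif(n, 0.05 * L, 0.95 * L)
      dir <- ifelse(stats::runif(n) < spec$direction_mix, 1, -1)
      speed <- rtrunc_speed(n, spec$speed_mean, spec$speed_sd)
      for (f in seq_len(n_movie_frames)) {
        if (f > 1) {
          rev <- stats::runif(n) < spec$reversal_probability
          if (any(rev)) {
            dir[rev] <- -dir[rev]
            speed[rev] <- rtrunc_speed(sum(rev), spec$speed_mean,
                                       spec$speed_sd)
          }
          mv <- stats::runif(n) >= spec$pause_probability
          step <- ifelse(mv, dir * speed * frame_interval, 0)
          p <- pos[f - 1, seq_len(n)] + step
          # reflect at the axon ends
          over <- p > L; under <- p < 0
          p[over] <- 2 * L - p[over]; dir[over] <- -1
          p[under] <- -p[under]; dir[under] <- 1
          pos[f, seq_len(n)] <- p
          moving[f, seq_len(n)] <- mv
        } else {
          pos[1, seq_len(n)] <- p0
        }
      }
      list(pos = pos, moving = moving)
    })
    pos <- sim$pos; moving <- sim$moving
  }

  arr <- array(0, c(nr, nc, n_movie_frames))
  for (f in seq_len(n_movie_frames)) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(n))
      img <- add_gaussian_spot(img, row0,
                               margin_px + 1 + pos[f, i] / pixel_size,
                               spot_sigma, spot_amplitude)
    arr[, , f] <- img
  }
  arr <- apply_camera_noise(arr, noise, seed_offset = 2L)
  arr[arr < 0] <- 0
  movie <- dcv_movie(arr, pixel_size, frame_interval, "BDNF-EGFP")
  path <- axon_path(rbind(c(row0, margin_px + 1),
                          c(row0, margin_px + 1 + len_px)),
                    pixel_size = pixel_size)
  tracks <- lapply(seq_len(n), function(i) {
    track_metrics(kymograph_track(seq_len(n_movie_frames), pos[, i],
                                  frame_interval))
  })
  list(movie = movie, path = path,
       ground_truth = list(tracks = tracks, positions_um = pos,
                           moving = moving, spec = spec))
}
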