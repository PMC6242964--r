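#' Detect single-vesicle fusion events in a high-rate trace
#'
#' Events are contiguous excursions above
#' `mean(baseline) + k_sigma * sd(baseline)` lasting at least
#' `min_frames` frames; excursions separated by fewer than `merge_gap`
#' frames are merged. The onset is the first frame above threshold and the
#' peak the maximum frame. Each event's segment extends past the excursion
#' for as long as the trace stays above `mean(baseline) + sd(baseline)`,
#' absorbing any later excursions it reaches — an event ends only when the
#' trace returns to baseline (or the trace ends), so slow decays and
#' terminal plateaus stay in one piece.
#'
#' @param trace a normalized [dcv_trace()] sampled at >= 10 Hz with a
#'   baseline window of >= 10 frames.
#' @param k_sigma detection threshold multiplier (default 4).
#' @param min_frames minimum excursion length (default 3).
#' @param merge_gap excursions closer than this many frames are merged
#'   (default 3).
#' @return A list of event descriptors: `onset`, `peak`, `end` (frame
#'   indices), `peak_amplitude`, `segment` (values onset..end), and the
#'   baseline statistics used.
#' @export
detect_events <- function(trace, k_sigma = 4, min_frames = 3,
                          merge_gap = 3) {
  stopifnot(inherits(trace, "dcv_trace"))
  if (!trace$normalized) stop("detect_events requires a normalized trace")
  if (trace$schedule$frame_interval > 0.1 + 1e-9)
    stop("detect_events requires a trace sampled at >= 10 Hz")
  base_idx <- window_frames(trace$schedule, "baseline")
  if (length(base_idx) < 10) stop("baseline window must have >= 10 frames")
  v <- trace$values
  n <- length(v)
  mu <- mean(v[base_idx])
  sg <- stats::sd(v[base_idx])
  thr <- if (sg == 0) mu + 1e-9 else mu + k_sigma * sg
  above <- v > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge excursions separated by short gaps
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1L < merge_gap)
      merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  merged <- merged[(merged[, 2] - merged[, 1] + 1L) >= min_frames, ,
                   drop = FALSE]
  if (nrow(merged) == 0) return(list())
  hold <- mu + (if (sg == 0) 1e-9 else sg)
  out <- list()
  i <- 1L
  while (i <= nrow(merged)) {
    onset <- merged[i, 1]
    end <- merged[i, 2]
    j <- i
    repeat {
      while (end < n && v[end + 1L] > hold) end <- end + 1L
      if (j < nrow(merged) && merged[j + 1L, 1] <= end + 1L) {
        j <- j + 1L
        end <- max(end, merged[j, 2])
      } else break
    }
    seg <- v[onset:end]
    peak <- onset + which.max(seg) - 1L
    out[[length(out) + 1L]] <-
      list(onset = onset, peak = peak, end = end,
           peak_amplitude = v[peak] - mu,
           segment = seg, baseline_mean = mu, baseline_sd = sg,
           frame_interval = trace$schedule$frame_interval,
           roi_id = trace$roi_id)
    i <- j + 1L
  }
  out
}

# Centered running mean (window w), edges handled by shrinking the window.
running_mean <- function(v, w) {
  n <- length(v)
  half <- w %/% 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Two-window median slope estimator (value/s): difference of the forward
# and backward w-frame window medians over their centre separation.
# Medians keep a window that mostly covers a plateau from being dragged by
# the steep segments flanking it.
two_window_slopes <- function(v, dt, w) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    fhi <- min(i + w, n); flo <- min(i + 1L, n)
    blo <- max(i - w, 1L); bhi <- max(i - 1L, 1L)
    sep <- ((flo + fhi) - (blo + bhi)) / 2 * dt
    if (sep <= 0) sep <- dt
    (stats::median(v[flo:fhi]) - stats::median(v[blo:bhi])) / sep
  }, numeric(1))
}

# Standard deviation of the two-window slope estimator per unit of raw
# per-frame noise, accounting for the running-mean pre-smoothing (window
# w_s). The 1.25 factor approximates the efficiency loss of the median.
slope_sd_factor <- function(w, w_s, dt) {
  weights <- stats::convolve(rep(1 / w, w), rep(1 / w_s, w_s),
                             type = "open")
  sqrt(2 * sum(weights^2)) / ((w + 1) * dt) * 1.25
}

# Collapse a state sequence by absorbing runs shorter than min_len into
# their predecessor (or successor for a leading run).
merge_short_runs <- function(state, min_len) {
  r <- rle(state)
  while (length(r$lengths) > 1L && any(r$lengths < min_len)) {
    i <- which(r$lengths < min_len)[1]
    r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
    r <- rle(inverse.rle(r))
  }
  r
}

# Phase decomposition of one event: smoothed segment, peak level m, start
# of the analysis window t0 (first frame reaching 95% of m), and the
# decay/plateau/baseline runs with their mean levels. Shared by
# classify_event() and analyze_events().
event_phase_runs <- function(event, plateau_slope_tol, plateau_min_frames,
                             baseline_tol) {
  seg <- event$segment
  dt <- event$frame_interval
  sd0 <- event$baseline_sd %||% 0
  minf <- plateau_min_frames
  sm_full <- running_mean(seg, minf)
  m <- max(sm_full)
  t0 <- which(sm_full >= 0.95 * m)[1]
  sm <- sm_full[t0:length(sm_full)]
  if (length(sm) < 2L * minf || m <= 0) return(NULL)
  states_at <- function(w) {
    slopes <- two_window_slopes(sm, dt, w)
    thr <- plateau_slope_tol * m + 3 * sd0 * slope_sd_factor(w, minf, dt)
    ifelse(sm < baseline_tol * m, "B",
           ifelse(abs(slopes) < thr & sm >= 1.5 * baseline_tol * m,
                  "P", "D"))
  }
  # the window scale adapts to the noise: near-noiseless data support
  # full-resolution slopes, noisy data need the wider window
  low_noise <- 3 * sd0 < 0.01 * m
  coarse_w <- if (low_noise) minf else 2L * minf
  r <- merge_short_runs(states_at(coarse_w), minf)
  fine <- states_at(minf)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "P") next
    idx <- starts[i]:ends[i]
    if (mean(sm[idx]) >= 0.85 * m) {
      # near-peak plateau candidates must survive at the finer scale: the
      # coarse estimator's sign change across a sharp peak can mimic a hold
      fr <- merge_short_runs(fine[idx], minf)
      if (!any(fr$values == "P" & fr$lengths >= minf)) r$values[i] <- "D"
    } else {
      # low plateaus must be sustained longer when the data are noisy:
      # slope estimates too uncertain to certify a brief shelf
      min_len <- if (low_noise) minf else 2L * minf
      if (length(idx) < min_len) r$values[i] <- "D"
    }
  }
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  level <- vapply(seq_along(r$values), function(i)
    mean(sm[starts[i]:ends[i]]), numeric(1))
  returned <- mean(seg[max(1, length(seg) - minf + 1L):length(seg)]) <
    baseline_tol * m
  list(m = m, t0 = t0,
       runs = data.frame(state = r$values, start = starts, end = ends,
                         level = level),
       returned = returned)
}

#' Classify one fusion event into the five kinetic patterns
#'
#' The decision procedure works on a lightly smoothed copy of the event
#' segment (centered running mean over `plateau_min_frames` frames), with
#' every threshold relative to the smoothed peak level `m` so labels are
#' invariant to amplitude scaling:
#'
#' 1. From the first frame reaching 95% of `m`, each frame is scored
#'    decay (D), plateau (P), or baseline (B): P when the local two-window
#'    median slope magnitude is below `plateau_slope_tol * m` per second
#'    (plus a noise-dependent allowance derived from the baseline sd) and
#'    the level is clearly above baseline; B below `baseline_tol * m`.
#'    Runs shorter than `plateau_min_frames` are absorbed, and plateau
#'    runs are vetted at two window scales (see Details in the package
#'    vignette).
#' 2. Plateau runs at or above 85% of `m` count as a hold at the peak
#'    (`plateau-` prefix); lower plateau runs are interior or terminal
#'    plateaus.
#' 3. `returned_to_baseline`: the trailing `plateau_min_frames` frames
#'    average below `baseline_tol * m`.
#'
#' Assembly: no peak hold and no low plateau, returned -> `full-decay`;
#' one terminal low plateau, not returned -> `decay-plateau`; one low
#' plateau and returned -> `decay-plateau-decay`; peak hold only,
#' returned -> `plateau-decay`; peak hold plus one terminal low plateau,
#' not returned -> `plateau-decay-plateau`. Anything else (extra
#' plateaus, inconsistent return flag) is `"other"`.
#'
#' @param event one event descriptor from [detect_events()], or any list
#'   with `segment`, `peak`, `onset`, `frame_interval` (and optionally
#'   `baseline_sd`).
#' @param plateau_slope_tol plateau slope tolerance as a fraction of the
#'   peak level per second (default 0.05).
#' @param plateau_min_frames minimum sustained frames for a plateau
#'   (default 5, i.e. 0.5 s at 10 Hz).
#' @param baseline_tol return-to-baseline criterion as a fraction of the
#'   peak level (default 0.2).
#' @return The event augmented with `pattern`, `returned_to_baseline`, and
#'   `phases` (the run-state sequence, for audit).
#' @export
classify_event <- function(event, plateau_slope_tol = 0.05,
                           plateau_min_frames = 5, baseline_tol = 0.2) {
  event$pattern <- "other"
  event$returned_to_baseline <- NA
  event$phases <- character(0)
  ph <- event_phase_runs(event, plateau_slope_tol, plateau_min_frames,
                         baseline_tol)
  if (is.null(ph)) return(event)
  runs <- ph$runs
  # trailing baseline is the event's end, interior dips count as decay
  if (nrow(runs) && runs$state[nrow(runs)] == "B")
    runs <- runs[-nrow(runs), , drop = FALSE]
  peak_hold <- any(runs$state == "P" & runs$level >= 0.85 * ph$m)
  low_p <- sum(runs$state == "P" & runs$level < 0.85 * ph$m)
  states <- runs$state
  states[states == "B"] <- "D"
  states <- rle(states)$values
  terminal_p <- length(states) > 0 && states[length(states)] == "P"
  returned <- ph$returned
  event$returned_to_baseline <- returned
  event$phases <- states
  event$pattern <- if (!peak_hold) {
    if (low_p == 0) {
      if (returned) "full-decay" else "other"
    } else if (low_p == 1) {
      if (terminal_p && !returned) "decay-plateau"
      else if (returned) "decay-plateau-decay"
      else "other"
    } else "other"
  } else {
    if (low_p == 0) {
      if (returned) "plateau-decay" else "other"
    } else if (low_p == 1 && terminal_p && !returned) {
      "plateau-decay-plateau"
    } else "other"
  }
  event
}

#' Detect, classify, and fit all events of a trace
#'
#' Runs [detect_events()], [classify_event()], and
#' [fit_single_exponential()] on the rise (onset to peak) and initial
#' decay (peak to the start of the first plateau, or to baseline) of each
#' event.
#'
#' @inheritParams detect_events
#' @inheritParams classify_event
#' @return data.frame, one row per event: `roi_id`, `onset`, `peak`,
#'   `end`, `pattern`, `returned_to_baseline`, `peak_amplitude`,
#'   `rise_tau`, `rise_converged`, `decay_tau`, `decay_converged`.
#' @export
analyze_events <- function(trace, k_sigma = 4, plateau_slope_tol = 0.05,
                           plateau_min_frames = 5, baseline_tol = 0.2) {
  evs <- detect_events(trace, k_sigma = k_sigma)
  rows <- lapply(evs, function(ev) {
    ev <- classify_event(ev, plateau_slope_tol, plateau_min_frames,
                         baseline_tol)
    dt <- ev$frame_interval
    rise_fit <- decay_fit <- NULL
    # rise: a few pre-onset frames anchor the baseline
    lead <- min(3L, ev$onset - 1L)
    rise_seg <- trace$values[(ev$onset - lead):ev$peak]
    if (length(rise_seg) >= 5)
      rise_fit <- fit_single_exponential(rise_seg, dt, "rise")
    # initial decay: from the peak to the first plateau (or baseline)
    ph <- event_phase_runs(ev, plateau_slope_tol, plateau_min_frames,
                           baseline_tol)
    if (!is.null(ph)) {
      runs <- ph$runs
      first_d <- which(runs$state == "D")[1]
      if (!is.na(first_d)) {
        stop_run <- which(runs$state != "D" & seq_len(nrow(runs)) > first_d)[1]
        stop_i <- if (is.na(stop_run)) runs$end[nrow(runs)]
                  else runs$end[stop_run - 1L]
        decay_seg <- ev$segment[(ph$t0 + runs$start[first_d] - 1L):
                                  (ph$t0 + stop_i - 1L)]
        if (length(decay_seg) >= 5)
          decay_fit <- fit_single_exponential(decay_seg, dt, "decay")
      }
    }
    data.frame(
      roi_id = if (is.null(ev$roi_id)) NA_integer_ else ev$roi_id,
      onset = ev$onset, peak = ev$peak, end = ev$end,
      pattern = ev$pattern,
      returned_to_baseline = ev$returned_to_baseline,
      peak_amplitude = ev$peak_amplitude,
      rise_tau = if (is.null(rise_fit)) NA_real_ else rise_fit$tau,
      rise_converged = !is.null(rise_fit) && rise_fit$converged,
      decay_tau = if (is.null(decay_fit)) NA_real_ else decay_fit$tau,
      decay_converged = !is.null(decay_fit) && decay_fit$converged)
  })
  if (!length(rows))
    return(data.frame(roi_id = integer(0), onset = integer(0),
                      peak = integer(0), end = integer(0),
                      pattern = character(0),
                      returned_to_baseline = logical(0),
                      peak_amplitude = numeric(0), rise_tau = numeric(0),
                      rise_converged = logical(0), decay_tau = numeric(0),
                      decay_converged = logical(0)))
  do.call(rbind, rows)
}

#' Per-pattern counts and proportions
#'
#' @param patterns character vector of pattern labels (five canonical
#'   labels plus `"other"`), e.g. the `pattern` column of
#'   [analyze_events()].
#' @return A list with `counts` (named integer vector over the five labels
#'   plus `"other"`) and `proportions` (over classified events, i.e.
#'   excluding `"other"`), plus `n` and `n_other`. Invariant to input
#'   order.
#' @export
summarize_patterns <- function(patterns) {
  labs <- c(release_patterns(), "other")
  counts <- table(factor(patterns, levels = labs))
  counts <- stats::setNames(as.integer(counts), labs)
  n_class <- sum(counts[release_patterns()])
  props <- if (n_class > 0) counts[release_patterns()] / n_class
           else stats::setNames(rep(NA_real_, 5), release_patterns())
  list(counts = counts, proportions = props,
       n = length(patterns), n_other = counts[["other"]])
}
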