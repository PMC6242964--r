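#' The five single-vesicle release patterns
#'
#' Kinetic classes of single-vesicle fusion transients, distinguished by
#' whether decay starts immediately at the peak and whether the trace has
#' returned to baseline by the final imaging frame:
#' `full-decay` (immediate decay, returns to baseline), `decay-plateau`
#' (decays to a sustained level above baseline), `decay-plateau-decay`
#' (decay interrupted by a brief plateau, then returns), `plateau-decay`
#' (held at peak before decaying to baseline) and `plateau-decay-plateau`
#' (held at peak, decays, ends above baseline).
#'
#' @return Character vector of the five labels, in canonical order.
#' @export
release_patterns <- function() {
  c("full-decay", "decay-plateau", "decay-plateau-decay",
    "plateau-decay", "plateau-decay-plateau")
}

#' Kinetic specification of one single-vesicle release transient
#'
#' Parameterizes a piecewise exponential/constant waveform on the
#' delta-F/F0 scale: an exponential rise `a * (1 - exp(-t/rise_tau))` from
#' the onset frame, followed by pattern-specific decay and plateau
#' segments. Plateaus are held at `plateau_level * amplitude`; decays are
#' single exponentials with time constant `decay_tau`, floored at the
#' plateau level for patterns that end in a plateau.
#'
#' @param pattern one of [release_patterns()].
#' @param amplitude peak delta-F/F0 amplitude `a` (> 0).
#' @param rise_tau,decay_tau rise and decay time constants in seconds (> 0).
#' @param plateau_level plateau height as a fraction of `amplitude`, in
#'   `[0, 1]`; ignored (forced to 0) for `full-decay`.
#' @param plateau_duration plateau hold time in seconds; ignored for
#'   `full-decay` and for the open-ended terminal plateau of
#'   `decay-plateau`.
#' @param onset_frame 1-based frame at which the rise starts.
#' @param reacidification_tau time constant (s) of vesicle re-acidification,
#'   an additional fluorescence-loss pathway during decay segments;
#'   `Inf` (the default) disables it.
#' @return An object of class `release_kinetics`.
#' @export
release_kinetics <- function(pattern, amplitude = 1, rise_tau = 0.2,
                             decay_tau = 1, plateau_level = 0.4,
                             plateau_duration = 2, onset_frame = 1L,
                             reacidification_tau = Inf) {
  pattern <- match.arg(pattern, release_patterns())
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be > 0")
  if (plateau_level < 0 || plateau_level > 1)
    stop("plateau_level must be in [0, 1]")
  if (plateau_duration < 0) stop("plateau_duration must be >= 0")
  if (reacidification_tau <= 0) stop("reacidification_tau must be > 0")
  if (pattern == "full-decay") {
    plateau_level <- 0
    plateau_duration <- 0
  }
  structure(list(pattern = pattern, amplitude = amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 plateau_level = plateau_level,
                 plateau_duration = plateau_duration,
                 onset_frame = as.integer(onset_frame),
                 reacidification_tau = reacidification_tau),
            class = "release_kinetics")
}

# Noiseless waveform on the schedule's frame grid. The rise is run for
# 3 * rise_tau (95% of the asymptote) and then hands over to the
# post-peak program; truncating there keeps the peak sharp (the last
# e-folds of an exponential rise are a near-flat ramp that would be
# indistinguishable from a brief plateau). Plateau floors are relative
# to the nominal amplitude.
release_waveform <- function(spec, schedule, reacidify = TRUE) {
  dt <- schedule$frame_interval
  nf <- n_frames(schedule)
  t <- (seq_len(nf) - 1) * dt
  t_on <- (spec$onset_frame - 1) * dt
  t_total <- (nf - 1) * dt
  rise_dur <- 3 * spec$rise_tau
  t_peak <- t_on + rise_dur
  a <- spec$amplitude
  peak <- a * (1 - exp(-rise_dur / spec$rise_tau))
  lev <- spec$plateau_level * a
  k_decay <- 1 / spec$decay_tau
  if (reacidify && is.finite(spec$reacidification_tau))
    k_decay <- k_decay + 1 / spec$reacidification_tau

  # time (s after peak) at which a decay from `from` crosses `lev`
  cross <- function(from) if (lev > 0 && from > lev) log(from / lev) / k_decay else Inf
  pat <- spec$pattern
  # end-of-plateau check for patterns that must decay after their plateau
  if (pat %in% c("decay-plateau-decay", "plateau-decay", "plateau-decay-plateau")) {
    plateau_end <- switch(pat,
      "decay-plateau-decay" = t_peak + cross(peak) + spec$plateau_duration,
      t_peak + spec$plateau_duration)
    if (!is.finite(plateau_end) || plateau_end >= t_total)
      stop("plateau extends past the end of the trace for pattern '", pat,
           "'; shorten plateau_duration or lengthen the schedule")
  }

  v <- numeric(nf)
  s_rise <- t >= t_on & t < t_peak
  v[s_rise] <- a * (1 - exp(-(t[s_rise] - t_on) / spec$rise_tau))
  post <- t >= t_peak
  s <- t[post] - t_peak
  v[post] <- switch(pat,
    "full-decay" = peak * exp(-s * k_decay),
    "decay-plateau" = pmax(peak * exp(-s * k_decay), lev),
    "decay-plateau-decay" = {
      s1 <- cross(peak)
      s2 <- s1 + spec$plateau_duration
      ifelse(s < s1, peak * exp(-s * k_decay),
             ifelse(s < s2, lev, lev * exp(-(s - s2) * k_decay)))
    },
    "plateau-decay" = {
      d <- spec$plateau_duration
      ifelse(s < d, peak, peak * exp(-(s - d) * k_decay))
    },
    "plateau-decay-plateau" = {
      d <- spec$plateau_duration
      ifelse(s < d, peak, pmax(peak * exp(-(s - d) * k_decay), lev))
    })
  v
}

# Poisson-Gaussian noise on the delta-F/F0 scale: the clean trace is mapped
# to raw fluorescence F = f0 * (1 + dff) with f0 = max(background_level, 1),
# noised on the intensity scale, and mapped back.
noisy_dff <- function(clean, noise, seed_offset = 0L) {
  if (noise$photon_scale == 0 && noise$read_sigma == 0) return(clean)
  f0 <- max(noise$background_level, 1)
  withr::with_seed(noise$seed + as.integer(seed_offset), {
    f <- f0 * (1 + clean)
    if (noise$photon_scale > 0)
      f <- stats::rpois(length(f), pmax(f, 0) * noise$photon_scale) /
        noise$photon_scale
    if (noise$read_sigma > 0)
      f <- f + stats::rnorm(length(f), 0, noise$read_sigma)
    f / f0 - 1
  })
}

#' Generate one synthetic single-vesicle release trace
#'
#' Builds the noiseless piecewise waveform for the requested pattern on the
#' schedule's frame grid, then applies the camera noise model on the
#' delta-F/F0 scale. The returned trace is already normalized
#' (delta-F/F0 units, baseline 0) and carries its ground truth as
#' `attr(trace, "ground_truth")`: the generating spec, the clean waveform,
#' and the noise model, sufficient to score any downstream output.
#'
#' @param spec a [release_kinetics()].
#' @param schedule a [protocol_schedule()]; use
#'   [single_vesicle_schedule()] for 10 Hz event traces.
#' @param noise a [noise_model()]; `read_sigma` acts on a raw-intensity
#'   scale with baseline `max(background_level, 1)`, so with the default
#'   background it is directly the delta-F/F0 noise sd.
#' @param seed_offset integer mixed into the noise seed (used by population
#'   generators to decorrelate traces).
#' @return A normalized [dcv_trace()] with ground truth attached.
#' @export
generate_release_trace <- function(spec, schedule, noise = noise_model(),
                                   seed_offset = 0L) {
  stopifnot(inherits(spec, "release_kinetics"),
            inherits(schedule, "protocol_schedule"))
  clean <- release_waveform(spec, schedule)
  values <- noisy_dff(clean, noise, seed_offset)
  tr <- dcv_trace(values, schedule, normalized = TRUE, f0 = 1)
  attr(tr, "ground_truth") <- list(spec = spec, clean = clean, noise = noise,
                                   seed_offset = as.integer(seed_offset))
  tr
}

#' Generate a labelled population of release events
#'
#' Draws `n` pattern labels i.i.d. from `proportions`, samples each trace's
#' kinetic parameters uniformly from `ranges`, and generates one noisy
#' trace per event with [generate_release_trace()]. Onset frames are drawn
#' uniformly within the stimulation window. Fully deterministic given the
#' noise model's seed.
#'
#' @param n number of events (>= 0).
#' @param proportions numeric 5-vector of class probabilities in the order
#'   of [release_patterns()]; must sum to 1 within 1e-9.
#' @param ranges named list of `c(min, max)` ranges for `amplitude`,
#'   `rise_tau`, `decay_tau`, `plateau_level`, `plateau_duration`.
#' @param noise a [noise_model()]; its seed drives label/parameter draws
#'   and per-trace noise.
#' @param schedule a [protocol_schedule()], default
#'   [single_vesicle_schedule()].
#' @return A list with `traces` (list of [dcv_trace()]), `labels`
#'   (character), and `params` (data.frame of the generating kinetics).
#' @export
generate_event_population <- function(n, proportions,
                                      ranges = list(
                                        amplitude = c(0.5, 2),
                                        rise_tau = c(0.1, 0.4),
                                        decay_tau = c(0.5, 2.5),
                                        plateau_level = c(0.3, 0.6),
                                        plateau_duration = c(1, 3)),
                                      noise = noise_model(),
                                      schedule = single_vesicle_schedule()) {
  if (n < 0) stop("n must be >= 0")
  if (length(proportions) != 5L || any(proportions < 0))
    stop("proportions must be a nonnegative 5-vector")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  pats <- release_patterns()
  if (n == 0)
    return(list(traces = list(), labels = character(0),
                params = data.frame()))
  stim <- window_frames(schedule, "stimulation")
  runif_in <- function(r) stats::runif(1, r[1], r[2])
  draws <- withr::with_seed(noise$seed, {
    labels <- sample(pats, n, replace = TRUE, prob = proportions)
    params <- lapply(seq_len(n), function(i) {
      list(label = labels[i],
           amplitude = runif_in(ranges$amplitude),
           rise_tau = runif_in(ranges$rise_tau),
           decay_tau = runif_in(ranges$decay_tau),
           plateau_level = runif_in(ranges$plateau_level),
           plateau_duration = runif_in(ranges$plateau_duration),
           onset_frame = sample(stim, 1))
    })
    list(labels = labels, params = params)
  })
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- draws$params[[i]]
    spec <- release_kinetics(p$label, amplitude = p$amplitude,
                             rise_tau = p$rise_tau, decay_tau = p$decay_tau,
                             plateau_level = p$plateau_level,
                             plateau_duration = p$plateau_duration,
                             onset_frame = p$onset_frame)
    traces[[i]] <- generate_release_trace(spec, schedule, noise,
                                          seed_offset = i)
    traces[[i]]$roi_id <- i
  }
  params <- do.call(rbind, lapply(draws$params, as.data.frame))
  list(traces = traces, labels = draws$labels, params = params)
}

#' Apply an optical or pharmacological perturbation to a generated trace
#'
#' `mes_quench`: perfusion with membrane-impermeant low-pH MES buffer
#' quenches all surface-exposed (de-quenched) reporter, so every value from
#' frame `k` onward is returned to baseline (noise is retained: the clean
#' signal component is subtracted).
#' `bafilomycin`: blocks the vesicular H+-ATPase, disabling the
#' re-acidification loss pathway; the trace is regenerated from its stored
#' ground truth with `reacidification_tau = Inf`. When re-acidification was
#' already off (the default) the output is identical to the input.
#'
#' @param trace a [dcv_trace()] produced by [generate_release_trace()].
#' @param perturbation `"mes_quench"` or `"bafilomycin"`.
#' @param k frame at which the MES wash reaches the cell (mes_quench only).
#' @return A [dcv_trace()] with updated values and ground truth.
#' @export
apply_perturbation <- function(trace, perturbation, k = NULL) {
  stopifnot(inherits(trace, "dcv_trace"))
  gt <- attr(trace, "ground_truth")
  if (is.null(gt))
    stop("trace carries no ground truth; perturbations apply to generated traces")
  if (!perturbation %in% c("mes_quench", "bafilomycin"))
    stop("unknown perturbation '", perturbation, "'")
  if (perturbation == "mes_quench") {
    if (is.null(k) || k < 1 || k > length(trace$values))
      stop("mes_quench requires a frame k within the trace")
    idx <- seq.int(k, length(trace$values))
    trace$values[idx] <- trace$values[idx] - gt$clean[idx]
    gt$clean[idx] <- 0
    gt$mes_quench_frame <- as.integer(k)
    attr(trace, "ground_truth") <- gt
    trace
  } else {
    spec <- gt$spec
    spec$reacidification_tau <- Inf
    out <- generate_release_trace(spec, trace$schedule, gt$noise,
                                  seed_offset = gt$seed_offset)
    out$roi_id <- trace$roi_id
    out
  }
}
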