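#' Normalize a raw trace to delta-F/F0
#'
#' `f0` is the mean raw intensity over the baseline window; values become
#' `(f - f0) / f0`. Already-normalized traces are returned unchanged with a
#' warning (flagged no-op), making the operation idempotent.
#'
#' @param trace a raw [dcv_trace()].
#' @return A normalized [dcv_trace()] with `f0` recorded.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "dcv_trace"))
  if (trace$normalized) {
    warning("trace is already normalized; returning unchanged")
    return(trace)
  }
  idx <- window_frames(trace$schedule, "baseline")
  f0 <- mean(trace$values[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean f0 must be > 0; trace unusable")
  gt <- attr(trace, "ground_truth")
  trace$values <- (trace$values - f0) / f0
  trace$f0 <- f0
  trace$normalized <- TRUE
  attr(trace, "ground_truth") <- gt
  trace
}

#' Stimulation and NH4Cl peak metrics and the release ratio
#'
#' `I1` is the delta-F/F0 maximum over the stimulation window, `I2` the
#' maximum over the NH4Cl window, and the release ratio is
#' `I1 / (I1 + I2)` — the fraction of the punctum's total reporter content
#' released by stimulation. Negative window maxima (no response) are
#' floored at 0 and flagged; a zero denominator flags the ratio undefined.
#'
#' By default a running 3-point median is applied before taking the
#' window maxima: the maximum of tens of noisy frames is biased upward by
#' about two noise standard deviations, while the median filter leaves
#' the slow (multi-second) window transients measurably unchanged.
#' Set `median_filter = FALSE` for strictly raw maxima.
#'
#' @param trace a normalized [dcv_trace()].
#' @param median_filter apply a 3-point running median before the window
#'   maxima (default `TRUE`).
#' @return A list of class `peak_metrics` with `I1`, `I2`, `ratio`,
#'   `ratio_defined`, and `flags` (character vector of audit flags).
#' @export
peak_metrics <- function(trace, median_filter = TRUE) {
  stopifnot(inherits(trace, "dcv_trace"))
  if (!trace$normalized) stop("peak_metrics requires a normalized trace")
  flags <- character(0)
  v <- if (median_filter) stats::runmed(trace$values, 3) else trace$values
  i1 <- max(v[window_frames(trace$schedule, "stimulation")])
  i2 <- max(v[window_frames(trace$schedule, "nh4cl")])
  if (i1 < 0) { i1 <- 0; flags <- c(flags, "I1_floored") }
  if (i2 < 0) { i2 <- 0; flags <- c(flags, "I2_floored") }
  defined <- (i1 + i2) > 0
  if (!defined) flags <- c(flags, "ratio_undefined")
  structure(list(I1 = i1, I2 = i2,
                 ratio = if (defined) i1 / (i1 + i2) else NA_real_,
                 ratio_defined = defined, flags = flags,
                 roi_id = trace$roi_id),
            class = "peak_metrics")
}

#' Fit a single exponential to a trace segment
#'
#' Least-squares fit of `a * (1 - exp(-t / tau)) + c` with time re-zeroed
#' to the segment start, via Levenberg-Marquardt. For `phase = "rise"` the
#' segment starts at the event onset and `a > 0`; for `phase = "decay"` it
#' starts at the peak and the same form is fitted with `a < 0`
#' (equivalently `(c + a) + |a| * exp(-t/tau)`); one canonical
#' parameterization `(a, tau, c)` is always reported. Deterministic:
#' initialization is `a0` = signed segment span, `tau0` = duration / 3,
#' `c0` = first value, with `tau` bounded in
#' `[frame_interval / 2, 10 * duration]`.
#'
#' @param values numeric segment (>= 5 samples), delta-F/F0 units.
#' @param frame_interval seconds per sample.
#' @param phase `"rise"` or `"decay"`.
#' @return A list of class `exp_fit`: `a`, `tau`, `c`, `phase`, `rmse`,
#'   `converged`, and `flags` (`"degenerate"` for flat segments,
#'   `"tau_at_bound"` when tau hit a bound).
#' @export
fit_single_exponential <- function(values, frame_interval,
                                   phase = c("rise", "decay")) {
  phase <- match.arg(phase)
  values <- as.numeric(values)
  if (length(values) < 5) stop("segment must have >= 5 samples")
  t <- (seq_along(values) - 1) * frame_interval
  dur <- max(t)
  span <- values[length(values)] - values[1]
  out <- list(a = NA_real_, tau = NA_real_, c = NA_real_, phase = phase,
              rmse = NA_real_, converged = FALSE, flags = character(0))
  class(out) <- "exp_fit"
  if (abs(span) < 1e-12 && stats::sd(values) < 1e-12) {
    out$a <- 0; out$c <- values[1]; out$rmse <- 0
    out$flags <- "degenerate"
    return(out)
  }
  lo <- c(a = -Inf, tau = frame_interval / 2, c = -Inf)
  hi <- c(a = Inf, tau = 10 * dur, c = Inf)
  start <- list(a = span, tau = dur / 3, c = values[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-t / tau)) + c,
                      data = data.frame(t = t, y = values),
                      start = start, lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$flags <- "fit_failed"
    return(out)
  }
  cf <- stats::coef(fit)
  out$a <- unname(cf["a"]); out$tau <- unname(cf["tau"])
  out$c <- unname(cf["c"])
  out$rmse <- sqrt(mean(stats::residuals(fit)^2))
  out$converged <- fit$convInfo$isConv %||% TRUE
  tol <- 1e-8 * max(out$tau, 1)
  if (out$tau <= lo["tau"] + tol || out$tau >= hi["tau"] - tol) {
    out$flags <- c(out$flags, "tau_at_bound")
    out$converged <- FALSE
  }
  if ((phase == "rise" && out$a < 0) || (phase == "decay" && out$a > 0))
    out$flags <- c(out$flags, "sign_mismatch")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp_fit (%s): a = %.4g, tau = %.4g s, c = %.4g, rmse = %.3g%s\n",
              x$phase, x$a, x$tau, x$c, x$rmse,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Peak metrics for a set of ROI traces
#'
#' Runs [normalize_trace()] + [peak_metrics()] over the synaptic ROIs of a
#' movie and tabulates the result.
#'
#' @param movie reporter-channel [dcv_movie()].
#' @param rois data.frame as returned by [detect_synaptic_rois()];
#'   only rows with `is_synaptic == TRUE` are measured.
#' @param schedule a [protocol_schedule()].
#' @return data.frame with `roi_id`, `I1`, `I2`, `ratio`, `ratio_defined`.
#' @export
measure_release <- function(movie, rois, schedule) {
  rois <- rois[!is.na(rois$is_synaptic) & rois$is_synaptic, , drop = FALSE]
  out <- lapply(seq_len(nrow(rois)), function(i) {
    p <- punctum(rois$row[i], rois$col[i], rois$radius[i])
    tr <- extract_trace(movie, p, schedule, roi_id = rois$roi_id[i])
    m <- peak_metrics(normalize_trace(tr))
    data.frame(roi_id = rois$roi_id[i], I1 = m$I1, I2 = m$I2,
               ratio = m$ratio, ratio_defined = m$ratio_defined)
  })
  if (!length(out))
    return(data.frame(roi_id = integer(0), I1 = numeric(0), I2 = numeric(0),
                      ratio = numeric(0), ratio_defined = logical(0)))
  do.call(rbind, out)
}
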