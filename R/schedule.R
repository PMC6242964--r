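#' Imaging protocol schedule
#'
#' Describes the frame windows of the standard release-imaging protocol:
#' a baseline period, field stimulation, a short rest, NH4Cl perfusion
#' (which de-quenches all reporter and so reads out total local expression),
#' and washout back to normal bath solution. Windows are half-open frame
#' intervals `[start, end)` in 1-based frame indices, so a window
#' `c(1, 21)` covers frames 1..20.
#'
#' The default mirrors the 1 Hz release protocol: 20 s baseline, 30 s of
#' 10 Hz field stimulation, 60 s rest, 120 s NH4Cl, then 30 s washout.
#'
#' @param baseline,stimulation,rest,nh4cl,washout integer length-2 vectors,
#'   half-open frame windows `[start, end)`.
#' @param frame_interval seconds per frame (> 0).
#' @return An object of class `protocol_schedule`.
#' @examples
#' sched <- protocol_schedule()
#' n_frames(sched)
#' @export
protocol_schedule <- function(baseline = c(1, 21),
                              stimulation = c(21, 51),
                              rest = c(51, 111),
                              nh4cl = c(111, 231),
                              washout = c(231, 261),
                              frame_interval = 1) {
  wins <- list(baseline = baseline, stimulation = stimulation,
               rest = rest, nh4cl = nh4cl, washout = washout)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) != 2L || !is.numeric(w) || any(!is.finite(w)))
      stop("window '", nm, "' must be a finite numeric length-2 vector")
    if (w[1] >= w[2]) stop("window '", nm, "' must have start < end")
    if (w[1] < 1) stop("window '", nm, "' must start at frame >= 1")
  }
  starts <- vapply(wins, `[`, numeric(1), 1L)
  ends <- vapply(wins, `[`, numeric(1), 2L)
  if (any(diff(starts) <= 0) || any(ends[-5] > starts[-1]))
    stop("protocol windows must be disjoint and ordered ",
         "baseline < stimulation < rest < nh4cl < washout")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(c(wins, list(frame_interval = frame_interval)),
            class = "protocol_schedule")
}

#' Number of frames covered by a schedule
#'
#' @param schedule a [protocol_schedule()].
#' @return Integer, the last frame of the washout window.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  as.integer(schedule$washout[2] - 1L)
}

#' Frame indices of a schedule window
#'
#' @param schedule a [protocol_schedule()].
#' @param window one of `"baseline"`, `"stimulation"`, `"rest"`, `"nh4cl"`,
#'   `"washout"`.
#' @return Integer vector of 1-based frame indices (half-open window).
#' @export
window_frames <- function(schedule, window) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  window <- match.arg(window,
                      c("baseline", "stimulation", "rest", "nh4cl", "washout"))
  w <- schedule[[window]]
  seq.int(w[1], w[2] - 1L)
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat("Protocol schedule (", x$frame_interval, " s/frame, ",
      n_frames(x), " frames)\n", sep = "")
  for (nm in c("baseline", "stimulation", "rest", "nh4cl", "washout")) {
    w <- x[[nm]]
    cat(sprintf("  %-12s frames [%d, %d)  (%.0f-%.0f s)\n", nm, w[1], w[2],
                (w[1] - 1) * x$frame_interval, (w[2] - 1) * x$frame_interval))
  }
  invisible(x)
}

#' High-rate protocol for single-vesicle imaging
#'
#' Convenience constructor matching the TIRF single-vesicle protocol:
#' 5 s baseline then 6 s of 50 Hz stimulation, imaged at 10 Hz, with the
#' remainder of the movie available for event decay. The rest/nh4cl/washout
#' windows are nominal (single-vesicle movies are not NH4Cl-perfused, but
#' the schedule type requires the full window set; they occupy the tail).
#'
#' @param total_s total movie duration in seconds (default 30).
#' @param frame_interval seconds per frame (default 0.1, i.e. 10 Hz).
#' @return A [protocol_schedule()].
#' @export
single_vesicle_schedule <- function(total_s = 30, frame_interval = 0.1) {
  nf <- round(total_s / frame_interval)
  b_end <- round(5 / frame_interval) + 1L
  s_end <- b_end + round(6 / frame_interval)
  tail_len <- nf + 1L - s_end
  if (tail_len < 3L) stop("total_s too short for the 5 s + 6 s protocol")
  cut1 <- s_end + tail_len %/% 3L
  cut2 <- s_end + 2L * (tail_len %/% 3L)
  protocol_schedule(baseline = c(1L, b_end),
                    stimulation = c(b_end, s_end),
                    rest = c(s_end, cut1),
                    nh4cl = c(cut1, cut2),
                    washout = c(cut2, nf + 1L),
                    frame_interval = frame_interval)
}
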