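#' Breath-hold acquisition paradigm
#'
#' Describes the timed stimulus protocol: an initial rest phase, an
#' end-exhalation breath-hold, and a recovery phase, sampled at a fixed frame
#' rate per wavelength.  The default (40 s rest, 20 s hold, 60 s recovery at
#' 1 Hz) is the 120 s protocol used throughout the package.
#'
#' All pipeline stages take the paradigm explicitly rather than hard-coding
#' frame numbers.  Conventions shared across the package: time is seconds
#' since acquisition start, frame `i` (1-based) is acquired at
#' `t = (i - 1) / sampling_hz`, the breath-hold window is the half-open
#' interval `(rest_s, rest_s + hold_s]`, and the profile-normalisation onset
#' is `t0 = rest_s`.
#'
#' @param rest_s Rest-phase duration in seconds.
#' @param hold_s Breath-hold duration in seconds.
#' @param recovery_s Recovery-phase duration in seconds.
#' @param sampling_hz Frames per second per wavelength.
#' @return An object of class `bh_paradigm`.
#' @examples
#' p <- paradigm()
#' n_frames(p)        # 120
#' analysis_window(p) # c(41, 80)
#' @export
paradigm <- function(rest_s = 40, hold_s = 20, recovery_s = 60,
                     sampling_hz = 1) {
  if (!all(is.finite(c(rest_s, hold_s, recovery_s, sampling_hz))) ||
      rest_s <= 0 || hold_s <= 0 || recovery_s <= 0 || sampling_hz <= 0) {
    stop("paradigm durations and sampling rate must all be positive", call. = FALSE)
  }
  structure(
    list(rest_s = rest_s, hold_s = hold_s, recovery_s = recovery_s,
         sampling_hz = sampling_hz,
         total_s = rest_s + hold_s + recovery_s),
    class = "bh_paradigm"
  )
}

#' @export
print.bh_paradigm <- function(x, ...) {
  cat(sprintf(
    "Breath-hold paradigm: %g s rest | %g s hold | %g s recovery (%g s total) at %g Hz\n",
    x$rest_s, x$hold_s, x$recovery_s, x$total_s, x$sampling_hz))
  invisible(x)
}

#' Number of frames per wavelength implied by a paradigm
#' @param p A `bh_paradigm`.
#' @return Integer frame count.
#' @export
n_frames <- function(p) {
  stopifnot(inherits(p, "bh_paradigm"))
  as.integer(round(p$total_s * p$sampling_hz))
}

#' Acquisition time of each frame
#' @param p A `bh_paradigm`.
#' @return Numeric vector of timestamps in seconds, starting at 0.
#' @export
frame_times <- function(p) {
  (seq_len(n_frames(p)) - 1) / p$sampling_hz
}

#' Default oxygenation-flow analysis window
#'
#' The correlation analysis uses the 2x`hold_s` span covering the breath-hold
#' and the first `hold_s` seconds of recovery, where the stimulus-locked
#' oxygenation changes are concentrated.  For the default paradigm this is
#' t = 41..80 s (40 frames at 1 Hz).
#'
#' @param p A `bh_paradigm`.
#' @return Numeric `c(start_s, end_s)`, inclusive at both ends.
#' @export
analysis_window <- function(p) {
  stopifnot(inherits(p, "bh_paradigm"))
  c(p$rest_s + 1 / p$sampling_hz, p$rest_s + 2 * p$hold_s)
}

#' Frame indices covered by a time window
#' @param p A `bh_paradigm`.
#' @param window_s `c(start_s, end_s)` inclusive; defaults to
#'   [analysis_window()].
#' @return Integer vector of 1-based frame indices.
#' @export
window_frames <- function(p, window_s = NULL) {
  stopifnot(inherits(p, "bh_paradigm"))
  if (is.null(window_s)) window_s <- analysis_window(p)
  if (length(window_s) != 2 || window_s[2] < window_s[1]) {
    stop("window_s must be c(start_s, end_s) with end >= start", call. = FALSE)
  }
  t <- frame_times(p)
  idx <- which(t >= window_s[1] - 1e-9 & t <= window_s[2] + 1e-9)
  if (length(idx) == 0) stop("window contains no frames", call. = FALSE)
  idx
}

#' Frame index at a given time
#' @param p A `bh_paradigm`.
#' @param t_s Time in seconds since acquisition start.
#' @return 1-based frame index.
#' @export
frame_at_time <- function(p, t_s) {
  idx <- as.integer(round(t_s * p$sampling_hz)) + 1L
  if (any(idx < 1L | idx > n_frames(p))) {
    stop("time outside the acquisition", call. = FALSE)
  }
  idx
}
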