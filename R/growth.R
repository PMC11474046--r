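#' Sliding-average smoothing of an area trajectory
#'
#' Centered moving average used to suppress frame-to-frame segmentation noise
#' before differencing. The default 12-frame window corresponds to 18 min at
#' the 1.5-min phase-contrast imaging interval. The window is applied
#' symmetrically: each point is averaged with up to `floor(window/2)` frames
#' on each side, and near the trajectory ends the window shrinks
#' symmetrically to the frames available, so no data are invented and the
#' output has the same length as the input.
#'
#' @param areas Numeric vector of cell areas (um^2), one per frame, length >= 2.
#' @param window Window width in frames (>= 1).
#' @return Smoothed vector, same length as `areas`.
#' @export
smooth_area <- function(areas, window = 12L) {
  areas <- as.numeric(areas)
  if (length(areas) < 2L) stopf("need at least 2 frames to smooth")
  if (anyNA(areas)) stopf("areas must not contain NA")
  if (window < 1L) stopf("window must be >= 1")
  n <- length(areas)
  h <- floor(window / 2)
  if (h == 0L) return(areas)
  cs <- cumsum(c(0, areas))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

#' Instantaneous relative growth rate
#'
#' Forward difference of the (smoothed) area trajectory divided by the area
#' at the first frame of each consecutive pair and by the frame interval:
#' `rate_i = (A[i+1] - A[i]) / (A[i] * frame_interval)`, in min^-1.
#'
#' @param areas Numeric vector of (typically smoothed) areas, length >= 2,
#'   strictly positive.
#' @param frame_interval Time between frames in minutes.
#' @return Numeric vector of length `length(areas) - 1`.
#' @export
instantaneous_growth_rate <- function(areas, frame_interval) {
  areas <- as.numeric(areas)
  if (length(areas) < 2L) stopf("need at least 2 frames")
  if (any(!is.finite(areas)) || any(areas <= 0)) stopf("areas must be positive and finite")
  if (frame_interval <= 0) stopf("frame_interval must be positive")
  n <- length(areas)
  diff(areas) / (areas[-n] * frame_interval)
}

#' Average growth rate over a cell cycle
#'
#' `ln(A_d / A_b) / dt`: the exponential rate that carries the birth area
#' `A_b` to the division area `A_d` over the interdivision time `dt`.
#'
#' @param a_birth Area at birth (um^2), positive.
#' @param a_division Area at division (um^2), positive.
#' @param dt Interdivision time (min), positive.
#' @return Average growth rate in min^-1.
#' @examples
#' average_growth_rate(2, 4, 60)  # ln(2)/60
#' @export
average_growth_rate <- function(a_birth, a_division, dt) {
  if (any(a_birth <= 0) || any(a_division <= 0) || any(dt <= 0))
    stopf("a_birth, a_division and dt must be positive")
  log(a_division / a_birth) / dt
}

#' Residual score of a single-exponential fit
#'
#' Fits a first-degree polynomial to the log-transformed area trajectory
#' (equivalently, a single exponential to the areas), computes per-frame
#' residuals on the area scale, and scores the trajectory as the mean of
#' `|residual| / area` over frames. Purely exponential growth scores ~0;
#' trajectories with a G1-phase growth dip score higher.
#'
#' @param areas Positive areas, length >= 3.
#' @param times Frame times in minutes, same length, not all equal.
#' @return Dimensionless residual score (>= 0).
#' @export
exp_fit_residuals <- function(areas, times) {
  areas <- as.numeric(areas); times <- as.numeric(times)
  if (length(areas) < 3L) stopf("need at least 3 frames")
  if (length(areas) != length(times)) stopf("areas and times must have equal length")
  if (any(areas <= 0)) stopf("areas must be positive")
  if (diff(range(times)) == 0) stopf("times are degenerate (all equal)")
  fit <- stats::lm.fit(cbind(1, times), log(areas))
  resid <- areas - exp(cbind(1, times) %*% fit$coefficients)[, 1L]
  mean(abs(resid) / areas)
}

#' Per-cell growth profile
#'
#' Convenience wrapper chaining the per-cell computations: area smoothing,
#' instantaneous relative growth rate on the smoothed trajectory, the average
#' growth rate from the active birth assignment (see [assign_birth()]), and
#' the exponential-fit residual score on the raw areas.
#'
#' @param track A `cell_track`, ideally after [assign_birth()].
#' @param frame_interval Imaging interval in minutes.
#' @param window Smoothing window in frames.
#' @return A `growth_profile` list: `cell_id`, `times`, `smoothed_area`,
#'   `inst_rate` (length n_frames - 1), `avg_rate`, `residual_score`,
#'   plus the birth/division bookkeeping carried over from the track.
#' @export
growth_profile <- function(track, frame_interval = 1.5, window = 12L) {
  stopifnot(inherits(track, "cell_track"))
  sm <- smooth_area(track$areas, window)
  rate <- instantaneous_growth_rate(sm, frame_interval)
  avg <- NA_real_
  if (!is.null(track$a_birth) && !is.na(track$a_birth) &&
      !is.null(track$dt) && !is.na(track$dt) && track$dt > 0)
    avg <- average_growth_rate(track$a_birth, track$a_division, track$dt)
  structure(list(
    cell_id = track$cell_id,
    times = track$times,
    smoothed_area = sm,
    inst_rate = rate,
    avg_rate = avg,
    residual_score = exp_fit_residuals(track$areas, track$times),
    birth_time = track$birth_time %||% NA_real_,
    division_time = track$division_time %||% NA_real_
  ), class = "growth_profile")
}

#' Growth profiles for a set of tracks
#'
#' @param tracks A `cell_track_set`.
#' @inheritParams growth_profile
#' @return Named list of `growth_profile` objects (class `growth_profiles`).
#' @export
growth_profiles <- function(tracks, frame_interval = 1.5, window = 12L) {
  stopifnot(inherits(tracks, "cell_track_set"))
  out <- lapply(tracks, growth_profile, frame_interval = frame_interval,
                window = window)
  structure(out, class = "growth_profiles", names = names(tracks))
}

#' @export
print.growth_profile <- function(x, ...) {
  cat(sprintf("Growth profile of cell %s: %d frames, avg rate %s min^-1, residual score %.3g\n",
              x$cell_id, length(x$times),
              if (is.na(x$avg_rate)) "NA" else sprintf("%.5f", x$avg_rate),
              x$residual_score))
  invisible(x)
}
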