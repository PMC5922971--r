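# Event detection on 1 kHz force / dial-orientation traces: touch, force
# plateau, rotation velocity, speed peaks, and sub-movement segmentation.

#' Analysis parameters for the trial-event pipeline
#'
#' All detection constants in one place.  Defaults are the published analysis
#' settings: 17 Hz low-pass for orientation before differentiation, 8.7 Hz for
#' force rate and for the speed derivative used in peak finding, 2.1 Hz for
#' the high-pass speed signal whose minima segment the rotation; touch is the
#' first sample above `baseline + 0.01 N` found by searching backwards from a
#' 0.2 N crossing; the force-rate peak is searched 50-350 ms after touch and
#' the plateau is where the rate first drops below 10% of that peak; the
#' rotation end is the last high-pass minimum more than 200 ms before the
#' shutter opened; trials whose rotation started 350 ms or later after touch
#' are flagged as aborted.
#'
#' @param velocity_cutoff_hz orientation low-pass before differentiation (Hz).
#' @param rate_cutoff_hz force-rate / speed-derivative low-pass (Hz).
#' @param highpass_cutoff_hz cutoff of the speed high-pass (Hz).
#' @param touch_search_force_n force level (N) searched forward before walking
#'   back to the criterion level.
#' @param touch_criterion_n criterion increment (N) above the pre-go baseline
#'   median.
#' @param baseline_window_ms baseline window length before the go signal (ms).
#' @param plateau_window_ms force-rate peak search window after touch (ms).
#' @param plateau_rate_fraction fraction of the peak force rate defining the
#'   plateau.
#' @param min_peak_rate_n_s noise floor (N/s) below which force-rate local
#'   maxima are ignored.
#' @param min_peak_speed_deg_s noise floor (deg/s) below which speed peaks are
#'   ignored (matches the online 10 deg/s movement criterion).
#' @param min_minimum_depth_deg_s depth floor (deg/s) for movement-scale
#'   minima of the high-passed speed; shallower local minima are noise
#'   ripple.
#' @param end_guard_ms rotation-end minima must precede the shutter opening by
#'   more than this (ms).
#' @param abort_latency_ms online onset latency at or above which a trial is
#'   flagged aborted (ms).
#' @param fs sampling rate (Hz).
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(velocity_cutoff_hz = 17,
                            rate_cutoff_hz = 8.7,
                            highpass_cutoff_hz = 2.1,
                            touch_search_force_n = 0.2,
                            touch_criterion_n = 0.01,
                            baseline_window_ms = 500,
                            plateau_window_ms = c(50, 350),
                            plateau_rate_fraction = 0.1,
                            min_peak_rate_n_s = 0.05,
                            min_peak_speed_deg_s = 10,
                            min_minimum_depth_deg_s = 2,
                            end_guard_ms = 200,
                            abort_latency_ms = 350,
                            fs = 1000) {
  structure(as.list(environment()), class = "analysis_params")
}

# index (1-based) of a time in ms on the trial grid
.t2i <- function(trial, t_ms) match(round(t_ms), trial$time)

#' Detect the time of initial touch
#'
#' Baseline force is the median over the 500 ms window ending immediately
#' before the go signal.  The first sample at or after the go signal whose
#' force exceeds 0.2 N anchors a backward search to the last sample at or
#' below `baseline + 0.01 N`; touch is the following sample.  The 0.2 N
#' forward search prevents triggering on noise blips before the true contact.
#'
#' @param trial a `trial_record` (see [trial_record()]).
#' @param params an [analysis_params()].
#' @return touch time (ms).
#' @export
detect_touch <- function(trial, params = analysis_params()) {
  go_i <- .t2i(trial, trial$meta$go_time)
  if (is.na(go_i)) stop("detect_touch: go_time not on the trial time grid")
  b0 <- go_i - params$baseline_window_ms
  if (b0 < 1L) stop("detect_touch: less than ", params$baseline_window_ms,
                    " ms of pre-go baseline")
  baseline <- median(trial$force[b0:(go_i - 1L)])
  after <- go_i - 1L + which(trial$force[go_i:length(trial$force)] >
                               params$touch_search_force_n)
  if (length(after) == 0L) stop("detect_touch: no contact (force never exceeded ",
                                params$touch_search_force_n, " N)")
  anchor <- after[1L]
  below <- which(trial$force[1:anchor] <= baseline + params$touch_criterion_n)
  j <- if (length(below) == 0L) 0L else below[length(below)]
  trial$time[min(j + 1L, anchor)]
}

#' Detect the force plateau after touch
#'
#' The force rate is the symmetric derivative of the 8.7 Hz low-passed force.
#' The maximum local peak of the rate within 50-350 ms after touch (ignoring
#' peaks below the noise floor) anchors a forward search for the first sample
#' where the rate drops below 10% of that peak; the plateau force is the raw
#' force there.  The restricted window avoids capturing the initial impact
#' transient and late force adjustments.
#'
#' @param trial a `trial_record`.
#' @param touch touch time (ms), from [detect_touch()].
#' @param params an [analysis_params()].
#' @return list with `plateau_time` (ms), `plateau_force` (N), `peak_rate`
#'   (N/s), `peak_rate_time` (ms).
#' @export
detect_force_plateau <- function(trial, touch, params = analysis_params()) {
  rate <- symmetric_derivative(
    filter_lowpass(trial$force, params$rate_cutoff_hz, params$fs), params$fs)
  w <- .t2i(trial, touch) + params$plateau_window_ms
  w[2] <- min(w[2], length(rate))
  peaks <- local_extrema(rate, "max")
  peaks <- peaks[peaks >= w[1] & peaks <= w[2] &
                   rate[peaks] >= params$min_peak_rate_n_s]
  if (length(peaks) == 0L) {
    stop("detect_force_plateau: no force-rate local peak above the noise ",
         "floor in the 50-350 ms window after touch")
  }
  pk <- peaks[which.max(rate[peaks])]
  later <- pk - 1L + which(rate[pk:length(rate)] <
                             params$plateau_rate_fraction * rate[pk])
  if (length(later) == 0L) stop("detect_force_plateau: force rate never fell below ",
                                params$plateau_rate_fraction, " of its peak")
  i <- later[1L]
  list(plateau_time = trial$time[i], plateau_force = trial$force[i],
       peak_rate = rate[pk], peak_rate_time = trial$time[pk])
}

#' Rotation velocity of the dial
#'
#' Symmetric numerical differentiation (+/- 1 sample) of the orientation
#' signal after 17 Hz triangular low-pass filtering.
#'
#' @param trial a `trial_record`.
#' @param params an [analysis_params()].
#' @return velocity trace (deg/s), same length as the orientation trace.
#' @export
rotation_velocity <- function(trial, params = analysis_params()) {
  symmetric_derivative(
    filter_lowpass(trial$orientation, params$velocity_cutoff_hz, params$fs),
    params$fs)
}

#' Peaks of the rotation speed profile
#'
#' The speed is the absolute value of the rotation velocity, low-pass filtered
#' at 8.7 Hz; peaks are negative-slope zero crossings of its first time
#' differential.  Peaks below the speed noise floor (default 10 deg/s, the
#' online movement criterion) are ignored.
#'
#' @param speed speed trace (deg/s), i.e. `abs(rotation_velocity(trial))`.
#' @param time time stamps (ms) matching `speed`; defaults to `0:(n-1)`.
#' @param params an [analysis_params()].
#' @return tibble with columns `time` (ms) and `speed` (deg/s at the peak),
#'   in temporal order; zero rows if there are no peaks.
#' @export
find_speed_peaks <- function(speed, time = seq_along(speed) - 1,
                             params = analysis_params()) {
  spd <- filter_lowpass(speed, params$rate_cutoff_hz, params$fs)
  d <- symmetric_derivative(spd, params$fs)
  n <- length(d)
  if (n < 2L) return(tibble::tibble(time = numeric(0), speed = numeric(0)))
  cross <- which(d[-n] > 0 & d[-1] <= 0)
  cross <- cross[spd[cross] >= params$min_peak_speed_deg_s]
  tibble::tibble(time = time[cross], speed = spd[cross])
}

#' Segment the rotation into onset, sub-movements and end
#'
#' Minima of the high-pass filtered speed signal (speed minus its 2.1 Hz
#' triangular low-pass) delimit the rotation.  Speed peaks occurring less
#' than 200 ms before the shutter opened (or after it) are discarded: under
#' the online rule the shutter opens 200 ms after the rotation speed settles,
#' so later peaks belong to visually guided corrections, not to the rotation
#' under study.  The onset is the first movement-scale high-pass minimum
#' found searching backwards from the first peak.  The end is the first
#' movement-scale minimum after which the speed never again exceeds the
#' online movement threshold before the shutter opened (for single-peak
#' trials this is the second, and last, movement-scale minimum); minima
#' followed by renewed movement separate successive sub-movements instead.
#'
#' @param trial a `trial_record`.
#' @param params an [analysis_params()].
#' @return list with `onset` (ms), `boundaries` (ms, possibly empty), `end`
#'   (ms), `n_peaks`, and `force_at_onset` (N).
#' @export
segment_rotation <- function(trial, params = analysis_params()) {
  shutter <- trial$meta$shutter_open_time
  if (is.null(shutter) || is.na(shutter))
    stop("segment_rotation: trial metadata has no shutter_open_time")
  speed <- abs(rotation_velocity(trial, params))
  peaks <- find_speed_peaks(speed, trial$time, params)
  peaks <- peaks[peaks$time < shutter - params$end_guard_ms, ]
  if (nrow(peaks) == 0L)
    stop("segment_rotation: unsegmentable (no speed peak above ",
         params$min_peak_speed_deg_s, " deg/s more than ",
         params$end_guard_ms, " ms before the shutter opening)")
  hp <- filter_highpass(speed, params$highpass_cutoff_hz, params$fs)
  # movement-scale minima: the high-pass dips well below zero at movement
  # edges and between sub-movements, while quiet-period noise ripple stays
  # shallow; the depth floor separates the two
  mi <- local_extrema(hp, "min")
  mi <- mi[hp[mi] <= -params$min_minimum_depth_deg_s]
  tmins <- trial$time[mi]
  before <- tmins[tmins <= peaks$time[1L]]
  if (length(before) == 0L)
    stop("segment_rotation: unsegmentable (no minimum before the first peak)")
  onset <- max(before)
  # the terminal minimum is the first movement-scale minimum after which the
  # speed never again exceeds the online movement threshold before the
  # shutter opened (minima followed by renewed movement separate
  # sub-movements instead)
  shut_i <- min(.t2i(trial, shutter), length(speed), na.rm = TRUE)
  cand <- tmins[tmins > peaks$time[1L] & tmins < shutter]
  end <- NA_real_
  for (m in cand) {
    i <- .t2i(trial, m)
    if (i >= shut_i || max(speed[(i + 1L):shut_i]) <
        params$min_peak_speed_deg_s) { end <- m; break }
  }
  if (is.na(end))
    stop("segment_rotation: unsegmentable (no terminal minimum before the ",
         "shutter opening)")
  boundaries <- tmins[tmins > onset & tmins < end]
  list(onset = onset, boundaries = boundaries, end = end,
       n_peaks = nrow(peaks),
       force_at_onset = trial$force[.t2i(trial, onset)])
}

#' Extract the full event set of one trial
#'
#' Runs touch detection, force-plateau detection and rotation segmentation
#' and checks the event-ordering invariant (touch <= onset <= boundaries <=
#' end, touch <= plateau).
#'
#' @param trial a `trial_record`.
#' @param params an [analysis_params()].
#' @return list of class `event_set`: `touch_time`, `force_plateau_time`,
#'   `plateau_force`, `rotation_onset_time`, `submovement_boundaries`,
#'   `rotation_end_time`, `force_at_onset`, `n_speed_peaks`, `aborted`
#'   (online-rule flag: rotation initiated at or after 350 ms past touch).
#' @export
detect_events <- function(trial, params = analysis_params()) {
  touch <- detect_touch(trial, params)
  plateau <- detect_force_plateau(trial, touch, params)
  seg <- segment_rotation(trial, params)
  ev <- structure(list(
    touch_time = touch,
    force_plateau_time = plateau$plateau_time,
    plateau_force = plateau$plateau_force,
    rotation_onset_time = seg$onset,
    submovement_boundaries = seg$boundaries,
    rotation_end_time = seg$end,
    force_at_onset = seg$force_at_onset,
    n_speed_peaks = seg$n_peaks,
    aborted = online_abort_flag(trial, params)
  ), class = "event_set")
  ok <- touch <= seg$onset && seg$onset <= seg$end &&
    all(seg$boundaries >= seg$onset & seg$boundaries <= seg$end) &&
    touch <= plateau$plateau_time
  if (!ok) stop("detect_events: event ordering invariant violated")
  ev
}

# Online trial-progression rule: touch when force exceeds 0.2 N, rotation
# onset when the online speed exceeds 10 deg/s; aborted if the latter occurs
# >= 350 ms after the former (or never).
online_abort_flag <- function(trial, params = analysis_params()) {
  ft <- which(trial$force > params$touch_search_force_n)
  if (length(ft) == 0L) return(TRUE)
  spd <- online_speed(trial$orientation, fs = params$fs)
  mv <- which(spd > params$min_peak_speed_deg_s & seq_along(spd) >= ft[1L])
  if (length(mv) == 0L) return(TRUE)
  (trial$time[mv[1L]] - trial$time[ft[1L]]) >= params$abort_latency_ms
}

#' Online rotation speed (apparatus emulation)
#'
#' The speed signal the apparatus used for its end-of-rotation rule:
#' sample-to-sample numerical differentiation of the orientation, rectified
#' and smoothed by a first-order low-pass with a 10 ms time constant
#' (coefficient `dt/(tau + dt) = 1/11` per 1 ms sample; corner frequency
#' `1/(2 pi tau)` ~ 16 Hz).
#'
#' @param orientation orientation trace (deg).
#' @param tau_s filter time constant (s).
#' @param fs sampling rate (Hz).
#' @return smoothed speed trace (deg/s).
#' @export
online_speed <- function(orientation, tau_s = 0.010, fs = 1000) {
  dt <- 1 / fs
  v <- c(0, diff(orientation)) / dt
  alpha <- dt / (tau_s + dt)
  as.numeric(stats::filter(alpha * abs(v), 1 - alpha, method = "recursive"))
}
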