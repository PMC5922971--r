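# Synthetic pointer-alignment trials with ground truth: force ramps to a
# plateau, minimum-jerk rotations with optional sub-movements, per-edge-length
# outcome models, and the apparatus' online shutter rule.

#' Generator configuration for synthetic pointer-alignment trials
#'
#' Defaults encode the published task statistics: rotation onset 0.20 s after
#' touch (between-participant SD 0.02 s, within-participant SD 0.05 s),
#' plateau force 1.64 N (between-participant SD 0.83 N), time to plateau
#' 0.31 s (SD 0.09 s), sub-movements in 44% of trials commencing 0.22 s after
#' rotation onset, six edge lengths x six initial orientations x 18 repeats
#' per participant (648 trials), pointer range +/- 38 deg, and the online
#' end-of-rotation rule (first-order low-pass speed, 10 ms time constant,
#' below 10 deg/s for at least 200 ms).
#'
#' The per-length outcome model is parameterized by the target median
#' absolute alignment error and the probability of rotating in the correct
#' direction; the per-length spread of the alignment-error distribution
#' emulates the published task performance (errors growing from ~3 deg for
#' the full-contact edge to chance-like behavior for the raised dot, with
#' ~15 deg movements of random direction for the dot).  Wrong-direction
#' trials move away from the target by ~15 deg and are clipped at the
#' pointer's +/- 38 deg range.
#'
#' Sensor noise defaults are at the quantization scale of the recording
#' apparatus (16-bit, potentiometer resolution < 0.1 deg); set
#' `noise = FALSE` for noiseless ground-truth recovery tests.
#'
#' @param edge_lengths mm; `Inf` denotes the 44 mm full-contact edge.
#' @param initial_orientations deg relative to the target.
#' @param repeats repeats per (length, orientation) cell per participant.
#' @param participants number of participants.
#' @param p_correct named vector, probability of correct direction per length
#'   (names match `edge_lengths`).
#' @param abs_error_median named vector, target median absolute alignment
#'   error (deg) per length.
#' @param wrong_move_mean,wrong_move_sd magnitude (deg) of wrong-direction /
#'   dot movements.
#' @param pointer_range_deg clip range of the pointer (deg).
#' @param onset_latency_mean,onset_latency_between_sd,onset_latency_within_sd
#'   rotation-onset latency model (s).
#' @param plateau_force_mean,plateau_force_between_sd,plateau_force_within_sd
#'   plateau-force model (N).
#' @param rise_time_mean,rise_time_sd time from touch to force plateau (s).
#' @param submove_prob probability a trial contains a second sub-movement.
#' @param submove_lag_mean,submove_lag_sd lag of the second sub-movement
#'   after rotation onset (s).
#' @param submove_min_amp_deg smallest sub-movement component amplitude
#'   (deg); movements whose split would produce a smaller component stay
#'   single (a component below the 10 deg/s speed floor would be
#'   unobservable by the velocity-peak criterion that defines sub-movements
#'   in the first place).
#' @param move_duration_base,move_duration_per_deg minimum-jerk component
#'   duration model (s, s/deg).
#' @param contact_step_n,contact_step_ms small fast force step at touch (the
#'   impact toe that makes contact instantaneous at the sensor).
#' @param reach_mean,reach_sd time from go signal to touch (s).
#' @param go_time_ms go-signal time within the trace (>= 500 ms baseline).
#' @param force_noise_sd,orientation_noise_sd Gaussian sensor noise SDs
#'   (N, deg).
#' @param noise logical; `FALSE` silences both noise sources.
#' @param online_tau_s,online_speed_threshold,online_hold_ms the apparatus'
#'   shutter rule parameters.
#' @param fs sampling rate (Hz).
#' @param seed root seed for [generate_dataset()].
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    edge_lengths = c(0, 1, 2, 4, 8, Inf),
    initial_orientations = c(-30, -20, -10, 10, 20, 30),
    repeats = 18,
    participants = 10,
    p_correct = c(`0` = 0.50, `1` = 0.55, `2` = 0.75, `4` = 0.92,
                  `8` = 0.97, `Inf` = 0.995),
    abs_error_median = c(`0` = 22, `1` = 19, `2` = 11.1, `4` = 5.9,
                         `8` = 4.0, `Inf` = 2.9),
    wrong_move_mean = 15, wrong_move_sd = 5,
    pointer_range_deg = 38,
    onset_latency_mean = 0.20, onset_latency_between_sd = 0.02,
    onset_latency_within_sd = 0.05,
    plateau_force_mean = 1.64, plateau_force_between_sd = 0.83,
    plateau_force_within_sd = 0.30,
    rise_time_mean = 0.31, rise_time_sd = 0.09,
    submove_prob = 0.44,
    submove_lag_mean = 0.22, submove_lag_sd = 0.02,
    submove_min_amp_deg = 3,
    move_duration_base = 0.25, move_duration_per_deg = 0.004,
    contact_step_n = 0.06, contact_step_ms = 10,
    reach_mean = 0.30, reach_sd = 0.04,
    go_time_ms = 600,
    force_noise_sd = 0.002, orientation_noise_sd = 0.005,
    noise = TRUE,
    online_tau_s = 0.010, online_speed_threshold = 10, online_hold_ms = 200,
    fs = 1000, seed = 1) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  keys <- as.character(edge_lengths)
  if (!all(keys %in% names(p_correct)) ||
      !all(keys %in% names(abs_error_median)))
    stop("generator_config: p_correct and abs_error_median must be named ",
         "for every edge length")
  stopifnot(all(p_correct >= 0 & p_correct <= 1),
            all(abs_error_median > 0), submove_prob >= 0, submove_prob <= 1,
            onset_latency_mean > 0, rise_time_mean > 0, plateau_force_mean > 0,
            go_time_ms >= 500)
  cfg
}

# minimum-jerk position profile on s in [0, 1]
.mj <- function(s) {
  s <- pmin(1, pmax(0, s))
  10 * s^3 - 15 * s^4 + 6 * s^5
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# SD of the correct-trial signed-error normal implied by the target median
# absolute error and p(correct), treating wrong-direction errors as all
# larger than the median.
.signed_error_sd <- function(target_median, p_correct) {
  p <- max(p_correct, 0.51)
  target_median / qnorm(0.5 + 0.25 / p)
}

#' Sample the behavioral outcome of one trial
#'
#' Direction is Bernoulli with the per-length probability of rotating
#' towards the target.  Correct-direction trials (non-zero edge lengths) end
#' at a Normal(0, sd) orientation about the target, truncated to the
#' toward-target side so the direction label is consistent with the realized
#' displacement; the SD is solved from the configured median absolute error.
#' Wrong-direction trials move away from the target by roughly 15 deg.  Dot
#' trials (length 0) produce ~15 deg movements of random direction.  Final
#' orientations are clipped to the pointer's +/- 38 deg range.
#'
#' @param edge_length mm.
#' @param initial_orientation deg.
#' @param cfg a [generator_config()].
#' @return list with `final_orientation` (deg) and `direction_correct`.
#' @export
sample_trial_outcome <- function(edge_length, initial_orientation, cfg) {
  key <- as.character(edge_length)
  p <- cfg$p_correct[[key]]
  theta0 <- initial_orientation
  s0 <- sign(theta0)
  toward <- runif(1) < p
  if (edge_length == 0 || !toward) {
    mag <- .rtrunc_norm(1, cfg$wrong_move_mean, cfg$wrong_move_sd, lo = 0.5)
    final <- if (toward) theta0 - s0 * mag else theta0 + s0 * mag
  } else {
    sd <- .signed_error_sd(cfg$abs_error_median[[key]], p)
    # truncate to the toward-target side of theta0
    repeat {
      final <- rnorm(1, 0, sd)
      if (s0 * (theta0 - final) > 0) break
    }
  }
  final <- pmin(cfg$pointer_range_deg, pmax(-cfg$pointer_range_deg, final))
  list(final_orientation = final,
       direction_correct = s0 * (theta0 - final) > 0)
}

#' Synthesize force and orientation traces for one trial
#'
#' The force rises in a fast 10 ms contact step to a small toe value and then
#' follows a minimum-jerk ramp to the plateau over the rise time; the
#' orientation follows one minimum-jerk displacement from the initial to the
#' final orientation (or, with the configured probability, two overlapping
#' minimum-jerk sub-movements, the second starting ~0.22 s after rotation
#' onset).  The shutter-opening time is determined by emulating the
#' apparatus' online rule on the generated trace (first-order low-passed
#' speed below 10 deg/s for at least 200 ms).  Gaussian sensor noise is added
#' when enabled.
#'
#' Uses the current RNG state; seed externally (or use [generate_dataset()]).
#'
#' @param final_orientation deg, from [sample_trial_outcome()].
#' @param meta list with `edge_length`, `initial_orientation`, and optionally
#'   `participant`, `trial`.
#' @param cfg a [generator_config()].
#' @param participant_params optional list overriding participant-level means:
#'   `latency_mean` (s), `plateau_mean` (N), `rise_mean` (s).
#' @return list with `trial` (a [trial_record()]) and `truth` (one-row tibble
#'   of ground-truth event times and trial facts).
#' @export
synthesize_traces <- function(final_orientation, meta, cfg,
                              participant_params = NULL) {
  pp <- participant_params %||% list(latency_mean = cfg$onset_latency_mean,
                                     plateau_mean = cfg$plateau_force_mean,
                                     rise_mean = cfg$rise_time_mean)
  fs <- cfg$fs
  theta0 <- meta$initial_orientation
  go <- cfg$go_time_ms
  touch <- go + round(1000 * .rtrunc_norm(1, cfg$reach_mean, cfg$reach_sd,
                                          lo = 0.1, hi = 0.6))
  plateau <- .rtrunc_norm(1, pp$plateau_mean, cfg$plateau_force_within_sd,
                          lo = 0.4)
  rise_ms <- round(1000 * .rtrunc_norm(1, pp$rise_mean, cfg$rise_time_sd,
                                       lo = 0.15, hi = 0.60))
  latency_ms <- round(1000 * .rtrunc_norm(1, pp$latency_mean,
                                          cfg$onset_latency_within_sd,
                                          lo = 0.05, hi = 0.45))
  onset <- touch + latency_ms
  D <- final_orientation - theta0
  dur_of <- function(amp) round(1000 * (cfg$move_duration_base +
                                          cfg$move_duration_per_deg * abs(amp)))
  split_draw <- runif(1) < cfg$submove_prob
  f1 <- runif(1, 0.4, 0.7)
  # split only when both components clear the observability floor
  two <- split_draw && min(f1, 1 - f1) * abs(D) >= cfg$submove_min_amp_deg
  if (two) {
    lag_ms <- round(1000 * .rtrunc_norm(1, cfg$submove_lag_mean,
                                        cfg$submove_lag_sd, lo = 0.05))
    comps <- list(list(amp = f1 * D, start = onset, dur = dur_of(f1 * D)),
                  list(amp = (1 - f1) * D, start = onset + lag_ms,
                       dur = dur_of((1 - f1) * D)))
  } else {
    comps <- list(list(amp = D, start = onset, dur = dur_of(D)))
  }
  true_end <- max(vapply(comps, function(c) c$start + c$dur, numeric(1)))
  n <- true_end + 900L  # settle margin: covers shutter hold + post window
  t <- 0:(n - 1L)

  force <- numeric(n)
  step_end <- touch + cfg$contact_step_ms
  i1 <- t >= touch & t < step_end
  force[i1] <- cfg$contact_step_n * .mj((t[i1] - touch) / cfg$contact_step_ms)
  i2 <- t >= step_end
  force[i2] <- cfg$contact_step_n + (plateau - cfg$contact_step_n) *
    .mj((t[i2] - step_end) / rise_ms)

  orientation <- rep(theta0, n)
  for (cmp in comps) {
    idx <- t >= cmp$start
    orientation[idx] <- orientation[idx] +
      cmp$amp * .mj((t[idx] - cmp$start) / cmp$dur)
  }
  # ground-truth movement onset/end: the 5%-of-peak-speed kinematic
  # convention, evaluated on the noiseless trace (a minimum-jerk profile has
  # zero velocity, acceleration and jerk at its formal start, so the formal
  # start is not an observable event)
  v_true <- abs(c(0, diff(orientation))) * cfg$fs
  vmax <- max(v_true)
  onset_truth <- t[which(v_true >= 0.05 * vmax)[1L]]
  # the end threshold references the final component's own peak speed
  # (analytic minimum-jerk peak, 1.875 A / T), so a smaller second
  # sub-movement has its end judged on its own scale, unaffected by the
  # overlap with the preceding component
  last_cmp <- comps[[length(comps)]]
  vmax_end <- 1.875 * abs(last_cmp$amp) / (last_cmp$dur / 1000)
  end_truth <- t[max(which(v_true >= 0.05 * vmax_end))]
  if (isTRUE(cfg$noise)) {
    force <- force + rnorm(n, 0, cfg$force_noise_sd)
    orientation <- orientation + rnorm(n, 0, cfg$orientation_noise_sd)
  }

  shutter <- online_shutter_time(orientation, onset, true_end, cfg)
  keep <- min(n, shutter + 300L)
  meta_full <- c(meta, list(go_time = go, shutter_open_time = shutter))
  trial <- trial_record(t[1:keep], force[1:keep], orientation[1:keep],
                        meta_full)
  truth <- tibble::tibble(
    participant = meta$participant %||% NA_integer_,
    trial = meta$trial %||% NA_integer_,
    edge_length = meta$edge_length,
    initial_orientation = theta0,
    touch_time = touch,
    rotation_onset_time = onset_truth,
    submovement_start = if (two) comps[[2]]$start else NA_real_,
    rotation_end_time = end_truth,
    final_orientation = final_orientation,
    plateau_force = plateau,
    plateau_time = step_end + rise_ms,
    n_submovements = length(comps),
    shutter_open_time = shutter,
    online_abort = online_abort_ground_truth(touch, onset, cfg)
  )
  list(trial = trial, truth = truth)
}

# shutter opens when the online speed has stayed below threshold for the
# configured hold after having exceeded it (or, if the movement never
# registers, a hold period after the true end)
online_shutter_time <- function(orientation, onset, true_end, cfg) {
  spd <- online_speed(orientation, tau_s = cfg$online_tau_s, fs = cfg$fs)
  thr <- cfg$online_speed_threshold
  hold <- cfg$online_hold_ms
  i_on <- which(spd > thr & seq_along(spd) >= onset + 1L)
  if (length(i_on) == 0L) return(as.integer(true_end + hold))
  below <- spd < thr
  below[1:i_on[1L]] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= hold)
  if (length(ok) == 0L) return(as.integer(length(spd)))
  as.integer(starts[ok[1L]] + hold - 1L)  # time in ms = index - 1
}

online_abort_ground_truth <- function(touch, onset, cfg) {
  # the apparatus aborted trials whose rotation started >= 350 ms after touch;
  # approximate the online onset by the true onset (speed crosses 10 deg/s
  # within a few ms of it for minimum-jerk components)
  (onset - touch) >= 350
}

#' Generate a full synthetic dataset
#'
#' The complete factorial design per participant: blocks of constant edge
#' length in the published order (infinite, 8, 4, 2, 1, 0 mm), three blocks
#' per length, each a random interleaving of the six initial orientations
#' repeated `repeats/3` times.  Participant-level means (onset latency,
#' plateau force, rise time) are drawn once per participant; every
#' participant gets an independent child seed derived from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list with `trials` (list of `trial_record`) and `truth` (tibble of
#'   per-trial ground truth).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  set.seed(as.integer(cfg$seed))
  child <- sample.int(.Machine$integer.max - 1L, cfg$participants)
  per_block <- cfg$repeats / 3
  if (per_block != round(per_block))
    stop("generate_dataset: repeats must be divisible by the 3 blocks")
  block_lengths <- sort(cfg$edge_lengths, decreasing = TRUE)
  trials <- list()
  truths <- list()
  k <- 0L
  for (p in seq_len(cfg$participants)) {
    set.seed(child[p])
    pp <- list(
      latency_mean = .rtrunc_norm(1, cfg$onset_latency_mean,
                                  cfg$onset_latency_between_sd, lo = 0.08),
      plateau_mean = .rtrunc_norm(1, cfg$plateau_force_mean,
                                  cfg$plateau_force_between_sd, lo = 0.6),
      rise_mean = .rtrunc_norm(1, cfg$rise_time_mean, 0.03,
                               lo = 0.18, hi = 0.55)
    )
    tnum <- 0L
    for (L in block_lengths) {
      for (b in 1:3) {
        oris <- sample(rep(cfg$initial_orientations, per_block))
        for (ori in oris) {
          tnum <- tnum + 1L; k <- k + 1L
          out <- sample_trial_outcome(L, ori, cfg)
          st <- synthesize_traces(
            out$final_orientation,
            meta = list(edge_length = L, initial_orientation = ori,
                        participant = p, trial = tnum),
            cfg = cfg, participant_params = pp)
          st$truth$direction_correct <- out$direction_correct
          trials[[k]] <- st$trial
          truths[[k]] <- st$truth
        }
      }
    }
  }
  list(trials = trials, truth = dplyr::bind_rows(truths))
}

#' Event-recovery report: pipeline vs ground truth
#'
#' Joins detected events to the generator's ground truth and reports per-event
#' timing bias and RMSE plus the relative plateau-force error, and flags
#' trials where the pipeline failed or its event-ordering invariants did not
#' hold.
#'
#' @param truth ground-truth tibble from [generate_dataset()].
#' @param measures measures tibble from [analyze_dataset()] run on the same
#'   trials.
#' @return list with `per_trial` (tibble of per-trial errors) and `summary`
#'   (tibble: event, bias, rmse, max_abs, n).
#' @export
recovery_report <- function(truth, measures) {
  if (nrow(truth) == 0L)
    return(list(per_trial = tibble::tibble(), summary = tibble::tibble()))
  j <- dplyr::inner_join(
    truth, measures,
    by = c("participant", "trial"), suffix = c("_true", "_det"))
  per_trial <- tibble::tibble(
    participant = j$participant,
    trial = j$trial,
    edge_length = j$edge_length_true,
    touch_error = j$touch_time_det - j$touch_time_true,
    onset_error = j$rotation_onset_time_det - j$rotation_onset_time_true,
    end_error = j$rotation_end_time_det - j$rotation_end_time_true,
    plateau_force_rel_error =
      j$plateau_force_det / j$plateau_force_true - 1,
    analyzed = !is.na(j$abs_error)
  )
  ev <- c("touch_error", "onset_error", "end_error",
          "plateau_force_rel_error")
  summary <- dplyr::bind_rows(lapply(ev, function(e) {
    x <- per_trial[[e]][per_trial$analyzed]
    tibble::tibble(event = e, bias = mean(x), rmse = sqrt(mean(x^2)),
                   max_abs = max(abs(x)), n = length(x))
  }))
  list(per_trial = per_trial, summary = summary)
}

#' Outcome-model statistics implied by a generator configuration
#'
#' Direct Monte-Carlo of [sample_trial_outcome()] over the design (no trace
#' synthesis): the per-length median absolute alignment error, proportion of
#' correct-direction trials, and the implied 75% edge-length threshold.  This
#' is the reference the full pipeline is compared against in calibration
#' tests.
#'
#' @param cfg a [generator_config()].
#' @param n_per_cell Monte-Carlo draws per (length, orientation) cell.
#' @param seed RNG seed.
#' @return tibble: `edge_length`, `median_abs_error`, `p_correct`; attribute
#'   `threshold_75`.
#' @export
implied_measures <- function(cfg = generator_config(), n_per_cell = 2000,
                             seed = 1) {
  set.seed(as.integer(seed))
  rows <- lapply(cfg$edge_lengths, function(L) {
    err <- numeric(0); corr <- logical(0)
    for (ori in cfg$initial_orientations) {
      sim <- replicate(n_per_cell, {
        o <- sample_trial_outcome(L, ori, cfg)
        c(o$final_orientation, o$direction_correct)
      })
      err <- c(err, abs(sim[1, ]))
      corr <- c(corr, as.logical(sim[2, ]))
    }
    tibble::tibble(edge_length = L, median_abs_error = median(err),
                   p_correct = mean(corr))
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$edge_length)
  attr(out, "threshold_75") <- threshold_75(out$edge_length, out$p_correct)
  out
}
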