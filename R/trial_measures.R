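# Per-trial measures and task summary statistics for pointer-alignment
# trials, plus batch analysis over a dataset.

#' Construct a trial record
#'
#' A trial record holds the 1 kHz force and dial-orientation traces of one
#' pointer-alignment trial plus its metadata.  Orientation is the dial
#' orientation in degrees relative to the target (target = 0 deg).
#'
#' @param time time stamps (ms), a uniform 1 ms grid.
#' @param force normal contact force (N) per sample.
#' @param orientation dial orientation (deg) per sample.
#' @param meta list with at least `go_time` (ms), `shutter_open_time` (ms),
#'   `initial_orientation` (deg), `edge_length` (mm); optionally
#'   `participant`, `trial`.
#' @return object of class `trial_record`.
#' @export
trial_record <- function(time, force, orientation, meta) {
  stopifnot(length(time) == length(force),
            length(force) == length(orientation))
  if (length(time) > 1L && any(diff(time) != 1L))
    stop("trial_record: time must be a uniform 1 ms grid")
  req <- c("go_time", "shutter_open_time", "initial_orientation", "edge_length")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stop("trial_record: missing metadata field(s): ", paste(miss, collapse = ", "))
  if (meta$go_time - time[1L] < 500)
    stop("trial_record: at least 500 ms of pre-go baseline required")
  structure(list(time = as.integer(time), force = as.numeric(force),
                 orientation = as.numeric(orientation), meta = meta),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(paste0("<trial_record> %d samples @1 kHz, edge %s mm, initial ",
                     "orientation %g deg\n"),
              length(x$time), format(x$meta$edge_length),
              x$meta$initial_orientation))
  invisible(x)
}

#' Per-trial behavioral measures from a detected event set
#'
#' The alignment error is the dial orientation (relative to the 0 deg target)
#' at the time the rotation ended.  The displacement is the change from the
#' initial orientation referenced to the direction towards the target:
#' positive values indicate rotation towards the target, negative away from
#' it; zero displacement counts as incorrect direction.
#'
#' @param trial a `trial_record`.
#' @param events an `event_set` from [detect_events()].
#' @return one-row tibble: `alignment_error`, `abs_error`,
#'   `displacement_toward_target`, `direction_correct`,
#'   `rotation_onset_latency`, `rotation_duration`, `n_submovements`,
#'   `plateau_force`, `force_at_onset`, `aborted`, plus trial identifiers.
#' @export
trial_measures <- function(trial, events) {
  meta <- trial$meta
  theta0 <- meta$initial_orientation
  thetaf <- trial$orientation[.t2i(trial, events$rotation_end_time)]
  err <- thetaf
  disp <- sign(theta0) * (theta0 - thetaf)
  tibble::tibble(
    participant = meta$participant %||% NA_integer_,
    trial = meta$trial %||% NA_integer_,
    edge_length = meta$edge_length,
    initial_orientation = theta0,
    alignment_error = err,
    abs_error = abs(err),
    displacement_toward_target = disp,
    direction_correct = disp > 0,
    rotation_onset_latency = events$rotation_onset_time - events$touch_time,
    rotation_duration = events$rotation_end_time - events$rotation_onset_time,
    n_submovements = length(events$submovement_boundaries) + 1L,
    touch_time = events$touch_time,
    rotation_onset_time = events$rotation_onset_time,
    rotation_end_time = events$rotation_end_time,
    force_plateau_time = events$force_plateau_time,
    plateau_force = events$plateau_force,
    force_at_onset = events$force_at_onset,
    aborted = events$aborted
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze one trial end to end
#'
#' @param trial a `trial_record`.
#' @param params an [analysis_params()].
#' @return list with `events` (an `event_set`) and `measures` (tibble row).
#' @export
analyze_trial <- function(trial, params = analysis_params()) {
  events <- detect_events(trial, params)
  list(events = events, measures = trial_measures(trial, events))
}

#' Analyze a dataset of trials
#'
#' Applies the full event pipeline to each trial; trials the pipeline cannot
#' segment are reported with `NA` measures and the error message in `note`
#' rather than aborting the batch.
#'
#' @param trials list of `trial_record`s.
#' @param params an [analysis_params()].
#' @return tibble of per-trial measures (one row per trial, `note` column
#'   holds failure messages).
#' @export
analyze_dataset <- function(trials, params = analysis_params()) {
  rows <- lapply(trials, function(tr) {
    out <- tryCatch(analyze_trial(tr, params), error = function(e) e)
    if (inherits(out, "error")) {
      tibble::tibble(
        participant = tr$meta$participant %||% NA_integer_,
        trial = tr$meta$trial %||% NA_integer_,
        edge_length = tr$meta$edge_length,
        initial_orientation = tr$meta$initial_orientation,
        alignment_error = NA_real_, abs_error = NA_real_,
        displacement_toward_target = NA_real_, direction_correct = NA,
        rotation_onset_latency = NA_real_, rotation_duration = NA_real_,
        n_submovements = NA_integer_, touch_time = NA_real_,
        rotation_onset_time = NA_real_, rotation_end_time = NA_real_,
        force_plateau_time = NA_real_, plateau_force = NA_real_,
        force_at_onset = NA_real_, aborted = NA,
        note = conditionMessage(out)
      )
    } else {
      dplyr::mutate(out$measures, note = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Task summary statistics per edge length
#'
#' Aggregation follows the participant-median convention: per-participant
#' medians of the absolute alignment error (and per-participant proportions of
#' correct-direction trials) are computed first, then averaged across
#' participants (mean +/- SEM).  Aborted and unanalyzable trials are excluded.
#' The absolute error can optionally be log-transformed and proportions
#' arcsine-transformed before averaging (the transforms used for parametric
#' statistics); summaries are back-transformed for reporting when enabled.
#'
#' The 75%-correct edge-length threshold (the 2AFC convention) is obtained by
#' linear interpolation of the across-participant mean proportion against
#' finite edge length (mm) between the two lengths bracketing 0.75.  If every
#' finite length is above 0.75 the threshold is left-censored at the smallest
#' length; if 0.75 is never reached the threshold is `NA`.
#'
#' @param measures tibble from [analyze_dataset()] (or ground-truth measures).
#' @param log_abs_error log-transform absolute errors before averaging?
#' @param arcsine_proportions arcsine-sqrt-transform proportions before
#'   averaging?
#' @return list of class `task_summary`: `per_participant` (tibble),
#'   `per_length` (tibble: `edge_length`, `n_participants`, `mean_abs_error`,
#'   `sem_abs_error`, `p_correct`, `sem_p_correct`), `threshold_75` (mm, may
#'   carry attribute `censored`), `n_excluded`.
#' @export
summarize_dataset <- function(measures, log_abs_error = FALSE,
                              arcsine_proportions = FALSE) {
  stopifnot(nrow(measures) > 0)
  ok <- !is.na(measures$abs_error) & !measures$aborted
  excluded <- sum(!ok)
  m <- measures[ok, ]
  if (nrow(m) == 0L) stop("summarize_dataset: no analyzable trials")
  per_participant <- m |>
    dplyr::group_by(.data$participant, .data$edge_length) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      median_abs_error = median(.data$abs_error),
      p_correct = mean(.data$direction_correct),
      .groups = "drop"
    )
  agg_err <- if (log_abs_error) {
    function(x) exp(mean(log(x)))
  } else mean
  agg_p <- if (arcsine_proportions) {
    function(p) sin(mean(asin(sqrt(p))))^2
  } else mean
  per_length <- per_participant |>
    dplyr::group_by(.data$edge_length) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      sem_abs_error = sd(.data$median_abs_error) / sqrt(dplyr::n()),
      sem_p_correct = sd(.data$p_correct) / sqrt(dplyr::n()),
      mean_abs_error = agg_err(.data$median_abs_error),
      p_correct = agg_p(.data$p_correct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$edge_length)
  structure(list(
    per_participant = per_participant,
    per_length = per_length,
    threshold_75 = threshold_75(per_length$edge_length, per_length$p_correct),
    n_excluded = excluded
  ), class = "task_summary")
}

#' 75%-correct edge-length threshold by linear interpolation
#'
#' @param lengths edge lengths (mm); infinite lengths are ignored.
#' @param p_correct proportion correct at each length.
#' @param level threshold level (default 0.75).
#' @return threshold length (mm); left-censored results carry attribute
#'   `censored = "left"`; `NA` if the level is never reached.
#' @export
threshold_75 <- function(lengths, p_correct, level = 0.75) {
  fin <- is.finite(lengths)
  l <- lengths[fin]; p <- p_correct[fin]
  o <- order(l); l <- l[o]; p <- p[o]
  if (length(l) == 0L) return(NA_real_)
  if (p[1] >= level) {
    thr <- l[1]
    attr(thr, "censored") <- "left"
    return(thr)
  }
  above <- which(p >= level)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  l[i - 1L] + (level - p[i - 1L]) / (p[i] - p[i - 1L]) * (l[i] - l[i - 1L])
}

#' @export
print.task_summary <- function(x, ...) {
  cat("<task_summary>\n")
  print(as.data.frame(x$per_length), digits = 3)
  thr <- x$threshold_75
  cat(sprintf("75%% direction threshold: %s mm%s; %d trial(s) excluded\n",
              ifelse(is.na(thr), "NA", format(round(as.numeric(thr), 2))),
              ifelse(is.null(attr(thr, "censored")), "",
                     " (left-censored)"), x$n_excluded))
  invisible(x)
}
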