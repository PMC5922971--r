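# minimal trial + event pair with a given initial and final orientation
fake_pair <- function(theta0, thetaf) {
  n <- 3000
  ori <- c(rep(theta0, 1500), rep(thetaf, 1500))
  trial <- trial_record(0:(n - 1), rep(1, n), ori,
                        meta = list(go_time = 600, shutter_open_time = 2700,
                                    initial_orientation = theta0,
                                    edge_length = 4, participant = 1L,
                                    trial = 1L))
  events <- structure(list(
    touch_time = 1000, force_plateau_time = 1300, plateau_force = 1.6,
    rotation_onset_time = 1200, submovement_boundaries = numeric(0),
    rotation_end_time = 2000, force_at_onset = 1.1, n_speed_peaks = 1L,
    aborted = FALSE), class = "event_set")
  list(trial = trial, events = events)
}

test_that("displacement sign convention references the target direction", {
  m <- with(fake_pair(-30, 0), trial_measures(trial, events))
  expect_equal(m$displacement_toward_target, 30)
  expect_equal(m$alignment_error, 0)
  expect_true(m$direction_correct)

  m <- with(fake_pair(10, 15), trial_measures(trial, events))
  expect_equal(m$displacement_toward_target, -5)
  expect_false(m$direction_correct)

  m <- with(fake_pair(20, 5), trial_measures(trial, events))
  expect_equal(m$displacement_toward_target, 15)
  expect_equal(m$alignment_error, 5)
  expect_true(m$direction_correct)

  # zero displacement counts as incorrect
  m <- with(fake_pair(10, 10), trial_measures(trial, events))
  expect_false(m$direction_correct)

  m <- with(fake_pair(-30, 0), trial_measures(trial, events))
  expect_equal(m$rotation_onset_latency, 200)
  expect_equal(m$rotation_duration, 800)
})

# synthetic measures table with known per-participant structure
fake_measures <- function() {
  rows <- list()
  k <- 0
  for (p in 1:2) {
    for (L in c(1, 2)) {
      errs <- if (p == 1) c(2, 4, 40) else c(10, 12, 14)   # medians: 4 and 12
      corr <- if (L == 1) c(TRUE, TRUE, FALSE) else c(TRUE, TRUE, TRUE)
      for (i in seq_along(errs)) {
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          participant = p, trial = k, edge_length = L,
          initial_orientation = 10, alignment_error = errs[i],
          abs_error = errs[i], displacement_toward_target = 1,
          direction_correct = corr[i], rotation_onset_latency = 200,
          rotation_duration = 500, n_submovements = 1L, touch_time = 1000,
          rotation_onset_time = 1200, rotation_end_time = 1700,
          force_plateau_time = 1310, plateau_force = 1.6,
          force_at_onset = 1.1, aborted = FALSE, note = NA_character_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("aggregation computes participant medians before averaging", {
  s <- summarize_dataset(fake_measures())
  row1 <- s$per_length[s$per_length$edge_length == 1, ]
  # participant medians are 4 and 12: mean of medians is 8, while the
  # pooled median of all six trials would be 11
  expect_equal(row1$mean_abs_error, 8)
  expect_equal(row1$sem_abs_error, sd(c(4, 12)) / sqrt(2))
  expect_equal(row1$p_correct, 2 / 3)
})

test_that("the 75% threshold interpolates linearly between lengths", {
  expect_equal(threshold_75(c(1, 2), c(0.55, 0.78)),
               1 + (0.75 - 0.55) / (0.78 - 0.55))
  # all lengths above criterion: left-censored at the smallest length
  thr <- threshold_75(c(0, 1, 2), c(0.8, 0.9, 0.95))
  expect_equal(as.numeric(thr), 0)
  expect_identical(attr(thr, "censored"), "left")
  # never reaching criterion: undefined
  expect_true(is.na(threshold_75(c(1, 2, 4), c(0.5, 0.6, 0.7))))
  # infinite lengths are excluded from the interpolation axis
  expect_equal(threshold_75(c(1, 2, Inf), c(0.55, 0.78, 1.0)),
               threshold_75(c(1, 2), c(0.55, 0.78)))
})

test_that("a single participant yields their median and no spread", {
  m <- fake_measures()
  s <- summarize_dataset(m[m$participant == 1, ])
  row1 <- s$per_length[s$per_length$edge_length == 1, ]
  expect_equal(row1$mean_abs_error, 4)
  expect_true(is.na(row1$sem_abs_error))
})

test_that("aborted and failed trials are excluded from summaries", {
  m <- fake_measures()
  m$aborted[1] <- TRUE
  m$abs_error[7] <- NA
  s <- summarize_dataset(m)
  expect_equal(s$n_excluded, 2)
})

test_that("optional transforms change the aggregation scale", {
  m <- fake_measures()
  s <- summarize_dataset(m, log_abs_error = TRUE)
  row1 <- s$per_length[s$per_length$edge_length == 1, ]
  expect_equal(row1$mean_abs_error, exp(mean(log(c(4, 12)))))
  s2 <- summarize_dataset(m, arcsine_proportions = TRUE)
  row2 <- s2$per_length[s2$per_length$edge_length == 1, ]
  expect_equal(row2$p_correct, sin(mean(asin(sqrt(c(2/3, 2/3)))))^2)
})

test_that("trial datasets round-trip through CSV/JSON serialization", {
  cfg <- generator_config(participants = 1, repeats = 3, edge_lengths = c(2),
                          p_correct = c(`2` = 0.75),
                          abs_error_median = c(`2` = 11.1), seed = 5)
  ds <- generate_dataset(cfg)
  stem <- file.path(withr::local_tempdir(), "trials")
  write_trials(ds$trials[1:4], stem)
  back <- read_trials(stem)
  expect_equal(length(back), 4L)
  for (i in 1:4) {
    expect_equal(back[[i]]$force, ds$trials[[i]]$force)
    expect_equal(back[[i]]$orientation, ds$trials[[i]]$orientation)
    expect_equal(back[[i]]$meta$shutter_open_time,
                 ds$trials[[i]]$meta$shutter_open_time)
  }
})
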