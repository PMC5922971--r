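small_cfg <- function(seed = 9, ...) {
  generator_config(participants = 1, repeats = 3,
                   edge_lengths = c(0, 2, Inf),
                   p_correct = c(`0` = 0.5, `2` = 0.75, `Inf` = 0.995),
                   abs_error_median = c(`0` = 22, `2` = 11.1, `Inf` = 2.9),
                   seed = seed, ...)
}

test_that("outcome sampling degenerates correctly and respects the clip range", {
  cfg <- generator_config(p_correct = c(`4` = 1), edge_lengths = 4,
                          abs_error_median = c(`4` = 1e-12))
  set.seed(1)
  for (ori in c(-30, 10)) {
    o <- sample_trial_outcome(4, ori, cfg)
    expect_equal(o$final_orientation, 0, tolerance = 1e-9)
    expect_true(o$direction_correct)
  }
  # forced wrong-direction moves clip at the pointer range
  cfg2 <- generator_config(p_correct = c(`4` = 0), edge_lengths = 4,
                           abs_error_median = c(`4` = 10),
                           wrong_move_mean = 50, wrong_move_sd = 1)
  set.seed(2)
  o <- sample_trial_outcome(4, 30, cfg2)
  expect_equal(o$final_orientation, 38)
  expect_false(o$direction_correct)
})

test_that("dot trials move ~15 deg with no net displacement", {
  cfg <- generator_config()
  set.seed(3)
  disp <- move <- numeric(4000)
  for (i in seq_along(disp)) {
    ori <- sample(c(-30, -20, -10, 10, 20, 30), 1)
    o <- sample_trial_outcome(0, ori, cfg)
    move[i] <- abs(o$final_orientation - ori)
    disp[i] <- sign(ori) * (ori - o$final_orientation)
  }
  expect_equal(mean(move), 15, tolerance = 0.7)
  # toward/away in equal measure; the +/-38 deg pointer clip truncates
  # away-moves from the +/-30 deg starts, so "virtually no" net displacement
  # means small relative to the ~15 deg movements, not exactly zero
  expect_lt(abs(mean(disp)), 2)
  expect_equal(mean(disp > 0), 0.5, tolerance = 0.03)
})

test_that("direction labels are consistent with realized displacement", {
  cfg <- generator_config()
  set.seed(4)
  for (i in 1:300) {
    L <- sample(c(0, 1, 2, 4, 8, Inf), 1)
    ori <- sample(c(-30, -20, -10, 10, 20, 30), 1)
    o <- sample_trial_outcome(L, ori, cfg)
    expect_identical(o$direction_correct,
                     sign(ori) * (ori - o$final_orientation) > 0)
  }
})

test_that("trace synthesis honors its ground truth by construction", {
  st <- make_trial(edge_length = 2, initial_orientation = 20, seed = 12)
  tr <- st$trial
  expect_s3_class(tr, "trial_record")
  expect_true(all(diff(tr$time) == 1))
  expect_gte(tr$meta$go_time, 500)
  # orientation starts at the initial orientation and ends at the outcome
  expect_equal(tr$orientation[1], 20)
  expect_equal(tr$orientation[length(tr$orientation)],
               st$truth$final_orientation, tolerance = 1e-9)
  # force rests at zero then plateaus at the drawn plateau force
  expect_equal(tr$force[1], 0)
  expect_equal(tr$force[length(tr$force)], st$truth$plateau_force,
               tolerance = 0.01)
  # the shutter never opens before the rotation has ended
  expect_gte(st$truth$shutter_open_time, st$truth$rotation_end_time)
})

test_that("a single-component movement has exactly one speed peak", {
  cfg <- generator_config(noise = FALSE, submove_prob = 0)
  set.seed(6)
  out <- sample_trial_outcome(8, -30, cfg)
  st <- synthesize_traces(out$final_orientation,
                          list(edge_length = 8, initial_orientation = -30),
                          cfg)
  sp <- abs(rotation_velocity(st$trial))
  expect_equal(nrow(find_speed_peaks(sp, st$trial$time)), 1L)
  expect_equal(st$truth$n_submovements, 1L)
})

test_that("datasets have the full factorial design and are reproducible", {
  cfg <- small_cfg()
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_equal(length(ds1$trials), 3 * 6 * 3)   # lengths x orientations x repeats
  tab <- table(ds1$truth$edge_length)
  expect_true(all(tab == 18))
  tab2 <- table(ds1$truth$initial_orientation, ds1$truth$edge_length)
  expect_true(all(tab2 == 3))
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(ds1$trials[[10]]$orientation, ds2$trials[[10]]$orientation)
  # different seed, different data
  ds3 <- generate_dataset(small_cfg(seed = 10))
  expect_false(identical(ds1$truth$final_orientation,
                         ds3$truth$final_orientation))
})

test_that("the default full design produces 648 trials per participant", {
  cfg <- generator_config(participants = 1, seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds$trials), 648L)
  expect_true(all(table(ds$truth$edge_length) == 108))
})

test_that("recovery report is empty on empty input and sane on data", {
  empty <- recovery_report(tibble::tibble(), tibble::tibble())
  expect_equal(nrow(empty$per_trial), 0L)

  cfg <- small_cfg(noise = FALSE)
  ds <- generate_dataset(cfg)
  meas <- analyze_dataset(ds$trials)
  rep <- recovery_report(ds$truth, meas)
  expect_equal(nrow(rep$per_trial), nrow(ds$truth))
  expect_true(all(c("touch_error", "onset_error", "end_error") %in%
                    names(rep$per_trial)))
  s <- rep$summary
  expect_equal(nrow(s), 4L)
  expect_lt(abs(s$bias[s$event == "touch_error"]), 10)
})

test_that("heavy sensor noise degrades recovery without crashing", {
  cfg <- small_cfg(force_noise_sd = 0.02, orientation_noise_sd = 0.05)
  ds <- generate_dataset(cfg)
  meas <- analyze_dataset(ds$trials)
  rep <- recovery_report(ds$truth, meas)
  expect_true(is.finite(rep$summary$rmse[rep$summary$event == "onset_error"]))
  # most trials should still be analyzable at 10x noise
  expect_gt(mean(rep$per_trial$analyzed), 0.5)
})

test_that("implied outcome statistics match their configuration", {
  cfg <- generator_config()
  imp <- implied_measures(cfg, n_per_cell = 1500, seed = 8)
  # at high p_correct the median |error| tracks the configured target
  expect_equal(imp$median_abs_error[imp$edge_length == Inf], 2.9,
               tolerance = 0.2)
  expect_equal(imp$p_correct[imp$edge_length == 2], 0.75, tolerance = 0.03)
  thr <- attr(imp, "threshold_75")
  expect_equal(as.numeric(thr), 2, tolerance = 0.4)
})
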