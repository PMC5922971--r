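# helper: bare trial record around hand-built traces
bare_trial <- function(force, orientation = NULL, shutter = NULL,
                       theta0 = 0, edge = 2) {
  n <- length(force)
  if (is.null(orientation)) orientation <- rep(theta0, n)
  trial_record(0:(n - 1), force, orientation,
               meta = list(go_time = 600, shutter_open_time = shutter %||% (n - 100),
                           initial_orientation = theta0, edge_length = edge))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("touch detection finds the criterion crossing exactly", {
  # noiseless ramp beginning at t = 1000 ms
  t <- 0:2999
  force <- pmax(0, (t - 999) * 0.05)
  expect_equal(detect_touch(bare_trial(force)), 1000)
})

test_that("a pre-contact noise blip is ignored by the backward search", {
  t <- 0:2999
  force <- pmax(0, (t - 999) * 0.02)
  force[800:810] <- 0.05            # brief blip above the criterion level
  set.seed(10)
  force <- force + rnorm(3000, 0.005, 0.001)   # baseline median ~0.005 N
  touch <- detect_touch(bare_trial(force))
  expect_gte(touch, 999)
  expect_lte(touch, 1002)
})

test_that("no contact is declared when force never reaches 0.2 N", {
  force <- c(rep(0, 1500), rep(0.15, 1500))
  expect_error(detect_touch(bare_trial(force)), "no contact")
})

test_that("force plateau detection recovers a smooth ramp", {
  # minimum-jerk ramp 0 -> 2 N over [1000, 1200], then constant
  t <- 0:2999
  s <- pmin(1, pmax(0, (t - 1000) / 200))
  force <- 2 * (10 * s^3 - 15 * s^4 + 6 * s^5)
  tr <- bare_trial(force)
  pl <- detect_force_plateau(tr, 1000)
  expect_equal(pl$plateau_time, 1200, tolerance = 0.015)  # within 15 ms
  expect_equal(pl$plateau_force, 2, tolerance = 0.01)     # within 1%
  expect_gt(pl$peak_rate, 10)                             # ~18.75 N/s at mid-ramp
})

test_that("flat force gives no force-rate peak", {
  tr <- bare_trial(rep(1, 3000))
  expect_error(detect_force_plateau(tr, 1000), "no force-rate local peak")
})

test_that("an early impact transient does not capture the rate peak", {
  t <- 0:2999
  s <- pmin(1, pmax(0, (t - 1030) / 250))
  force <- 1.6 * (10 * s^3 - 15 * s^4 + 6 * s^5)
  # sharp transient in the first 20 ms after touch at t = 1000
  force <- force + ifelse(t >= 1000 & t < 1020,
                          0.4 * sin(pi * (t - 1000) / 20)^2, 0)
  pl <- detect_force_plateau(bare_trial(force), 1000)
  expect_gt(pl$peak_rate_time, 1050)     # peak from the main ramp, not the spike
  expect_equal(pl$plateau_force, 1.6, tolerance = 0.02)
})

test_that("rotation velocity tracks slope and rests at zero", {
  n <- 3000
  tr <- bare_trial(rep(0, n), orientation = 0.03 * (0:(n - 1)))  # 30 deg/s
  v <- rotation_velocity(tr)
  expect_equal(v[100:(n - 100)], rep(30, n - 199), tolerance = 1e-6)
  tr0 <- bare_trial(rep(0, n), orientation = rep(7, n))
  expect_equal(rotation_velocity(tr0), rep(0, n))
})

test_that("speed peaks are found at bell maxima, in order", {
  mj <- function(t, start, dur) pmin(1, pmax(0, (t - start) / dur))
  t <- 0:2999
  s1 <- mj(t, 1000, 300)
  bell <- function(s) 1.875 / 0.3 * 16 * (s * (1 - s))^2 * 30  # deg/s scale
  one <- bell(s1)
  pk <- find_speed_peaks(one, t)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 1150, tolerance = 5)

  two <- bell(s1) + bell(mj(t, 1700, 300))
  pk2 <- find_speed_peaks(two, t)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$time, c(1150, 1850), tolerance = 5)

  expect_equal(nrow(find_speed_peaks(rep(0, 3000), t)), 0L)
})

test_that("a motionless trial is unsegmentable", {
  tr <- bare_trial(c(rep(0, 1000), rep(1.5, 2000)), orientation = rep(-20, 3000),
                   shutter = 2500)
  expect_error(segment_rotation(tr), "unsegmentable")
})

test_that("segmentation recovers onset and end of clean rotations", {
  for (seed in 1:8) {
    st <- make_trial(edge_length = 8, initial_orientation = -30, seed = seed)
    seg <- segment_rotation(st$trial)
    expect_lte(abs(seg$onset - st$truth$rotation_onset_time), 10)
    expect_lte(abs(seg$end - st$truth$rotation_end_time), 10)
    expect_gte(seg$onset, st$truth$touch_time)
  }
})

test_that("two overlapping sub-movements yield one interior boundary", {
  # force a two-component movement by choosing a seed whose split draw fires
  found <- FALSE
  for (seed in 1:20) {
    st <- make_trial(edge_length = Inf, initial_orientation = 30, seed = seed)
    if (st$truth$n_submovements == 2) {
      found <- TRUE
      seg <- segment_rotation(st$trial)
      expect_equal(length(seg$boundaries), 1L)
      expect_gt(seg$boundaries[1], seg$onset)
      expect_lt(seg$boundaries[1], seg$end)
      break
    }
  }
  expect_true(found)
})

test_that("detected events are ordered on every analyzable trial", {
  cfg <- generator_config(noise = TRUE, participants = 1, repeats = 3,
                          edge_lengths = c(2, 8, Inf),
                          p_correct = c(`2` = 0.75, `8` = 0.97, `Inf` = 0.995),
                          abs_error_median = c(`2` = 11.1, `8` = 4.0, `Inf` = 2.9),
                          seed = 77)
  ds <- generate_dataset(cfg)
  for (tr in ds$trials[seq(1, length(ds$trials), by = 5)]) {
    ev <- tryCatch(detect_events(tr), error = function(e) NULL)
    if (is.null(ev)) next
    expect_lte(ev$touch_time, ev$rotation_onset_time)
    expect_lte(ev$rotation_onset_time, ev$rotation_end_time)
    expect_lte(ev$touch_time, ev$force_plateau_time)
    if (length(ev$submovement_boundaries) > 0) {
      expect_true(all(ev$submovement_boundaries > ev$rotation_onset_time &
                        ev$submovement_boundaries < ev$rotation_end_time))
    }
  }
})

test_that("pipeline outputs are invariant to orientation offsets and force baseline shifts", {
  st <- make_trial(edge_length = 4, initial_orientation = 20, seed = 3)
  tr <- st$trial
  a <- analyze_trial(tr)
  # constant orientation offset: velocity-based events unchanged
  tr2 <- tr
  tr2$orientation <- tr$orientation + 100
  seg <- segment_rotation(tr2)
  expect_equal(seg$onset, a$events$rotation_onset_time)
  expect_equal(seg$end, a$events$rotation_end_time)
  # force baseline shift below the 0.01 N criterion: touch unchanged
  tr3 <- tr
  tr3$force <- tr$force + 0.004
  expect_equal(detect_touch(tr3), a$events$touch_time)
})

test_that("online speed implements the first-order 10 ms smoother", {
  # constant 50 deg/s rotation: the smoothed speed converges geometrically
  # with per-sample factor 1 - 1/11
  ori <- cumsum(rep(0.05, 400))
  s <- online_speed(ori)
  expect_equal(s[400], 50, tolerance = 1e-3)
  resid <- 50 - s[2:100]
  expect_equal(resid[2:99] / resid[1:98], rep(10 / 11, 98), tolerance = 1e-9)
  expect_equal(1 / (2 * pi * 0.010), 15.9, tolerance = 0.01)  # corner freq, Hz
})
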