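test_that("zero-phase Butterworth filtering matches its transfer function", {
  fs <- 60
  # constant signal: steady-state initialization keeps DC gain exactly 1
  const <- matrix(7.3, 200, 2)
  expect_equal(lowpass_filter(const, fs), const)

  # measured attenuation of a sinusoid against the filter's own digital
  # frequency response |H(e^{i w})|^2 (forward-backward squares the
  # magnitude); the analog closed form 1/(1 + (f/8)^10) holds at low
  # frequency but bilinear-transform warping makes it inaccurate near
  # Nyquist, so the 20-Hz check uses the exact digital response.
  bf <- signal::butter(5, 8 / (fs / 2), type = "low")
  digital_gain2 <- function(f) {
    z <- exp(1i * 2 * pi * f / fs)
    Mod(sum(bf$b * z^-(0:5)) / sum(bf$a * z^-(0:5)))^2
  }
  measure <- function(f) {
    t <- seq(0, 10, by = 1 / fs)
    y <- lowpass_filter(cbind(sin(2 * pi * f * t)), fs)
    mid <- y[200:400]
    fit <- lm(mid ~ sin(2 * pi * f * t[200:400]) + cos(2 * pi * f * t[200:400]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_equal(measure(20), digital_gain2(20), tolerance = 0.05)
  expect_equal(measure(1), 1 / (1 + (1 / 8)^10), tolerance = 0.02)
  expect_error(lowpass_filter(matrix(0, 10, 1), fs), "too short")
  expect_error(lowpass_filter(matrix(0, 100, 1), sample_rate = 12), "cutoff")
})

test_that("tangential velocity reproduces analytic speeds", {
  fs <- 60
  n <- 120
  # uniform linear motion, 1 mm/frame
  tr <- matrix(0, n, 12,
               dimnames = list(NULL, as.vector(t(outer(
                 c("elbow", "wrist_ulnar", "wrist_radial", "hand_dorsum"),
                 c("_x", "_y", "_z"), paste0)))))
  tr[, "wrist_ulnar_x"] <- seq_len(n)
  v <- tangential_velocity(tr, fs)
  expect_equal(v$speed, rep(60, n))
  # stationary marker
  tr0 <- tr; tr0[, "wrist_ulnar_x"] <- 5
  expect_equal(tangential_velocity(tr0, fs)$speed, rep(0, n))
})

test_that("the deceleration peak of a minimum-jerk reach sits at tau 0.7887", {
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 2)
  tr <- lowpass_filter(simulate_reach_to_drop(cfg, 0)[[1]], cfg$sample_rate)
  vel <- tangential_velocity(tr, cfg$sample_rate)
  sb <- segment_phases(vel, cfg$sample_rate)
  n_r <- cfg$reach_duration * cfg$sample_rate
  expect_true(sb$ok)
  expect_equal(sb$deceleration_peak_frame, 0.7887 * n_r, tolerance = 2 / (0.7887 * n_r))
  expect_gt(sb$deceleration_peak_frame, sb$peak_velocity_frame)
  expect_equal(sb$reach_end_frame, n_r, tolerance = 2 / n_r)
  expect_lt(sb$reach_end_frame, sb$trial_end_frame)
})

test_that("trials without a deceleration peak are flagged, not dropped", {
  # monotonically increasing speed: a single ramp has no second peak
  sb <- segment_phases(list(speed = seq(0, 100, length.out = 60)), 60)
  expect_false(sb$ok)
  expect_match(sb$reason, "peak")
})

test_that("DTW equals the exhaustive path-enumeration oracle on small series", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1); p <- sample(c(1, 3, 12), 1)
    a <- matrix(rnorm(n * p), n, p); b <- matrix(rnorm(m * p), m, p)
    expect_equal(dtw_distance(a, b), dtw_brute_force(a, b), tolerance = 1e-11)
  }
})

test_that("DTW is symmetric, zero on identity and duration-normalized", {
  set.seed(3)
  a <- matrix(rnorm(90 * 3), 90, 3); b <- matrix(rnorm(80 * 3), 80, 3)
  expect_identical(dtw_distance(a, a), 0)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  # uniform time dilation changes the normalized score by < 10%
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 23)
  trs <- simulate_reach_to_drop(cfg, subject_noise = 2)
  upsample <- function(m) apply(m, 2, function(col)
    stats::approx(seq_along(col), col, n = 2 * length(col))$y)
  d1 <- median_pairwise_dtw(trs)
  d2 <- median_pairwise_dtw(lapply(trs, upsample))
  expect_equal(d2, d1, tolerance = 0.1)
})

test_that("whole-segment cumulative cost dominates its parts", {
  # with common segment boundaries across trials, the unnormalized cost of
  # the whole reach exceeds that of either of its phases
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 31)
  trs <- lapply(simulate_reach_to_drop(cfg, 2), lowpass_filter,
                sample_rate = 60)
  dp <- round(0.7887 * 60); grasp <- 60
  for (j in 2:4) {
    whole <- dtw_distance(trs[[1]][1:grasp, ], trs[[j]][1:grasp, ],
                          normalize = FALSE)
    expect_gte(whole, dtw_distance(trs[[1]][1:dp, ], trs[[j]][1:dp, ],
                                   normalize = FALSE))
    expect_gte(whole, dtw_distance(trs[[1]][dp:grasp, ], trs[[j]][dp:grasp, ],
                                   normalize = FALSE))
  }
})

test_that("motor noise is zero iff trials repeat exactly, and offsets behave", {
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 5)
  trs <- simulate_reach_to_drop(cfg, 0)
  expect_identical(median_pairwise_dtw(trs), 0)
  # common translation of all trials is invisible
  shift <- function(m, dx) m + dx
  expect_identical(median_pairwise_dtw(lapply(trs, shift, dx = 50)), 0)
  # on noisy trials, displacing a single trial raises the median score
  noisy <- simulate_reach_to_drop(cfg, 1)
  base <- median_pairwise_dtw(noisy)
  expect_equal(median_pairwise_dtw(lapply(noisy, shift, dx = 200)), base,
               tolerance = 1e-12)
  one_moved <- noisy; one_moved[[1]] <- shift(one_moved[[1]], 200)
  expect_gt(median_pairwise_dtw(one_moved), base)
})

test_that("subjects with incomplete trial sets are excluded with a reason", {
  cfg <- kinematic_sim_config(seed = 12)
  full <- simulate_reach_to_drop(cfg, 1)
  trials <- list(ok = full, short = full[1:9])
  sc <- motor_noise_scores(trials, segments = "whole")
  expect_false(is.na(sc$whole[sc$subject_id == "ok"]))
  expect_true(is.na(sc$whole[sc$subject_id == "short"]))
  ex <- attr(sc, "exclusions")
  expect_equal(ex$subject_id, "short")
  expect_match(ex$reason, "9 of 10")
})

test_that("trajectory CSV round-trips through the long format", {
  coh <- simulate_kinematic_cohort(n_per_group = c(TD = 1, High = 1, Low = 1),
                                   seed = 3)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectories(coh$trials, path)
  back <- read_trajectories(path)
  expect_identical(names(back), names(coh$trials))
  orig <- coh$trials[[1]][[4]]
  expect_equal(back[[1]][[4]], unclass(orig)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # schema violations are named errors
  bad <- read.csv(path)[, -5]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trajectories(path), "x_mm")
})
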