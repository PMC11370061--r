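#' Minimum-jerk position profile
#'
#' Normalized minimum-jerk displacement s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
#' for tau in `[0, 1]`; its velocity is 30 tau^2 (1 - tau)^2, a single bell
#' peaking at tau = 0.5.
#'
#' @param tau normalized time in `[0, 1]`.
#' @return displacement fraction in `[0, 1]`.
#' @export
min_jerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Configuration for the reach-to-drop trajectory generator
#'
#' Emulates a marker-based recording (four markers: elbow, ulnar wrist,
#' radial wrist, hand dorsum; 60 Hz) of a two-part upper-limb action: a reach
#' from a rest position to a ball on a support, then a transport of the ball
#' to a drop box. Each sub-movement follows a minimum-jerk path of the
#' reference (wrist) point; a 2-frame dwell at the ball makes the inter-peak
#' speed minimum well defined. Trial-to-trial variability is controlled by a
#' per-subject noise amplitude: a Gaussian 3-D displacement field, low-pass
#' filtered at `noise_cutoff` Hz (default 2.5 Hz, the bandwidth of slow
#' execution-to-execution variability; well inside the 8-Hz preprocessing
#' band so the perturbation survives filtering), scaled to `subject_noise` mm RMS per axis, and applied rigidly to
#' all markers. During the feedforward part of the reach (before the nominal
#' deceleration peak at 78.9% of reach time) the amplitude is multiplied by
#' `ff_gain`. A small log-normal duration jitter varies movement time across
#' trials.
#'
#' @param n_trials trials per subject (default 10, the task's trial count).
#' @param sample_rate sampling rate in Hz (default 60).
#' @param reach_duration,drop_duration nominal sub-movement durations (s).
#' @param duration_jitter_sd SD of the log-normal duration jitter.
#' @param noise_cutoff low-pass cutoff applied to the noise field (Hz).
#' @param start,ball,castle 3-D positions (mm) of the rest position, ball
#'   support and drop box.
#' @param marker_offsets 4 x 3 matrix of rigid marker offsets (mm) from the
#'   reference point, rows named elbow, wrist_ulnar, wrist_radial,
#'   hand_dorsum.
#' @param seed integer seed.
#' @return a `kinematic_sim_config` list.
#' @export
kinematic_sim_config <- function(n_trials = 10, sample_rate = 60,
                                 reach_duration = 1.0, drop_duration = 1.0,
                                 duration_jitter_sd = 0.04,
                                 noise_cutoff = 2.5,
                                 start = c(0, 0, 0),
                                 ball = c(200, 0, 50),
                                 castle = c(200, 250, 180),
                                 marker_offsets = rbind(
                                   elbow        = c(-230, 0, 40),
                                   wrist_ulnar  = c(0, -15, 0),
                                   wrist_radial = c(0, 18, 6),
                                   hand_dorsum  = c(55, 10, 15)),
                                 seed = 1L) {
  if (n_trials < 2) stop("n_trials must be at least 2")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (reach_duration <= 0 || drop_duration <= 0) stop("durations must be positive")
  structure(list(n_trials = n_trials, sample_rate = sample_rate,
                 reach_duration = reach_duration, drop_duration = drop_duration,
                 duration_jitter_sd = duration_jitter_sd,
                 noise_cutoff = noise_cutoff,
                 start = start, ball = ball, castle = castle,
                 marker_offsets = marker_offsets, seed = as.integer(seed)),
            class = "kinematic_sim_config")
}

# Normalized time of the first deceleration peak of a minimum-jerk movement:
# the root of 60 - 360 tau + 360 tau^2 after tau = 0.5, i.e. (3 + sqrt(3))/6.
MIN_JERK_DP_TAU <- (3 + sqrt(3)) / 6

#' Simulate reach-to-drop trials for one subject
#'
#' Generates `cfg$n_trials` pre-segmented trials (each spanning movement
#' start to movement end) as frames x 12 matrices with columns
#' `<marker>_{x,y,z}` in mm. With `subject_noise = 0` and
#' `duration_jitter_sd = 0` all trials are identical.
#'
#' @param cfg a [kinematic_sim_config()].
#' @param subject_noise per-axis RMS amplitude (mm) of the smooth trajectory
#'   noise; must be non-negative.
#' @param ff_gain multiplier on the noise amplitude during the feedforward
#'   part of the reach (default 1 = phase-uniform noise).
#' @return list of trial matrices, each with attributes `sample_rate` and
#'   `grasp_frame` (the generator's true reach/drop boundary).
#' @export
simulate_reach_to_drop <- function(cfg, subject_noise, ff_gain = 1) {
  stopifnot(inherits(cfg, "kinematic_sim_config"))
  if (subject_noise < 0) stop("subject_noise must be non-negative")
  set.seed(cfg$seed)
  markers <- rownames(cfg$marker_offsets)
  lapply(seq_len(cfg$n_trials), function(tr) {
    jit <- function() if (cfg$duration_jitter_sd > 0)
      exp(rnorm(1, 0, cfg$duration_jitter_sd)) else 1
    n_r <- max(10L, round(cfg$reach_duration * jit() * cfg$sample_rate))
    n_d <- max(10L, round(cfg$drop_duration * jit() * cfg$sample_rate))
    tau_r <- seq(0, 1, length.out = n_r)
    tau_d <- seq(0, 1, length.out = n_d)
    reach <- outer(min_jerk_pos(tau_r), cfg$ball - cfg$start) +
      matrix(cfg$start, n_r, 3, byrow = TRUE)
    dwell <- matrix(cfg$ball, 2, 3, byrow = TRUE)
    drop <- outer(min_jerk_pos(tau_d), cfg$castle - cfg$ball) +
      matrix(cfg$ball, n_d, 3, byrow = TRUE)
    ref <- rbind(reach, dwell, drop)
    n <- nrow(ref)

    if (subject_noise > 0) {
      raw <- matrix(rnorm(n * 3), n, 3)
      sm <- lowpass_filter(raw, cfg$sample_rate, cutoff = cfg$noise_cutoff)
      sm <- sweep(sm, 2, apply(sm, 2, sd), "/") * subject_noise
      if (ff_gain != 1) {
        dp_frame <- round(MIN_JERK_DP_TAU * n_r)
        env <- c(rep(ff_gain, dp_frame), rep(1, n - dp_frame))
        env <- as.numeric(stats::filter(env, rep(1 / 5, 5), sides = 2))
        env[1:2] <- env[3]; env[(n - 1):n] <- env[n - 2]
        sm <- sm * env
      }
      ref <- ref + sm
    }

    out <- do.call(cbind, lapply(markers, function(m)
      sweep(ref, 2, cfg$marker_offsets[m, ], "+")))
    colnames(out) <- as.vector(t(outer(markers, c("_x", "_y", "_z"), paste0)))
    attr(out, "sample_rate") <- cfg$sample_rate
    attr(out, "grasp_frame") <- n_r + 1L
    attr(out, "trial") <- tr
    out
  })
}

#' Simulate a kinematic cohort of TD, High- and Low-subtype subjects
#'
#' Draws a per-subject noise amplitude from a truncated Gaussian around the
#' group mean and generates the full trial set per subject. Defaults encode
#' the study conditions the analysis targets: equal baseline noise in TD and
#' the "High" subtype, elevated noise in the "Low" subtype, with the "Low"
#' elevation further amplified during the feedforward reach phase.
#'
#' @param n_per_group named subject counts for `TD`, `High`, `Low`.
#' @param noise_mean named mean noise amplitude (mm) per group.
#' @param noise_sd between-subject SD of the noise amplitude (mm).
#' @param ff_gain named feedforward noise multiplier per group.
#' @param cfg trial-level configuration from [kinematic_sim_config()].
#' @param seed integer seed.
#' @return list with `subjects` (data.frame: subject_id, group, sigma) and
#'   `trials` (named list of per-subject trial lists).
#' @export
simulate_kinematic_cohort <- function(n_per_group = c(TD = 79, High = 37, Low = 33),
                                      noise_mean = c(TD = 1.5, High = 1.5, Low = 1.75),
                                      noise_sd = 0.45,
                                      ff_gain = c(TD = 1, High = 1, Low = 1.2),
                                      cfg = kinematic_sim_config(),
                                      seed = 1L) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  sigma <- pmax(0.2, rnorm(n, noise_mean[groups], noise_sd))
  ids <- sprintf("K%04d", seq_len(n))
  subjects <- data.frame(subject_id = ids, group = groups, sigma = sigma,
                         stringsAsFactors = FALSE)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  trials <- lapply(seq_len(n), function(i) {
    ci <- cfg; ci$seed <- trial_seeds[i]
    simulate_reach_to_drop(ci, subject_noise = sigma[i],
                           ff_gain = ff_gain[groups[i]])
  })
  names(trials) <- ids
  list(subjects = subjects, trials = trials)
}
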