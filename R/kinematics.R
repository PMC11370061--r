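#' Zero-phase Butterworth low-pass filtering of a trajectory
#'
#' Filters every coordinate column with a Butterworth low-pass applied
#' forward and backward (zero phase), as is standard for marker-based motion
#' capture before differentiation. Initial conditions are set to the filter's
#' steady state for a step at the first (resp. last) sample, so a constant
#' signal passes through exactly unchanged and edge transients from the large
#' DC component of position data are avoided.
#'
#' @param traj numeric matrix, frames x coordinates (mm).
#' @param sample_rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz (default 8).
#' @param order filter order (default 5).
#' @return filtered matrix of the same dimension.
#' @export
lowpass_filter <- function(traj, sample_rate, cutoff = 8, order = 5) {
  traj <- as.matrix(traj)
  if (sample_rate <= 2 * cutoff)
    stop("sample_rate must exceed twice the cutoff frequency")
  if (nrow(traj) < 3 * order)
    stop(sprintf("trial too short to filter: %d frames < %d", nrow(traj), 3 * order))
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  out <- filtfilt_cpp(bf$b, bf$a, traj, lfilter_zi(bf$b, bf$a))
  dimnames(out) <- dimnames(traj)
  out
}

# Steady-state filter state for a unit-step input (direct form II transposed):
# solve (I - A) z = B with A the transposed companion matrix of `a`.
lfilter_zi <- function(b, a) {
  nf <- length(a)
  stopifnot(length(b) == nf, abs(a[1] - 1) < 1e-12)
  N <- nf - 1L
  comp <- matrix(0, N, N)
  comp[1, ] <- -a[-1]
  if (N > 1) comp[cbind(2:N, 1:(N - 1))] <- 1
  solve(diag(N) - t(comp), b[-1] - a[-1] * b[1])
}

#' Tangential velocity and acceleration of one marker
#'
#' Computes the per-frame tangential speed of a marker as the Euclidean norm
#' of the central-difference derivative of its 3-D position (one-sided
#' differences at the endpoints), and the scalar acceleration as the central
#' difference of the speed.
#'
#' @param traj frames x 12 trajectory matrix with columns named
#'   `<marker>_x/_y/_z`.
#' @param sample_rate sampling rate (Hz).
#' @param marker marker name; the ulnar (medial) wrist marker by default.
#' @return list with `speed` (mm/s) and `accel` (mm/s^2), each of trajectory
#'   length.
#' @export
tangential_velocity <- function(traj, sample_rate, marker = "wrist_ulnar") {
  cols <- paste0(marker, c("_x", "_y", "_z"))
  assert_columns(as.data.frame(traj[1:2, , drop = FALSE]), cols, "trajectory")
  pos <- traj[, cols, drop = FALSE]
  d <- apply(pos, 2, central_diff) * sample_rate
  speed <- sqrt(rowSums(d^2))
  accel <- central_diff(speed) * sample_rate
  list(speed = speed, accel = accel)
}

central_diff <- function(x) {
  n <- length(x)
  if (n < 3) stop("series too short to differentiate")
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

# Local maxima of `x` with prominence >= min_prom. Prominence of a peak is
# its height above the higher of the two deepest valleys separating it from
# larger (or boundary) terrain on each side.
local_peaks <- function(x, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) == 0 || min_prom <= 0) return(idx)
  keep <- vapply(idx, function(i) {
    left <- x[1:i]; right <- x[i:n]
    higher_l <- which(left > x[i]); higher_r <- which(right > x[i])
    base_l <- min(left[if (length(higher_l)) (max(higher_l)):i else 1:i])
    base_r <- min(right[if (length(higher_r)) 1:(min(higher_r)) else seq_along(right)])
    (x[i] - max(base_l, base_r)) >= min_prom
  }, logical(1))
  idx[keep]
}

#' Segment a reach-to-drop trial into phases
#'
#' Finds (1) the end of the reach (grasp) as the global speed minimum between
#' the two principal speed peaks of the trial (the two largest local maxima
#' separated by at least `min_peak_sep` seconds), and (2) the deceleration
#' peak (DP) as the first local maximum of deceleration (minus the velocity
#' slope) strictly after the reach's maximum-speed frame, requiring a
#' prominence of at least `prom_frac` of the maximum deceleration. The reach
#' before DP is the feedforward phase; DP to grasp is the feedback phase.
#'
#' Trials where no qualifying deceleration peak exists are flagged
#' unsegmentable (with a reason) rather than dropped silently.
#'
#' @param vel a [tangential_velocity()] result.
#' @param sample_rate sampling rate (Hz).
#' @param min_peak_sep minimum separation of the two principal peaks (s).
#' @param prom_frac prominence threshold as a fraction of max deceleration.
#' @return list with `ok`, `reason`, `reach_end_frame`,
#'   `deceleration_peak_frame`, `trial_end_frame`, `peak_velocity_frame`.
#' @export
segment_phases <- function(vel, sample_rate, min_peak_sep = 0.25,
                           prom_frac = 0.05) {
  speed <- vel$speed
  n <- length(speed)
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                reach_end_frame = NA_integer_,
                                deceleration_peak_frame = NA_integer_,
                                trial_end_frame = n,
                                peak_velocity_frame = NA_integer_)
  pk <- local_peaks(speed, min_prom = 0.02 * max(speed))
  if (length(pk) < 2) return(fail("fewer than two principal speed peaks"))
  # two largest peaks separated by >= min_peak_sep
  ord <- pk[order(speed[pk], decreasing = TRUE)]
  p1 <- ord[1]
  p2 <- ord[which(abs(ord - p1) >= min_peak_sep * sample_rate)[1]]
  if (is.na(p2)) return(fail("principal speed peaks too close"))
  lo <- min(p1, p2); hi <- max(p1, p2)
  reach_end <- lo + which.min(speed[lo:hi]) - 1L

  reach_speed <- speed[1:reach_end]
  vmax <- which.max(reach_speed)
  decel <- -central_diff(reach_speed) * sample_rate
  dp_cand <- local_peaks(decel, min_prom = prom_frac * max(decel))
  dp_cand <- dp_cand[dp_cand > vmax]
  if (length(dp_cand) == 0) return(fail("no deceleration peak after max velocity"))
  dp <- dp_cand[1]
  if (!(dp > 0 && dp < reach_end)) return(fail("deceleration peak outside reach"))
  list(ok = TRUE, reason = NA_character_,
       reach_end_frame = reach_end, deceleration_peak_frame = dp,
       trial_end_frame = n, peak_velocity_frame = vmax)
}

#' Normalized multivariate DTW distance between two trajectory segments
#'
#' Dynamic time warping with per-frame local cost equal to the Euclidean
#' distance in coordinate space (12-D for four markers), the symmetric2 step
#' pattern (diagonal steps weighted twice), and both endpoints constrained to
#' match. The cumulative cost is divided by N + M (the symmetric2
#' normalization), which removes the bias of overall movement duration.
#'
#' @param a,b numeric matrices (frames x coordinates) with equal column count.
#' @param normalize return the duration-normalized distance (default) or the
#'   raw cumulative cost.
#' @return a single non-negative number.
#' @export
dtw_distance <- function(a, b, normalize = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty segment")
  res <- dtw_sym2_cpp(a, b)
  if (normalize) res$normalized else res$distance
}
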