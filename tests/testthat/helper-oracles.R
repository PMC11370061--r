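# Independent oracles and small fixture builders, used to pin the package's
# implementations. These deliberately use naive exhaustive algorithms.

# Exhaustive enumeration of all monotone, endpoint-matched warping paths with
# symmetric2 step weights (diagonal counts the local cost twice), normalized
# by N + M. Branch-and-bound pruning keeps it tractable for <= 6 frames.
dtw_brute_force <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  d <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  recurse <- function(i, j, cost) {
    if (cost >= best) return(invisible(NULL))
    if (i == n && j == m) { best <<- cost; return(invisible(NULL)) }
    if (i < n && j < m) recurse(i + 1, j + 1, cost + 2 * d[i + 1, j + 1])
    if (i < n) recurse(i + 1, j, cost + d[i + 1, j])
    if (j < m) recurse(i, j + 1, cost + d[i, j + 1])
  }
  recurse(1L, 1L, d[1, 1])
  best / (n + m)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i)
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))),
    recursive = FALSE)
}

# Minimum disagreement over all bijections from candidate labels onto
# reference labels (padded when the label sets differ in size).
align_brute_force <- function(reference, candidate) {
  ref_lev <- sort(unique(reference))
  cand_lev <- sort(unique(candidate))
  k <- max(length(ref_lev), length(cand_lev))
  ref_pad <- c(ref_lev, paste0(".pad", seq_len(k - length(ref_lev))))
  cand_pad <- c(cand_lev, paste0(".pad", seq_len(k - length(cand_lev))))
  errs <- vapply(all_permutations(seq_len(k)), function(p) {
    mapped <- ref_pad[p][match(candidate, cand_pad)]
    mean(mapped != reference)
  }, numeric(1))
  min(errs)
}

# Single-Gaussian (null) motor-profile table with stratification covariates.
make_null_table <- function(n = 156, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("N%04d", seq_len(n)),
             diagnosis = "autism",
             md = rnorm(n, 10, 3), ac = rnorm(n, 10, 3), bl = rnorm(n, 10, 3),
             total = NA_real_,
             study_id = sample(c("A", "B", "C"), n, TRUE),
             sex = sample(c("M", "F"), n, TRUE),
             module = sample(1:3, n, TRUE),
             stringsAsFactors = FALSE)
}

# Well-separated spherical blobs in the three subscale features.
make_blob_table <- function(n_per_blob = 50, centers, sd = 1, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b)
    cbind(md = rnorm(n_per_blob, centers[b, 1], sd),
          ac = rnorm(n_per_blob, centers[b, 2], sd),
          bl = rnorm(n_per_blob, centers[b, 3], sd))))
  n <- nrow(rows)
  data.frame(subject_id = sprintf("B%04d", seq_len(n)), diagnosis = "autism",
             rows, total = rowMeans(rows),
             study_id = sample(c("A", "B"), n, TRUE),
             sex = sample(c("M", "F"), n, TRUE),
             module = sample(1:3, n, TRUE),
             blob = rep(seq_len(nrow(centers)), each = n_per_blob),
             stringsAsFactors = FALSE)
}

# Long-format two-group, two-phase noise table with a subject random
# intercept and phase-specific group gaps given as Cohen's d on the total
# (between + within) SD. The variance partition mirrors the kinematic
# scores, where stable between-subject differences dominate the residual.
sim_phase_long <- function(gap_ff = 0, gap_fb = 0, n = 35,
                           subj_sd = 1.2, e_sd = 0.8) {
  subj <- sprintf("s%03d", seq_len(2 * n))
  grp <- rep(c("High", "Low"), each = n)
  intercept <- rnorm(2 * n, 0, subj_sd)
  tot <- sqrt(subj_sd^2 + e_sd^2)
  data.frame(
    subject_id = rep(subj, 2), group = rep(grp, 2),
    phase = rep(c("feedforward", "feedback"), each = 2 * n),
    value = c(intercept + rnorm(2 * n, 0, e_sd) +
                ifelse(grp == "Low", gap_ff * tot, 0),
              intercept + rnorm(2 * n, 0, e_sd) +
                ifelse(grp == "Low", gap_fb * tot, 0)))
}

# Two-subtype synthetic autism cohort with the study's effect structure and
# batch offsets removed, ready for clustering.
make_subtyped_corrected <- function(seed) {
  p <- simulate_profiles(profile_sim_config(seed = seed))
  suppressWarnings(batch_correct(merge_and_filter(p)))
}
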