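#' Per-subject motor noise from repeated trials
#'
#' Motor noise is operationalized as the median normalized multivariate DTW
#' distance between all unique pairs of a subject's repeated trials (the
#' off-diagonal of the 10 x 10 trial-similarity matrix). Higher values mean
#' less repeatable movement. The score is computed on the whole movement or
#' on a phase segment:
#' \describe{
#'   \item{whole}{movement start to movement end (reach + drop).}
#'   \item{reach_feedforward}{reach onset to the first deceleration peak
#'     after peak velocity.}
#'   \item{reach_feedback}{deceleration peak to the grasp.}
#'   \item{drop}{grasp to movement end.}
#' }
#'
#' Trials are low-pass filtered before segmentation and distance computation.
#' Subjects lacking the full trial count are excluded (not imputed), and
#' subjects with any unsegmentable trial are excluded from phase scores only;
#' every exclusion is recorded in the `exclusions` attribute.
#'
#' @param trials named list (by subject) of lists of trial matrices, as from
#'   [simulate_kinematic_cohort()]`$trials`.
#' @param segments character vector of segments to score.
#' @param n_trials_required required trial count per subject (default 10).
#' @param cutoff,order Butterworth low-pass parameters.
#' @param marker marker used for velocity-based segmentation.
#' @return data.frame (`subject_id`, one column per segment) with an
#'   `exclusions` data.frame attribute (`subject_id`, `segment`, `reason`).
#' @export
motor_noise_scores <- function(trials,
                               segments = c("whole", "reach_feedforward",
                                            "reach_feedback", "drop"),
                               n_trials_required = 10,
                               cutoff = 8, order = 5,
                               marker = "wrist_ulnar") {
  segments <- match.arg(segments, several.ok = TRUE)
  subjects <- names(trials)
  excl <- list()
  note_excl <- function(id, seg, reason)
    excl[[length(excl) + 1]] <<- data.frame(subject_id = id, segment = seg,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
  need_phase <- any(segments != "whole")

  rows <- lapply(subjects, function(id) {
    trs <- trials[[id]]
    out <- as.list(setNames(rep(NA_real_, length(segments)), segments))
    if (length(trs) < n_trials_required) {
      for (s in segments) note_excl(id, s, sprintf(
        "only %d of %d trials completed", length(trs), n_trials_required))
      return(out)
    }
    fs <- attr(trs[[1]], "sample_rate")
    filt <- lapply(trs, lowpass_filter, sample_rate = fs,
                   cutoff = cutoff, order = order)
    segb <- NULL
    if (need_phase) {
      segb <- lapply(filt, function(tr)
        segment_phases(tangential_velocity(tr, fs, marker), fs))
      bad <- which(!vapply(segb, `[[`, logical(1), "ok"))
      if (length(bad) > 0) {
        for (s in setdiff(segments, "whole")) note_excl(id, s, sprintf(
          "unsegmentable trial(s) %s: %s", paste(bad, collapse = ","),
          segb[[bad[1]]]$reason))
        segb <- NULL
      }
    }
    cut_segment <- function(tr, sb, seg) {
      switch(seg,
             whole = tr,
             reach_feedforward = tr[1:sb$deceleration_peak_frame, , drop = FALSE],
             reach_feedback = tr[sb$deceleration_peak_frame:sb$reach_end_frame, ,
                                 drop = FALSE],
             drop = tr[sb$reach_end_frame:nrow(tr), , drop = FALSE])
    }
    for (s in segments) {
      if (s != "whole" && is.null(segb)) next
      segs <- lapply(seq_along(filt), function(i)
        cut_segment(filt[[i]], segb[[i]], s))
      out[[s]] <- median_pairwise_dtw(segs)
    }
    out
  })

  res <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (s in segments) res[[s]] <- vapply(rows, function(r) r[[s]], numeric(1))
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), segment = character(0),
               reason = character(0))
  res
}

#' Median pairwise normalized DTW distance of a trial set
#'
#' @param segs list of segment matrices (same column count).
#' @return median of all unique pairwise normalized DTW distances.
#' @export
median_pairwise_dtw <- function(segs) {
  if (length(segs) < 2) stop("need at least two trials")
  median(dtw_pairwise_cpp(lapply(segs, function(s) as.matrix(unclass(s)))))
}
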