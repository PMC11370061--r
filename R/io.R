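#' Write / read tabular pipeline artifacts
#'
#' Profiles and phenotype tables round-trip through plain CSV. Trajectories
#' use a long-format CSV (`subject_id`, `trial`, `frame`, `marker`, `x_mm`,
#' `y_mm`, `z_mm`) with a JSON sidecar (`<path>.json`) recording the sample
#' rate, so a trajectory file is self-describing.
#'
#' @param trials named list (by subject) of per-subject trial lists, as from
#'   [simulate_kinematic_cohort()]`$trials`.
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trials, path) {
  markers <- c("elbow", "wrist_ulnar", "wrist_radial", "hand_dorsum")
  rows <- lapply(names(trials), function(id) {
    do.call(rbind, lapply(trials[[id]], function(tr) {
      n <- nrow(tr)
      do.call(rbind, lapply(markers, function(m) {
        data.frame(subject_id = id, trial = attr(tr, "trial"),
                   frame = seq_len(n), marker = m,
                   x_mm = tr[, paste0(m, "_x")],
                   y_mm = tr[, paste0(m, "_y")],
                   z_mm = tr[, paste0(m, "_z")],
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  long <- do.call(rbind, rows)
  write.csv(long, path, row.names = FALSE)
  fs <- attr(trials[[1]][[1]], "sample_rate")
  jsonlite::write_json(list(sample_rate = fs, n_subjects = length(trials),
                            markers = markers),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param path input CSV path (sidecar `<path>.json` must exist).
#' @return named list (by subject) of per-subject lists of frames x 12 trial
#'   matrices with `sample_rate`, `trial` attributes.
#' @export
read_trajectories <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "trial", "frame", "marker", "x_mm", "y_mm", "z_mm")
  assert_columns(long, required, "trajectory CSV")
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing trajectory sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  markers <- meta$markers
  out <- lapply(split(long, long$subject_id), function(sub) {
    tl <- lapply(split(sub, sub$trial), function(trd) {
      trd <- trd[order(trd$frame), ]
      mats <- lapply(markers, function(m) {
        md <- trd[trd$marker == m, c("x_mm", "y_mm", "z_mm")]
        as.matrix(md)
      })
      tr <- do.call(cbind, mats)
      colnames(tr) <- as.vector(t(outer(markers, c("_x", "_y", "_z"), paste0)))
      attr(tr, "sample_rate") <- meta$sample_rate
      attr(tr, "trial") <- trd$trial[1]
      tr
    })
    tl[order(as.integer(names(tl)))]
  })
  out[unique(long$subject_id)]
}
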