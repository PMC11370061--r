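#' Merge motor-profile tables and apply cohort filters
#'
#' Concatenates column-compatible tables, then (1) drops duplicated
#' `subject_id` rows keeping the first occurrence, (2) drops rows outside the
#' age range, and (3) drops rows missing more than one of the three MABC2
#' subscales. Every exclusion is logged with its reason in the `exclusions`
#' attribute.
#'
#' @param tables a data.frame or list of data.frames with the motor-profile
#'   columns (`subject_id`, `diagnosis`, `study_id`, `module`, `sex`, `age`,
#'   `md`, `ac`, `bl`, `total`).
#' @param age_range inclusive age bounds in years (default 3-16).
#' @return the filtered table with an `exclusions` attribute.
#' @export
merge_and_filter <- function(tables, age_range = c(3, 16)) {
  if (is.data.frame(tables)) tables <- list(tables)
  core <- c("subject_id", "diagnosis", "study_id", "module", "sex", "age",
            "md", "ac", "bl", "total")
  for (t in tables) assert_columns(t, core, "profile table")
  tab <- do.call(rbind, lapply(tables, function(t)
    t[, union(core, intersect(names(t), "true_subtype")), drop = FALSE]))

  excl <- data.frame(subject_id = character(0), reason = character(0))
  drop_rows <- function(mask, reason) {
    if (any(mask)) {
      excl <<- rbind(excl, data.frame(subject_id = tab$subject_id[mask],
                                      reason = reason))
      tab <<- tab[!mask, , drop = FALSE]
    }
  }
  drop_rows(duplicated(tab$subject_id), "duplicate subject_id")
  drop_rows(is.na(tab$age) | tab$age < age_range[1] | tab$age > age_range[2],
            sprintf("age outside [%g, %g]", age_range[1], age_range[2]))
  n_missing <- rowSums(is.na(tab[, c("md", "ac", "bl")]))
  drop_rows(n_missing >= 2, "more than one MABC2 subscale missing")

  if (nrow(tab) == 0L) stop("empty cohort after filtering")
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- excl
  tab
}

#' Remove nuisance (batch) variance from MABC2 scores
#'
#' Fits, for each score (md, ac, bl, total), an ordinary least squares model
#' with dummy-coded originating study ID, MABC2 module, sex and diagnosis as
#' predictors, then subtracts only the fitted contributions of study ID,
#' module and sex. Diagnosis-related variance is deliberately retained. The
#' reference level of each factor is its most frequent category (projection
#' of the non-reference offsets is invariant to this choice up to a constant
#' absorbed into the intercept). Factors with fewer than two observed levels
#' are dropped with a warning; a rank-deficient (confounded) design is an
#' error naming the aliased terms. Rows with a missing score are excluded
#' from that score's fit and stay missing afterwards.
#'
#' @param table a motor-profile table (see [merge_and_filter()]).
#' @param scores score columns to correct.
#' @return the table with corrected scores, of class `corrected_profiles`,
#'   carrying a `correction_betas` attribute (per-score named coefficient
#'   vectors of the removed nuisance terms).
#' @export
batch_correct <- function(table, scores = c("md", "ac", "bl", "total")) {
  assert_columns(table, c(scores, "study_id", "module", "sex", "diagnosis"),
                 "profile table")
  nuisance <- c("study_id", "module", "sex")
  dat <- table
  rownames(dat) <- NULL
  for (f in c(nuisance, "diagnosis")) {
    lev <- names(sort(table(as.character(dat[[f]])), decreasing = TRUE))
    dat[[f]] <- factor(as.character(dat[[f]]), levels = lev)
  }
  use <- c(nuisance[vapply(nuisance, function(f) nlevels(dat[[f]]) >= 2,
                           logical(1))])
  dropped <- setdiff(nuisance, use)
  if (length(dropped) > 0)
    warning("factor(s) with a single level dropped from the correction model: ",
            paste(dropped, collapse = ", "))
  rhs <- paste(c(use, if (nlevels(dat$diagnosis) >= 2) "diagnosis"),
               collapse = " + ")
  if (rhs == "") stop("no usable predictors for batch correction")

  betas <- list()
  out <- table
  for (sc in scores) {
    fml <- stats::as.formula(paste(sc, "~", rhs))
    fit <- lm(fml, data = dat, na.action = na.exclude)
    cf <- coef(fit)
    if (anyNA(cf))
      stop("rank-deficient correction design; aliased term(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    mm <- model.matrix(fit)
    asn <- attr(mm, "assign")
    terms_lab <- attr(stats::terms(fit), "term.labels")
    col_term <- c("(Intercept)", terms_lab)[asn + 1]
    nuis_cols <- which(col_term %in% use)
    adj <- as.numeric(mm[, nuis_cols, drop = FALSE] %*% cf[nuis_cols])
    # expand back to all rows (na.exclude kept the row order of complete rows)
    full_adj <- rep(NA_real_, nrow(dat))
    full_adj[as.integer(rownames(mm))] <- adj
    corrected <- dat[[sc]] - full_adj
    corrected[is.na(dat[[sc]])] <- NA_real_
    out[[sc]] <- corrected
    betas[[sc]] <- cf[nuis_cols]
  }
  attr(out, "correction_betas") <- betas
  class(out) <- unique(c("corrected_profiles", class(table)))
  out
}
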