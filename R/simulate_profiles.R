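#' Configuration for the motor-profile generator
#'
#' Describes a multi-site cohort of autistic, typically-developing (TD) and
#' Developmental Coordination Disorder (DCD) children with MABC2 standardized
#' scores on the Manual Dexterity (md), Aiming & Catching (ac) and Balance
#' (bl) subscales. The autism group is a two-component mixture of a hidden
#' "High" and "Low" motor subtype, separated by `subtype_effect_d` pooled-SD
#' units per subscale (large on md/bl, small on ac by default). Additive
#' batch offsets by originating study, MABC2 age-band module and sex emulate
#' multi-site acquisition.
#'
#' Scores live on the MABC2 standard-score scale (TD reference mean 10,
#' SD 3 per subscale); the total is kept on the same scale (mean of the three
#' subscales) so that only relative structure matters.
#'
#' @param n_per_group named counts for `autism`, `td`, `dcd` subjects.
#' @param subtype_fraction proportion of autistic subjects in the "Low"
#'   subtype, in `[0, 1]`.
#' @param subtype_effect_d named separation (pooled-SD units) between hidden
#'   subtypes for `md`, `ac`, `bl`.
#' @param group_means named list of subscale means for `td`, `dcd` and the
#'   autism `high` subtype ("Low" means are derived from `subtype_effect_d`).
#' @param score_sd within-group SD of every subscale score.
#' @param batch_offsets named list of additive score offsets per level of
#'   `study_id`, `module` and `sex`.
#' @param study_levels,study_prob originating-study labels and their
#'   sampling probabilities.
#' @param female_prob named probability of female sex per diagnosis.
#' @param age_range age range (years); MABC2 modules are assigned from age
#'   (module 1: 3-6 y, module 2: 7-10 y, module 3: 11-16 y).
#' @param seed integer seed.
#' @return a `profile_sim_config` list.
#' @export
profile_sim_config <- function(n_per_group = c(autism = 156, td = 149, dcd = 23),
                               subtype_fraction = 0.44,
                               subtype_effect_d = c(md = 2.0, ac = 0.45, bl = 2.0),
                               group_means = list(
                                 td   = c(md = 10,  ac = 10,  bl = 10),
                                 dcd  = c(md = 4.5, ac = 5.5, bl = 4.5),
                                 high = c(md = 6.5, ac = 6.5, bl = 6.5)),
                               score_sd = 3,
                               batch_offsets = list(
                                 study_id = c(MEDEA = 0, NDA_A = 1.5, NDA_B = -1.0),
                                 module   = c(`1` = 0, `2` = 0, `3` = 0),
                                 sex      = c(M = 0, F = 0)),
                               study_levels = c("MEDEA", "NDA_A", "NDA_B"),
                               study_prob = c(0.5, 0.3, 0.2),
                               female_prob = c(autism = 0.19, td = 0.23, dcd = 0.39),
                               age_range = c(3, 16),
                               seed = 1L) {
  if (any(n_per_group <= 0)) stop("n_per_group must be positive counts")
  if (subtype_fraction < 0 || subtype_fraction > 1)
    stop("subtype_fraction must lie in [0, 1]")
  if (score_sd <= 0) stop("score_sd must be positive")
  stopifnot(all(c("md", "ac", "bl") %in% names(subtype_effect_d)))
  structure(list(n_per_group = n_per_group,
                 subtype_fraction = subtype_fraction,
                 subtype_effect_d = subtype_effect_d,
                 group_means = group_means,
                 score_sd = score_sd,
                 batch_offsets = batch_offsets,
                 study_levels = study_levels,
                 study_prob = study_prob,
                 female_prob = female_prob,
                 age_range = age_range,
                 seed = as.integer(seed)),
            class = "profile_sim_config")
}

#' Simulate a multi-site motor-profile table
#'
#' Draws one row per subject with diagnosis, originating study, MABC2 module
#' (from age), sex, age and Gaussian subscale scores around the group (and,
#' for autism, hidden-subtype) means, plus the configured additive batch
#' offsets. Autistic rows carry the hidden generating subtype in
#' `true_subtype`; this column exists only for validation of downstream
#' recovery and is never used by the analysis itself.
#'
#' @param cfg a [profile_sim_config()].
#' @return a data.frame (`subject_id`, `diagnosis`, `study_id`, `module`,
#'   `sex`, `age`, `md`, `ac`, `bl`, `total`, `true_subtype`).
#' @export
simulate_profiles <- function(cfg = profile_sim_config()) {
  stopifnot(inherits(cfg, "profile_sim_config"))
  set.seed(cfg$seed)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  age <- round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  module <- ifelse(age < 7, 1L, ifelse(age < 11, 2L, 3L))
  study <- sample(cfg$study_levels, n, replace = TRUE, prob = cfg$study_prob)
  sex <- ifelse(runif(n) < cfg$female_prob[groups], "F", "M")

  subtype <- rep(NA_character_, n)
  is_aut <- groups == "autism"
  n_aut <- sum(is_aut)
  n_low <- round(cfg$subtype_fraction * n_aut)
  subtype[is_aut] <- sample(c(rep("Low", n_low), rep("High", n_aut - n_low)))

  mean_for <- function(score) {
    mu <- numeric(n)
    mu[groups == "td"] <- cfg$group_means$td[score]
    mu[groups == "dcd"] <- cfg$group_means$dcd[score]
    hi <- cfg$group_means$high[score]
    mu[is_aut & subtype == "High"] <- hi
    mu[is_aut & subtype == "Low"] <-
      hi - cfg$subtype_effect_d[score] * cfg$score_sd
    mu
  }
  off <- cfg$batch_offsets
  batch <- off$study_id[study] + off$module[as.character(module)] + off$sex[sex]
  scores <- sapply(c("md", "ac", "bl"), function(s)
    rnorm(n, mean_for(s), cfg$score_sd) + batch)

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    diagnosis = groups, study_id = study, module = module,
                    sex = sex, age = age,
                    md = scores[, "md"], ac = scores[, "ac"], bl = scores[, "bl"],
                    stringsAsFactors = FALSE)
  out$total <- rowMeans(out[, c("md", "ac", "bl")])
  out$true_subtype <- subtype
  out
}

#' Simulate a phenotype table for the autistic subjects
#'
#' Generates per-subject phenotype measures with a configured standardized
#' gap between the hidden motor subtypes for IQ (lower in "Low") and age at
#' independent walking (later in "Low"), and no subtype difference by
#' construction for age at first words, ADOS-2 calibrated severity scores and
#' SRS. This mirrors the expectation that core autism symptomatology is
#' orthogonal to the motor split.
#'
#' @param profiles a motor-profile table with a `true_subtype` column.
#' @param iq_gap_d standardized IQ gap (High minus Low) in pooled-SD units.
#' @param walk_delay_d standardized delay in age at walking (Low minus High).
#' @param seed integer seed.
#' @return a data.frame with `subject_id`, `iq`, `walk_age_months`,
#'   `words_age_months`, `ados_css_total`, `ados_css_sa`, `ados_css_rrb`, `srs`.
#' @export
simulate_phenotypes <- function(profiles, iq_gap_d = 0.7, walk_delay_d = 0.67,
                                seed = 1L) {
  assert_columns(profiles, c("subject_id", "diagnosis", "true_subtype"),
                 "profile table")
  aut <- profiles[profiles$diagnosis == "autism", ]
  if (nrow(aut) == 0L || all(is.na(aut$true_subtype)))
    stop("phenotype simulation requires autistic rows with hidden subtype labels")
  set.seed(seed)
  n <- nrow(aut)
  low <- aut$true_subtype == "Low"
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  iq <- rnorm(n, 100 - ifelse(low, iq_gap_d * 15, 0), 15)
  walk <- rnorm(n, 13 + ifelse(low, walk_delay_d * 4, 0), 4)
  data.frame(subject_id = aut$subject_id,
             iq = iq,
             walk_age_months = clamp(walk, 8, 40),
             words_age_months = clamp(rnorm(n, 18, 6), 6, 60),
             ados_css_total = clamp(round(rnorm(n, 7, 1.8)), 1, 10),
             ados_css_sa = clamp(round(rnorm(n, 7, 1.8)), 1, 10),
             ados_css_rrb = clamp(round(rnorm(n, 7, 2)), 1, 10),
             srs = rnorm(n, 75, 10),
             stringsAsFactors = FALSE)
}
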