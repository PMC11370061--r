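#' Default end-to-end pipeline configuration
#'
#' Assembles the per-stage configurations of the full synthetic study:
#' profile simulation, phenotype simulation, kinematic cohort simulation,
#' batch correction, subtype discovery and group statistics. One global seed
#' is fanned out into named per-stage substreams, so changing the number of
#' draws in one stage leaves every other stage unchanged. The configuration
#' round-trips through YAML via [yaml::write_yaml()].
#'
#' @param seed global integer seed.
#' @param n_profiles named subject counts per diagnosis.
#' @param n_kinematic named subject counts per kinematic group.
#' @param reval a [reval_config()] (its seed is re-derived from `seed`).
#' @param sigclust_sims Monte-Carlo draws for the cluster significance test.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_profiles = c(autism = 156, td = 149, dcd = 23),
                            n_kinematic = c(TD = 79, High = 37, Low = 33),
                            reval = reval_config(),
                            sigclust_sims = 10000) {
  reval$seed <- substream_seed(seed, "reval")
  structure(list(seed = as.integer(seed), n_profiles = n_profiles,
                 n_kinematic = n_kinematic, reval = reval,
                 sigclust_sims = sigclust_sims),
            class = "pipeline_config")
}

#' Run the full synthetic study end to end
#'
#' Executes all stages in order — simulate, preprocess (merge, filter, batch
#' correct), subtype discovery, kinematic motor-noise scoring, and group
#' statistics — writing every tabular artifact as CSV plus a JSON model card
#' and a run manifest into `out_dir`. Re-running with the same configuration
#' reproduces all numeric outputs exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent); `NULL` skips all
#'   file output.
#' @param verbose print stage progress.
#' @return list with `profiles`, `corrected`, `model`, `phenotypes`,
#'   `noise`, `stats` (per-stage results), invisibly writes artifacts.
#' @export
run_full_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage 1/5: simulate")
  profiles <- stage("simulate", {
    pc <- profile_sim_config(n_per_group = cfg$n_profiles,
                             seed = substream_seed(cfg$seed, "profiles"))
    simulate_profiles(pc)
  })
  phenotypes <- stage("simulate", simulate_phenotypes(
    profiles, seed = substream_seed(cfg$seed, "phenotypes")))

  say("stage 2/5: preprocess")
  corrected <- stage("preprocess", batch_correct(merge_and_filter(profiles)))

  say("stage 3/5: subtype discovery")
  model <- stage("subtype", fit_motor_subtypes(
    corrected, cfg$reval, sigclust_sims = cfg$sigclust_sims))

  say("stage 4/5: kinematics / motor noise")
  noise_res <- stage("noise", {
    cohort <- simulate_kinematic_cohort(
      n_per_group = cfg$n_kinematic,
      cfg = kinematic_sim_config(),
      seed = substream_seed(cfg$seed, "kinematics"))
    scores <- motor_noise_scores(cohort$trials)
    list(cohort = cohort, scores = scores)
  })

  say("stage 5/5: statistics")
  stats_res <- stage("stats", {
    labels <- model$labels
    aut <- merge(labels, phenotypes, by = "subject_id")
    pheno_vars <- c("iq", "walk_age_months", "words_age_months",
                    "ados_css_total", "ados_css_sa", "ados_css_rrb", "srs")
    # High/Low phenotype contrasts are defined for the two-subtype solution
    pheno_tests <- if (model$best_k == 2) {
      do.call(rbind, lapply(pheno_vars, function(v) {
        res <- compare_groups(aut[[v]], factor(aut$subtype, c("High", "Low")))
        res$variable <- v
        res
      }))
    } else {
      warning("best_k != 2: subtype phenotype contrasts skipped")
      NULL
    }

    nz <- merge(noise_res$scores, noise_res$cohort$subjects, by = "subject_id")
    noise_anova <- anova_posthoc(nz$whole, nz$group)

    keep <- complete.cases(nz[, c("reach_feedforward", "reach_feedback")])
    long <- rbind(
      data.frame(subject_id = nz$subject_id[keep], group = nz$group[keep],
                 phase = "feedforward", value = nz$reach_feedforward[keep]),
      data.frame(subject_id = nz$subject_id[keep], group = nz$group[keep],
                 phase = "feedback", value = nz$reach_feedback[keep]))
    lmm <- fit_group_phase_lmm(long)

    merged <- merge(corrected, labels[, c("subject_id", "subtype")],
                    by = "subject_id", all.x = TRUE)
    grp_subtype <- ifelse(merged$diagnosis == "autism",
                          paste0("autism_", merged$subtype), merged$diagnosis)
    aic <- aic_compare(merged$total, merged$diagnosis, grp_subtype)
    list(phenotype_tests = pheno_tests, noise_anova = noise_anova,
         lmm = lmm, aic = aic)
  })

  result <- list(profiles = profiles, phenotypes = phenotypes,
                 corrected = corrected, model = model,
                 noise = noise_res$scores,
                 noise_subjects = noise_res$cohort$subjects,
                 stats = stats_res, config = cfg)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  invisible(result)
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.csv(result$profiles, p("profiles.csv"), row.names = FALSE)
  write.csv(result$phenotypes, p("phenotypes.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$corrected), p("profiles_corrected.csv"),
            row.names = FALSE)
  jsonlite::write_json(attr(result$corrected, "correction_betas"),
                       p("correction_betas.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$model$labels, p("subtype_labels.csv"), row.names = FALSE)
  write.csv(result$model$curve, p("stability_curve.csv"), row.names = FALSE)
  m <- result$model
  jsonlite::write_json(list(
    best_k = m$best_k,
    generalization_accuracy = m$generalization_accuracy,
    sigclust_p = if (!is.null(m$sigclust)) m$sigclust$p_value else NULL,
    config = unclass(m$config)), p("model_card.json"),
    auto_unbox = TRUE, digits = NA)
  noise_out <- merge(result$noise_subjects, result$noise, by = "subject_id")
  write.csv(noise_out, p("motor_noise.csv"), row.names = FALSE)
  if (!is.null(result$stats$phenotype_tests))
    write.csv(result$stats$phenotype_tests, p("phenotype_tests.csv"),
              row.names = FALSE)
  write.csv(result$stats$noise_anova$posthoc, p("noise_posthoc.csv"),
            row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("motorstrat")),
    seed = result$config$seed,
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  # named vectors become explicit maps so their names survive YAML
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (inherits(x, "reval_config")) return(unclass(x))
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  rv <- do.call(reval_config, y$reval[setdiff(names(y$reval), "seed")])
  rv$seed <- y$reval$seed
  structure(list(seed = as.integer(y$seed),
                 n_profiles = unlist(y$n_profiles),
                 n_kinematic = unlist(y$n_kinematic),
                 reval = rv, sigclust_sims = y$sigclust_sims),
            class = "pipeline_config")
}
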