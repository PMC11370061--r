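test_that("profile generation is reproducible and validates its config", {
  cfg <- profile_sim_config(seed = 11)
  expect_identical(simulate_profiles(cfg), simulate_profiles(cfg))
  expect_error(profile_sim_config(n_per_group = c(autism = 0, td = 10, dcd = 5)),
               "positive")
  expect_error(profile_sim_config(subtype_fraction = 1.2), "\\[0, 1\\]")
})

test_that("configured subtype effect sizes are recovered empirically", {
  cfg <- profile_sim_config(
    n_per_group = c(autism = 150, td = 20, dcd = 5),
    subtype_effect_d = c(md = 2.0, ac = 0.45, bl = 2.0),
    batch_offsets = list(study_id = c(MEDEA = 0, NDA_A = 0, NDA_B = 0),
                         module = c(`1` = 0, `2` = 0, `3` = 0),
                         sex = c(M = 0, F = 0)),
    seed = 21)
  tab <- simulate_profiles(cfg)
  aut <- tab[tab$diagnosis == "autism", ]
  d_emp <- vapply(c("md", "ac", "bl"), function(s)
    cohens_d(aut[[s]][aut$true_subtype == "High"],
             aut[[s]][aut$true_subtype == "Low"]), numeric(1))
  expect_equal(unname(d_emp), c(2.0, 0.45, 2.0), tolerance = 0.3 / 2)
})

test_that("zero subtype separation leaves hidden labels unrecoverable", {
  cfg <- profile_sim_config(subtype_effect_d = c(md = 0, ac = 0, bl = 0),
                            seed = 5)
  aut <- subset(simulate_profiles(cfg), diagnosis == "autism")
  d <- cohens_d(aut$md[aut$true_subtype == "High"],
                aut$md[aut$true_subtype == "Low"])
  expect_lt(abs(d), 0.4)
})

test_that("reach-to-drop trials repeat exactly without noise and jitter", {
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 3)
  trs <- simulate_reach_to_drop(cfg, subject_noise = 0)
  for (t in trs[-1])
    expect_equal(unclass(t)[, ], unclass(trs[[1]])[, ])
  expect_identical(dtw_distance(trs[[1]], trs[[2]]), 0)
  expect_error(simulate_reach_to_drop(cfg, subject_noise = -1), "non-negative")
})

test_that("reference-point reach velocity is the minimum-jerk bell", {
  cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 1)
  tr <- simulate_reach_to_drop(cfg, subject_noise = 0)[[1]]
  fs <- attr(tr, "sample_rate")
  n_r <- attr(tr, "grasp_frame") - 1L
  vel <- tangential_velocity(tr, fs)
  reach_speed <- vel$speed[1:n_r]
  # single maximum at tau = 0.5, peak speed 1.875 A / T (analytic maximum of
  # the minimum-jerk speed profile 30 tau^2 (1 - tau)^2)
  A <- sqrt(sum((cfg$ball - cfg$start)^2))
  expect_lte(abs(which.max(reach_speed) - (n_r + 1) / 2), 1.5)
  expect_equal(max(reach_speed), 1.875 * A / cfg$reach_duration,
               tolerance = 0.02)
  tau <- (seq_len(n_r) - 1) / (n_r - 1)
  expect_gt(cor(reach_speed, 30 * tau^2 * (1 - tau)^2), 0.999)
})

test_that("pairwise trajectory deviation grows monotonically with noise", {
  rms_dev <- vapply(c(0.5, 1, 2, 4), function(sg) {
    cfg <- kinematic_sim_config(duration_jitter_sd = 0, seed = 17)
    trs <- simulate_reach_to_drop(cfg, subject_noise = sg)
    pairs <- utils::combn(length(trs), 2)
    mean(vapply(seq_len(ncol(pairs)), function(p)
      sqrt(mean((trs[[pairs[1, p]]] - trs[[pairs[2, p]]])^2)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rms_dev) > 0))
})

test_that("phenotype gaps are injected for IQ and walking age only", {
  cfg <- profile_sim_config(n_per_group = c(autism = 300, td = 5, dcd = 5),
                            seed = 9)
  tab <- simulate_profiles(cfg)
  ph <- simulate_phenotypes(tab, iq_gap_d = 0.7, walk_delay_d = 0.67, seed = 2)
  aut <- merge(tab[tab$diagnosis == "autism", c("subject_id", "true_subtype")],
               ph, by = "subject_id")
  hi <- aut$true_subtype == "High"
  expect_equal(cohens_d(aut$iq[hi], aut$iq[!hi]), 0.7, tolerance = 0.3 / 0.7)
  expect_equal(cohens_d(aut$walk_age_months[!hi], aut$walk_age_months[hi]),
               0.67, tolerance = 0.3 / 0.67)
  # core symptom measures carry no subtype signal by construction
  for (v in c("ados_css_total", "ados_css_sa", "srs"))
    expect_lt(abs(cohens_d(aut[[v]][hi], aut[[v]][!hi])), 0.3)
})
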