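base_row <- function(id, age = 8, md = 10, ac = 10, bl = 10, study = "A") {
  data.frame(subject_id = id, diagnosis = "autism", study_id = study,
             module = 2L, sex = "M", age = age, md = md, ac = ac, bl = bl,
             total = mean(c(md, ac, bl)), stringsAsFactors = FALSE)
}

test_that("merging de-duplicates and applies age and missingness filters", {
  t1 <- rbind(base_row("a"), base_row("b"), base_row("young", age = 2.5))
  t2 <- rbind(base_row("a", md = 1), base_row("c"),
              base_row("old", age = 16.5))
  miss2 <- base_row("m2"); miss2$ac <- NA; miss2$bl <- NA
  miss1 <- base_row("m1"); miss1$ac <- NA
  merged <- merge_and_filter(list(t1, t2, miss2, miss1))
  expect_setequal(merged$subject_id, c("a", "b", "c", "m1"))
  expect_equal(merged$md[merged$subject_id == "a"], 10)  # first kept
  ex <- attr(merged, "exclusions")
  expect_setequal(ex$subject_id, c("a", "young", "old", "m2"))
  expect_match(ex$reason[ex$subject_id == "m2"], "subscale")
  expect_error(merge_and_filter(base_row("x", age = 1)), "empty cohort")
})

test_that("correction is a no-op when scores carry no batch structure", {
  set.seed(4)
  n <- 120
  tab <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    diagnosis = sample(c("autism", "td"), n, TRUE),
                    study_id = sample(c("A", "B"), n, TRUE),
                    module = sample(1:3, n, TRUE),
                    sex = sample(c("M", "F"), n, TRUE),
                    age = runif(n, 3, 16), stringsAsFactors = FALSE)
  # scores an exact function of diagnosis: every nuisance beta is exactly 0
  base <- ifelse(tab$diagnosis == "autism", 5, 10)
  tab$md <- base; tab$ac <- base + 1; tab$bl <- base - 1
  tab$total <- base
  cp <- batch_correct(tab)
  for (s in c("md", "ac", "bl", "total"))
    expect_equal(cp[[s]], tab[[s]], tolerance = 1e-10)
})

test_that("an injected study offset is projected out exactly", {
  cfg0 <- profile_sim_config(seed = 31)
  off <- cfg0$batch_offsets
  off$study_id <- c(MEDEA = 0, NDA_A = 3, NDA_B = 0)
  cfg <- profile_sim_config(batch_offsets = off, seed = 31)
  cp <- batch_correct(merge_and_filter(simulate_profiles(cfg)))
  dat <- as.data.frame(cp)
  dat$module <- factor(dat$module)
  refit <- lm(md ~ study_id + module + sex + diagnosis, data = dat)
  nuis <- coef(refit)[grep("study_id|module|sex", names(coef(refit)))]
  expect_lt(max(abs(nuis)), 1e-8)
  # the diagnosis contrast is untouched by the correction: compare with the
  # same generator draw without any offsets
  cp0 <- batch_correct(merge_and_filter(simulate_profiles(
    profile_sim_config(seed = 31))))
  b1 <- coef(lm(md ~ diagnosis, data = as.data.frame(cp)))[-1]
  b0 <- coef(lm(md ~ diagnosis, data = as.data.frame(cp0)))[-1]
  expect_equal(b1, b0, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("correction is idempotent and cannot inflate score variance", {
  cp <- batch_correct(merge_and_filter(simulate_profiles(
    profile_sim_config(seed = 13))))
  cp2 <- batch_correct(as.data.frame(cp))
  for (s in c("md", "ac", "bl", "total")) {
    expect_equal(cp2[[s]], cp[[s]], tolerance = 1e-8)
    expect_lte(var(cp[[s]]), var(simulate_profiles(
      profile_sim_config(seed = 13))[[s]]) + 1e-12)
  }
})

test_that("confounded nuisance factors raise a rank-deficiency error", {
  tab <- do.call(rbind, lapply(1:30, function(i)
    base_row(paste0("r", i), study = c("A", "B")[i %% 2 + 1])))
  set.seed(2); tab$md <- tab$md + rnorm(30)
  tab$sex <- ifelse(tab$study_id == "A", "M", "F")  # study aliases sex
  expect_error(batch_correct(tab), "alias")
})

test_that("rows missing one subscale keep it missing after correction", {
  tab <- simulate_profiles(profile_sim_config(seed = 8))
  tab$ac[c(3, 9)] <- NA
  cp <- batch_correct(tab)
  expect_true(all(is.na(cp$ac[c(3, 9)])))
  expect_false(anyNA(cp$ac[-c(3, 9)]))
})
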