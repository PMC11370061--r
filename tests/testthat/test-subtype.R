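test_that("stratified split hits the 70/30 target and is reproducible", {
  tab <- make_null_table(156, seed = 2)
  sp <- suppressWarnings(stratified_split(tab, 0.7, seed = 10))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_equal(sort(c(sp$train, sp$validation)), 1:156)
  expect_equal(length(sp$train), 109, tolerance = 3 / 109)
  sp2 <- suppressWarnings(stratified_split(tab, 0.7, seed = 10))
  expect_identical(sp, sp2)
  # single homogeneous stratum of 10
  one <- make_null_table(10, seed = 3)
  one$study_id <- "A"; one$sex <- "M"; one$module <- 1L
  sp1 <- stratified_split(one, 0.7, seed = 1)
  expect_length(sp1$train, 7)
  expect_length(sp1$validation, 3)
})

test_that("label alignment matches the exhaustive-permutation oracle", {
  expect_equal(align_labels(c(0, 0, 1, 1), c(1, 1, 0, 0))$error, 0)
  expect_equal(align_labels(c(0, 0, 1, 1), c(0, 1, 0, 1))$error, 0.5)
  expect_error(align_labels(c(0, 1), c(0, 1, 1)), "equal length")
  set.seed(42)
  for (i in 1:200) {
    k_ref <- sample(2:4, 1); k_cand <- sample(2:4, 1)
    len <- sample(4:8, 1)
    ref <- sample(0:(k_ref - 1), len, TRUE)
    cand <- sample(0:(k_cand - 1), len, TRUE)
    expect_equal(align_labels(ref, cand)$error, align_brute_force(ref, cand),
                 info = sprintf("instance %d", i))
  }
})

test_that("alignment-based accuracies are invariant to cluster relabeling", {
  set.seed(7)
  ref <- sample(0:2, 60, TRUE); cand <- sample(0:2, 60, TRUE)
  base <- align_labels(ref, cand)$error
  for (p in list(c(1, 2, 0), c(2, 0, 1))) {
    expect_equal(align_labels(ref, p[cand + 1])$error, base)
    expect_equal(align_labels(p[ref + 1], cand)$error, base)
  }
})

test_that("normalized stability separates structured from unstructured data", {
  cfg <- reval_config(cv_repeats = 30, seed = 1)
  set.seed(1)
  blobs <- rbind(matrix(rnorm(120, 0), ncol = 2),
                 matrix(rnorm(120, 10), ncol = 2))
  expect_lt(normalized_stability(blobs, 2, cfg)$normalized_stability, 0.05)
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    normalized_stability(matrix(rnorm(240), ncol = 2), 2, cfg,
                         seed = s)$normalized_stability
  }, numeric(1))
  expect_gt(mean(nulls), 0.2)   # well above the two-blob case
  # duplicated identical points cluster deterministically
  dup <- rbind(matrix(0, 30, 2), matrix(5, 30, 2))
  expect_equal(normalized_stability(dup, 2, cfg)$stability, 0)
})

test_that("the stability minimum recovers the true number of blobs", {
  # equidistant blobs: at k = 2 the merge choice is ambiguous across folds
  # (three symmetric solutions), so only the true k = 3 is stable
  sep <- 8.5 / sqrt(2)
  tab3 <- make_blob_table(40, centers = rbind(c(0, 0, 0), c(sep, sep, 0),
                                              c(sep, 0, sep)), seed = 4)
  Z <- scale(as.matrix(tab3[, c("md", "ac", "bl")]))
  cfg <- reval_config(cv_repeats = 30, seed = 4)
  ns <- vapply(2:4, function(k)
    normalized_stability(Z, k, cfg, seed = 40 + k)$normalized_stability,
    numeric(1))
  expect_equal(which.min(ns) + 1L, 3L)
  expect_lt(ns[2], 0.05)
  expect_gt(ns[1], 0.3)
  const <- tab3; const$md <- 5; const$ac <- 5; const$bl <- 5
  expect_error(suppressWarnings(select_best_k(const, cfg)), "degenerate")
})

test_that("well-separated subtypes generalize to the held-out split", {
  tab <- make_blob_table(60, centers = rbind(c(0, 0, 0), c(8, 0, 8)),
                         sd = 1, seed = 6)
  tab$total <- rowMeans(tab[, c("md", "ac", "bl")])
  cfg <- reval_config(k_range = 2:5, cv_repeats = 20, seed = 6)
  m <- suppressWarnings(fit_motor_subtypes(tab, cfg, sigclust_sims = 0))
  expect_equal(m$best_k, 2)
  expect_gte(m$generalization_accuracy, 0.95)
  # subtype semantics follow the corrected total score
  lab <- merge(m$labels, tab[, c("subject_id", "blob")], by = "subject_id")
  low_blob <- which.min(tapply(tab$total, tab$blob, mean))
  expect_gt(mean((lab$subtype == "Low") == (lab$blob == low_blob)), 0.95)
  # predict() reproduces the training labels for separable data
  pred <- predict(m, tab)
  expect_gt(mean(pred == lab$subtype[match(tab$subject_id, lab$subject_id)]),
            0.95)
})

test_that("sigclust attains its minimum p on strongly clustered data", {
  set.seed(9)
  X <- rbind(matrix(rnorm(150), ncol = 3), matrix(rnorm(150, 6), ncol = 3))
  res <- sigclust_test(X, n_sim = 200, seed = 9)
  expect_equal(res$p_value, 1 / 201)
  expect_error(sigclust_test(X[1:5, ]), "at least 10")
  expect_warning(sigclust_test(X, n_sim = 50, seed = 1), "unstable")
})

test_that("the full subtype stage is deterministic under a fixed seed", {
  cp <- make_subtyped_corrected(seed = 101)
  cfg <- reval_config(k_range = 2:4, cv_repeats = 15, seed = 5)
  m1 <- suppressWarnings(fit_motor_subtypes(cp, cfg, sigclust_sims = 100))
  m2 <- suppressWarnings(fit_motor_subtypes(cp, cfg, sigclust_sims = 100))
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$curve, m2$curve)
  expect_identical(m1$sigclust$p_value, m2$sigclust$p_value)
})
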