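#' Configuration for stability-based relative clustering validation
#'
#' Hyperparameters of the subtype-discovery pipeline: per-feature
#' standardization (mean 0, SD 1), UMAP embedding (fit on the training split
#' only and applied in transform mode elsewhere), k-means clustering, and a
#' k-nearest-neighbor classifier, wrapped in a repeated cross-validation
#' scheme over candidate cluster counts.
#'
#' @param k_range candidate cluster counts (default 2:10).
#' @param cv_folds folds of the internal cross-validation scheme (default 2).
#' @param cv_repeats repetitions of the scheme (default 100).
#' @param split_fraction train share of the train/validation split
#'   (default 0.70, stratified on study ID, sex and module).
#' @param umap_neighbors,umap_min_dist,umap_components UMAP hyperparameters
#'   (defaults 30, 0, 2; Euclidean metric, fixed random state).
#' @param knn_k neighbor count of the classifier (default 5).
#' @param kmeans_nstart random restarts of k-means (default 10).
#' @param seed integer seed for the whole stage.
#' @return a `reval_config` list.
#' @export
reval_config <- function(k_range = 2:10, cv_folds = 2, cv_repeats = 100,
                         split_fraction = 0.70,
                         umap_neighbors = 30, umap_min_dist = 0.0,
                         umap_components = 2,
                         knn_k = 5, kmeans_nstart = 10, seed = 42L) {
  if (min(k_range) < 2) stop("k_range must start at 2 or above")
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  structure(list(k_range = k_range, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, split_fraction = split_fraction,
                 umap_neighbors = umap_neighbors, umap_min_dist = umap_min_dist,
                 umap_components = umap_components, knn_k = knn_k,
                 kmeans_nstart = kmeans_nstart, seed = as.integer(seed)),
            class = "reval_config")
}

#' Stratified train/validation split
#'
#' Splits rows into train and validation sets with the configured train
#' fraction inside every stratum of study ID x sex x module (each stratum's
#' train share is within one subject of the target). Strata smaller than 2
#' are collapsed into a pooled stratum with a warning.
#'
#' @param table a profile table with `study_id`, `sex`, `module` columns.
#' @param split_fraction train share (default 0.7).
#' @param seed integer seed.
#' @return list with integer row indices `train` and `validation`.
#' @export
stratified_split <- function(table, split_fraction = 0.7, seed = 42L) {
  assert_columns(table, c("study_id", "sex", "module"), "profile table")
  set.seed(seed)
  strata <- interaction(table$study_id, table$sex, table$module, drop = TRUE)
  tabs <- table(strata)
  small <- names(tabs)[tabs < 2]
  if (length(small) > 0) {
    warning(sprintf("%d stratum/strata with a single subject pooled", length(small)))
    strata <- as.character(strata)
    strata[strata %in% small] <- ".pooled"
  }
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- round(split_fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    if (length(idx) == 1L) n_tr <- 1L
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_len(nrow(table)), train))
}

#' Align two cluster labelings and compute the misclassification error
#'
#' Finds the label permutation of `candidate` that minimizes disagreement
#' with `reference` via optimal bipartite matching (Hungarian assignment) on
#' the confusion matrix; unequal label sets are handled by zero-padding to a
#' square matrix. All downstream accuracies are therefore invariant to
#' arbitrary relabeling of clusters.
#'
#' @param reference,candidate equal-length label vectors (any atomic labels).
#' @return list with `labels` (candidate relabeled into reference labels),
#'   `error` (minimized disagreement fraction) and `mapping`.
#' @export
align_labels <- function(reference, candidate) {
  if (length(reference) != length(candidate))
    stop("label vectors must have equal length")
  ref_lev <- sort(unique(reference))
  cand_lev <- sort(unique(candidate))
  k <- max(length(ref_lev), length(cand_lev))
  conf <- matrix(0, k, k)
  conf[seq_along(cand_lev), seq_along(ref_lev)] <-
    as.matrix(table(factor(candidate, cand_lev), factor(reference, ref_lev)))
  sol <- clue::solve_LSAP(conf, maximum = TRUE)
  agree <- sum(conf[cbind(seq_len(k), sol)])
  mapping <- setNames(rep(NA, length(cand_lev)), cand_lev)
  for (i in seq_along(cand_lev)) {
    j <- sol[i]
    mapping[i] <- if (j <= length(ref_lev)) ref_lev[j] else NA
  }
  labels <- unname(mapping[as.character(candidate)])
  list(labels = labels, error = 1 - agree / length(reference),
       mapping = mapping)
}

#' Normalized clustering stability for one candidate k
#'
#' Repeatedly partitions the (embedded) training features into internal
#' folds; each fold is clustered independently with k-means, a k-NN
#' classifier fit on one fold's cluster labels predicts the other fold, and
#' the prediction is compared (after optimal label alignment) with that
#' fold's own cluster labels. Stability is the mean misclassification error
#' across folds and repeats; normalized stability divides it by the
#' asymptotic error of uniformly random labeling, (k - 1)/k, making curves
#' comparable across k.
#'
#' @param X numeric feature matrix (embedded training set).
#' @param k number of clusters.
#' @param cfg a [reval_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `k`, `stability`, `normalized_stability`, `dispersion`
#'   (SD of per-repeat means).
#' @export
normalized_stability <- function(X, k, cfg = reval_config(), seed = cfg$seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (n < 2 * k) stop("need at least 2k observations")
  set.seed(seed)
  rep_err <- vapply(seq_len(cfg$cv_repeats), function(r) {
    fold <- sample(rep(seq_len(cfg$cv_folds), length.out = n))
    errs <- vapply(seq_len(cfg$cv_folds), function(f) {
      te <- which(fold == f); tr <- which(fold != f)
      cl_tr <- safe_kmeans(X[tr, , drop = FALSE], k, cfg$kmeans_nstart)
      cl_te <- safe_kmeans(X[te, , drop = FALSE], k, cfg$kmeans_nstart)
      if (is.null(cl_tr) || is.null(cl_te)) return((k - 1) / k)
      pred <- knn_predict(X[tr, , drop = FALSE], cl_tr,
                          X[te, , drop = FALSE], cfg$knn_k)
      align_labels(cl_te, pred)$error
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(k = k, stability = mean(rep_err),
       normalized_stability = mean(rep_err) / ((k - 1) / k),
       dispersion = sd(rep_err))
}

# k-means that retries once on an empty-cluster failure and signals NULL if
# a valid k-cluster solution cannot be obtained (degenerate data).
safe_kmeans <- function(X, k, nstart) {
  if (nrow(unique(X)) < k) return(NULL)
  for (attempt in 1:2) {
    km <- tryCatch(suppressWarnings(kmeans(X, k, nstart = nstart,
                                           iter.max = 100)),
                   error = function(e) NULL)
    if (!is.null(km)) return(km$cluster)
  }
  warning("k-means failed twice (empty cluster); worst-case error recorded")
  NULL
}

knn_predict <- function(X_train, labels, X_test, k) {
  as.integer(as.character(class::knn(X_train, X_test,
                                     factor(labels), k = min(k, nrow(X_train)))))
}

#' Select the number of clusters minimizing normalized stability
#'
#' Standardizes the training features, fits the UMAP embedder on the
#' training set, and computes the normalized-stability curve over the
#' candidate k range; the selected k is the argmin, with ties broken toward
#' the smaller k (parsimony).
#'
#' @param train data.frame with complete `md`, `ac`, `bl` columns.
#' @param cfg a [reval_config()].
#' @return list with `best_k`, `curve` (data.frame: k, stability,
#'   normalized_stability, dispersion), `scaler`, `umap_model`, `embedding`.
#' @export
select_best_k <- function(train, cfg = reval_config()) {
  feats <- as.matrix(train[, c("md", "ac", "bl")])
  if (anyNA(feats)) stop("clustering features must be complete")
  sds <- apply(feats, 2, sd)
  if (any(sds == 0)) stop("degenerate input: constant feature(s) ",
                          paste(colnames(feats)[sds == 0], collapse = ", "))
  scaler <- list(center = colMeans(feats), scale = sds)
  Z <- scale(feats, scaler$center, scaler$scale)
  set.seed(cfg$seed)
  um <- uwot::umap(Z, n_neighbors = min(cfg$umap_neighbors, nrow(Z) - 1),
                   min_dist = cfg$umap_min_dist,
                   n_components = cfg$umap_components, metric = "euclidean",
                   ret_model = TRUE, n_threads = 1, n_sgd_threads = 1)
  E <- um$embedding
  curve <- lapply(seq_along(cfg$k_range), function(i)
    normalized_stability(E, cfg$k_range[i], cfg,
                         seed = substream_seed(cfg$seed, paste0("k", cfg$k_range[i]))))
  curve <- do.call(rbind, lapply(curve, as.data.frame))
  best_k <- curve$k[which.min(curve$normalized_stability)]
  list(best_k = best_k, curve = curve, scaler = scaler, umap_model = um,
       embedding = E)
}
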