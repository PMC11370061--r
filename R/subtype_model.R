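#' Fit a motor-subtype model by stability-based clustering validation
#'
#' The main fitting function of the package. Takes a (batch-corrected)
#' motor-profile table, keeps the autistic subjects with complete subscale
#' scores, splits them into train and validation sets (stratified on study
#' ID, sex and module), selects the number of clusters minimizing normalized
#' stability on the training split, clusters both splits independently with
#' that k, and measures generalization accuracy as the (alignment-corrected)
#' agreement between the validation set's own cluster labels and the labels
#' predicted by a k-NN classifier trained on the training split. Cluster
#' indices are given the semantics "High"/"Low" by the mean corrected total
#' score of the training clusters (only defined for k = 2; for other k the
#' labels are `cluster_1..k` ordered by decreasing mean total).
#'
#' A Monte-Carlo cluster significance test against a single multivariate
#' Gaussian null ([sigclust_test()]) is run on the standardized training
#' features unless `sigclust_sims = 0`.
#'
#' @param data a profile table (ideally from [batch_correct()]).
#' @param cfg a [reval_config()].
#' @param diagnosis_value value of the `diagnosis` column to subtype
#'   (default "autism").
#' @param sigclust_sims Monte-Carlo draws of the significance test
#'   (default 1000; 0 disables).
#' @return an object of class `motor_subtypes`; see
#'   [predict.motor_subtypes()], [summary.motor_subtypes()],
#'   [plot.motor_subtypes()].
#' @export
fit_motor_subtypes <- function(data, cfg = reval_config(),
                               diagnosis_value = "autism",
                               sigclust_sims = 1000) {
  assert_columns(data, c("subject_id", "diagnosis", "md", "ac", "bl", "total"),
                 "profile table")
  aut <- data[data$diagnosis == diagnosis_value, , drop = FALSE]
  complete <- complete.cases(aut[, c("md", "ac", "bl")])
  if (any(!complete))
    warning(sprintf("%d subject(s) with incomplete subscales excluded from clustering",
                    sum(!complete)))
  aut <- aut[complete, , drop = FALSE]
  if (nrow(aut) < 20) stop("too few complete subjects to subtype")

  sp <- stratified_split(aut, cfg$split_fraction,
                         seed = substream_seed(cfg$seed, "split"))
  train <- aut[sp$train, , drop = FALSE]
  validation <- aut[sp$validation, , drop = FALSE]

  sel <- select_best_k(train, cfg)
  k <- sel$best_k

  E_tr <- sel$embedding
  Z_va <- scale(as.matrix(validation[, c("md", "ac", "bl")]),
                sel$scaler$center, sel$scaler$scale)
  set.seed(substream_seed(cfg$seed, "transform"))
  E_va <- uwot::umap_transform(Z_va, sel$umap_model, n_threads = 1)

  set.seed(substream_seed(cfg$seed, "final"))
  cl_tr <- safe_kmeans(E_tr, k, cfg$kmeans_nstart)
  cl_va <- safe_kmeans(E_va, k, cfg$kmeans_nstart)
  if (is.null(cl_tr) || is.null(cl_va))
    stop("k-means failed on the final clustering")
  pred_va <- knn_predict(E_tr, cl_tr, E_va, cfg$knn_k)
  al <- align_labels(pred_va, cl_va)
  generalization_accuracy <- 1 - al$error
  cl_va_aligned <- al$labels

  # label semantics from mean corrected total of the training clusters
  mean_tot <- tapply(train$total, cl_tr, mean)
  ord <- order(mean_tot, decreasing = TRUE)   # 1st = highest total
  sem <- if (k == 2) c("High", "Low") else paste0("cluster_", seq_len(k))
  semantics <- setNames(sem, names(mean_tot)[ord])

  labels <- rbind(
    data.frame(subject_id = train$subject_id, split = "train",
               cluster = cl_tr,
               subtype = unname(semantics[as.character(cl_tr)])),
    data.frame(subject_id = validation$subject_id, split = "validation",
               cluster = cl_va_aligned,
               subtype = unname(semantics[as.character(cl_va_aligned)])))

  sig <- NULL
  if (sigclust_sims > 0) {
    Z_all <- scale(as.matrix(aut[, c("md", "ac", "bl")]))
    sig <- sigclust_test(Z_all, n_sim = sigclust_sims,
                         seed = substream_seed(cfg$seed, "sigclust"))
  }

  structure(list(best_k = k, curve = sel$curve,
                 generalization_accuracy = generalization_accuracy,
                 labels = labels, label_semantics = semantics,
                 scaler = sel$scaler, umap_model = sel$umap_model,
                 train_embedding = E_tr, train_clusters = cl_tr,
                 validation_embedding = E_va,
                 sigclust = sig, config = cfg,
                 n_train = nrow(train), n_validation = nrow(validation),
                 call = match.call()),
            class = "motor_subtypes")
}

#' @export
print.motor_subtypes <- function(x, ...) {
  cat("Motor subtype model (stability-based relative clustering validation)\n")
  cat(sprintf("  subjects: %d train / %d validation\n", x$n_train, x$n_validation))
  cat(sprintf("  best k: %d (normalized stability %.3f)\n", x$best_k,
              min(x$curve$normalized_stability)))
  cat(sprintf("  generalization accuracy: %.1f%%\n",
              100 * x$generalization_accuracy))
  if (!is.null(x$sigclust))
    cat(sprintf("  Gaussian-null cluster significance: p = %.4g\n",
                x$sigclust$p_value))
  tab <- table(x$labels$subtype)
  cat("  subtype sizes:", paste(sprintf("%s = %d", names(tab), tab),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.motor_subtypes <- function(object, ...) {
  out <- list(best_k = object$best_k, curve = object$curve,
              generalization_accuracy = object$generalization_accuracy,
              sizes = table(object$labels$subtype, object$labels$split),
              sigclust_p = if (!is.null(object$sigclust))
                object$sigclust$p_value else NA_real_)
  class(out) <- "summary.motor_subtypes"
  out
}

#' @export
print.summary.motor_subtypes <- function(x, ...) {
  cat("Normalized stability by candidate k:\n")
  print(x$curve, row.names = FALSE, digits = 3)
  cat(sprintf("\nSelected k = %d; generalization accuracy = %.1f%%\n",
              x$best_k, 100 * x$generalization_accuracy))
  if (!is.na(x$sigclust_p))
    cat(sprintf("Cluster significance vs single-Gaussian null: p = %.4g\n",
                x$sigclust_p))
  cat("\nSubtype sizes by split:\n")
  print(x$sizes)
  invisible(x)
}

#' Predict subtype labels for new subjects
#'
#' Applies the fitted scaler and UMAP transform to new subscale scores and
#' assigns each subject the subtype of its nearest training neighbors
#' (k-NN classifier fit on the training cluster labels).
#'
#' @param object a fitted `motor_subtypes` model.
#' @param newdata data.frame with complete `md`, `ac`, `bl` columns.
#' @param ... unused.
#' @return character vector of subtype labels.
#' @export
predict.motor_subtypes <- function(object, newdata, ...) {
  feats <- as.matrix(newdata[, c("md", "ac", "bl")])
  if (anyNA(feats)) stop("newdata must have complete md, ac, bl scores")
  Z <- scale(feats, object$scaler$center, object$scaler$scale)
  E <- uwot::umap_transform(Z, object$umap_model, n_threads = 1)
  cl <- knn_predict(object$train_embedding, object$train_clusters, E,
                    object$config$knn_k)
  unname(object$label_semantics[as.character(cl)])
}

#' Plot the stability curve and training embedding
#'
#' Left panel: mean normalized stability against candidate k with a
#' one-dispersion band and the selected k marked. Right panel: the 2-D
#' training embedding colored by subtype.
#'
#' @param x a fitted `motor_subtypes` model.
#' @param ... unused.
#' @export
plot.motor_subtypes <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cv <- x$curve
  graphics::plot(cv$k, cv$normalized_stability, type = "b", pch = 19,
                 xlab = "number of clusters k", ylab = "normalized stability",
                 main = "Stability curve",
                 ylim = range(c(cv$normalized_stability - cv$dispersion,
                                cv$normalized_stability + cv$dispersion)))
  graphics::arrows(cv$k, cv$normalized_stability - cv$dispersion,
                   cv$k, cv$normalized_stability + cv$dispersion,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  graphics::abline(v = x$best_k, lty = 2, col = "red")
  subt <- x$labels$subtype[x$labels$split == "train"]
  graphics::plot(x$train_embedding, col = as.integer(factor(subt)) + 1,
                 pch = 19, xlab = "UMAP 1", ylab = "UMAP 2",
                 main = "Training embedding")
  graphics::legend("topright", legend = levels(factor(subt)),
                   col = seq_along(unique(subt)) + 1, pch = 19, bty = "n")
  invisible(x)
}

#' Cluster significance test against a single multivariate Gaussian null
#'
#' Tests whether a 2-cluster structure is stronger than expected from one
#' multivariate Gaussian. The statistic is the 2-means cluster index
#' (within-cluster sum of squares over total sum of squares; smaller =
#' stronger clustering). Null datasets are drawn from a zero-mean Gaussian
#' with diagonal covariance equal to the eigenvalues of the sample
#' covariance, each floored at a background-noise variance estimated as the
#' squared median absolute deviation (MAD, scaled for Gaussian consistency)
#' of all column-centered data entries. The p-value is the Monte-Carlo
#' fraction `(1 + #{null CI <= observed CI}) / (n_sim + 1)`.
#'
#' @param X numeric matrix (n x p), n >= 10.
#' @param n_sim number of null datasets (default 1000; fewer than 100 gives
#'   an unstable p and a warning).
#' @param seed integer seed.
#' @return object of class `sigclust_result` with `cluster_index`,
#'   `null_cluster_index`, `p_value`, `n_sim`, `seed`.
#' @export
sigclust_test <- function(X, n_sim = 1000, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 observations")
  if (n_sim < 100) warning("n_sim < 100 gives an unstable p-value")
  set.seed(seed)
  ci_obs <- cluster_index_2means(X)
  eig <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  centered <- sweep(X, 2, colMeans(X))
  bg <- mad(as.vector(centered))^2
  lam <- pmax(eig, bg)
  ci_null <- vapply(seq_len(n_sim), function(i) {
    Y <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(lam), p)
    cluster_index_2means(Y)
  }, numeric(1))
  structure(list(cluster_index = ci_obs, null_cluster_index = ci_null,
                 p_value = (1 + sum(ci_null <= ci_obs)) / (n_sim + 1),
                 n_sim = n_sim, seed = seed),
            class = "sigclust_result")
}

cluster_index_2means <- function(X) {
  km <- suppressWarnings(kmeans(X, 2, nstart = 20, iter.max = 100))
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  km$tot.withinss / tss
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat("Cluster significance vs single multivariate Gaussian null\n")
  cat(sprintf("  2-means cluster index: %.4f\n", x$cluster_index))
  cat(sprintf("  Monte-Carlo p-value:   %.4g  (%d simulations)\n",
              x$p_value, x$n_sim))
  invisible(x)
}
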