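#' Low-dimensional embedding of methylation samples
#'
#' Classical multidimensional scaling (on Euclidean sample distances) or
#' principal component analysis of samples on M-values, optionally
#' restricted to a DML feature subset. Missing values are imputed with the
#' per-probe mean (count reported via `message()`); coordinates are
#' deterministic up to sign for a fixed algorithm.
#'
#' @param m an `m_matrix` (see [beta_to_m()]) or numeric matrix
#'   probes x samples.
#' @param method `"mds"` or `"pca"`.
#' @param features optional character vector of probe ids to restrict to.
#' @param k number of output dimensions (default 2).
#' @return samples x k coordinate matrix; for PCA the attribute
#'   `"var_explained"` carries the per-component variance fractions.
#' @export
embed_samples <- function(m, method = c("mds", "pca"), features = NULL,
                          k = 2) {
  method <- match.arg(method)
  vals <- if (is.list(m)) m$values else m
  if (!is.null(features)) vals <- vals[features, , drop = FALSE]
  if (ncol(vals) < 3) stop("need at least 3 samples to embed")
  n_na <- sum(is.na(vals))
  if (n_na) {
    message(n_na, " missing values imputed with per-probe means")
    mu <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- mu[idx[, 1]]
  }
  x <- t(vals)
  if (method == "mds") {
    coords <- cmdscale(dist(x), k = k)
  } else {
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(k), drop = FALSE]
    attr(coords, "var_explained") <-
      (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  }
  rownames(coords) <- colnames(vals)
  coords
}

#' Hierarchical clustering of samples on a DML feature set
#'
#' Samples are clustered on Euclidean distances over the supplied feature
#' rows of the M-value matrix. The linkage used is recorded in the result
#' so reports can state it.
#'
#' @param m an `m_matrix` or numeric matrix probes x samples.
#' @param features character vector of probe ids (non-empty).
#' @param linkage linkage method passed to [stats::hclust()]; default
#'   `"complete"`.
#' @return list of class `hier_cluster` with `hclust`, `linkage`,
#'   `features`.
#' @export
hier_cluster <- function(m, features, linkage = "complete") {
  vals <- if (is.list(m)) m$values else m
  if (!length(features)) stop("features must be non-empty")
  if (ncol(vals) < 2) stop("need at least 2 samples to cluster")
  vals <- vals[intersect(features, rownames(vals)), , drop = FALSE]
  hc <- hclust(dist(t(vals)), method = linkage)
  structure(list(hclust = hc, linkage = linkage, features = features),
            class = "hier_cluster")
}

#' One-vs-one random-forest classification of two participant groups
#'
#' Samples of the two groups are split stratified 70/30 into training and
#' held-out sets; a small hyperparameter grid (`ntree` x `mtry`) is tuned
#' by stratified 10-fold cross-validation on the training set; the best
#' model is refit and evaluated on the held-out set. The top 10% of
#' features by Gini importance are reported for downstream combined-model
#' PCA.
#'
#' @param m an `m_matrix` or numeric matrix probes x samples.
#' @param sample_meta data frame with `sample_id` and `group` matching the
#'   matrix columns.
#' @param features character vector of probe ids (the previously called
#'   DML for this pair) used as predictors.
#' @param pair character vector of two group labels.
#' @param seed integer seed controlling the split, folds and forests.
#' @param train_frac training fraction (default 0.7).
#' @param cv_folds number of cross-validation folds (default 10).
#' @param grid data frame of candidate `ntree` / `mtry` combinations;
#'   default trees in \{200, 500\} and mtry in \{sqrt(p), p/3\}.
#' @param min_per_class minimum samples per class (default 4).
#' @return list of class `classifier_report`: `comparison`, `best`,
#'   `cv_accuracy`, `test_accuracy`, `top_features`, `n_train`, `n_test`,
#'   `seed`.
#' @export
classify_one_vs_one <- function(m, sample_meta, features, pair, seed = 1L,
                                train_frac = 0.7, cv_folds = 10,
                                grid = NULL, min_per_class = 4) {
  vals <- if (is.list(m)) m$values else m
  stopifnot(length(pair) == 2)
  keep <- sample_meta$group %in% pair
  y <- factor(sample_meta$group[keep], levels = pair)
  if (any(table(y) < min_per_class))
    stop("each class needs at least ", min_per_class, " samples")
  features <- intersect(features, rownames(vals))
  if (!length(features)) stop("no usable features")
  x <- t(vals[features, keep, drop = FALSE])
  p <- length(features)
  if (is.null(grid))
    grid <- expand.grid(ntree = c(200, 500),
                        mtry = unique(pmax(1, c(floor(sqrt(p)),
                                                floor(p / 3)))))
  set.seed(seed)
  # stratified 70/30 split
  tr <- unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(2, round(train_frac * length(idx))))))
  x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
  x_te <- x[-tr, , drop = FALSE]; y_te <- y[-tr]

  fold_of <- unsplit(lapply(split(seq_along(y_tr), y_tr), function(idx)
    sample(rep_len(seq_len(cv_folds), length(idx)))), y_tr)
  cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    acc <- vapply(seq_len(cv_folds), function(f) {
      if (!any(fold_of == f)) return(NA_real_)
      fit <- randomForest::randomForest(
        x_tr[fold_of != f, , drop = FALSE], y_tr[fold_of != f],
        ntree = grid$ntree[gi], mtry = grid$mtry[gi])
      mean(predict(fit, x_tr[fold_of == f, , drop = FALSE]) ==
             y_tr[fold_of == f])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(cv_acc), , drop = FALSE]

  fit <- randomForest::randomForest(x_tr, y_tr, ntree = best$ntree,
                                    mtry = best$mtry, importance = TRUE)
  test_acc <- mean(predict(fit, x_te) == y_te)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  n_top <- max(1, ceiling(0.10 * length(imp)))
  top_features <- names(sort(imp, decreasing = TRUE))[seq_len(n_top)]

  structure(list(comparison = paste(pair, collapse = "_vs_"),
                 best = best, cv_accuracy = max(cv_acc),
                 test_accuracy = test_acc, top_features = top_features,
                 n_train = length(tr), n_test = length(y_te),
                 seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("one-vs-one classifier:", x$comparison, "\n")
  cat(sprintf("  CV accuracy %.3f (ntree=%d, mtry=%d), held-out %.3f (n=%d)\n",
              x$cv_accuracy, x$best$ntree, x$best$mtry, x$test_accuracy,
              x$n_test))
  cat("  top features:", length(x$top_features), "\n")
  invisible(x)
}
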