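# Pairwise classification of sequences by corpus label from the four
# statistical features, with an exact binomial test of accuracy against the
# no-information rate (NIR).

#' Standardize features and split into training and test sets
#'
#' Splits a two-label feature table into training and test partitions
#' (stratified by label, per-class counts rounded half-up), then z-scores
#' each feature using means and standard deviations fitted on the training
#' partition only.
#'
#' @param features data frame from [feature_table()] or
#'   [generate_labeled_dataset()]; must contain exactly two distinct
#'   `corpus_label` values.
#' @param train_fraction fraction of each class assigned to training. The
#'   default 2/3 is the "67% to 33%" convention.
#' @param seed integer seed for the partition.
#' @param stratified if `FALSE`, split ignores labels.
#' @return list with `train`, `test` (data frames whose feature columns are
#'   z-scored) and `scaling` (`center`, `scale` fitted on training data).
#' @export
standardize_and_split <- function(features, train_fraction = 2 / 3,
                                  seed = 1, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labs <- unique(features$corpus_label)
  if (length(labs) != 2) {
    stop("expected exactly 2 labels, got ", length(labs))
  }
  n <- nrow(features)
  train_idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(labs, function(l) {
        idx <- which(features$corpus_label == l)
        sample(idx, round_half_up(train_fraction * length(idx)))
      }))
    } else {
      sample.int(n, round_half_up(train_fraction * n))
    }
  })
  train <- features[sort(train_idx), , drop = FALSE]
  test <- features[-sort(train_idx), , drop = FALSE]
  for (part in list(train, test)) {
    missing <- setdiff(labs, unique(part$corpus_label))
    if (length(missing) > 0) {
      stop("label absent from a partition: ", paste(missing, collapse = ", "))
    }
  }
  center <- vapply(train[feature_names], mean, numeric(1))
  scale_ <- vapply(train[feature_names], stats::sd, numeric(1))
  if (any(scale_ == 0)) {
    stop(
      "zero-variance feature(s) in training data: ",
      paste(feature_names[scale_ == 0], collapse = ", ")
    )
  }
  rescale <- function(df) {
    df[feature_names] <- sweep(
      sweep(as.matrix(df[feature_names]), 2, center), 2, scale_, "/"
    )
    df
  }
  list(
    train = rescale(train), test = rescale(test),
    scaling = list(center = center, scale = scale_)
  )
}

confusion_stats <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  acc <- mean(truth == pred)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(
    accuracy = acc, precision = prec, recall = rec, f1 = f1,
    n_correct = sum(truth == pred), n_test = length(truth)
  )
}

new_classification_run <- function(family, config, stats, train_labels,
                                   converged = TRUE) {
  run <- c(
    list(family = family, config = config, converged = converged),
    stats,
    list(nir = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_)
  )
  class(run) <- "classification_run"
  accuracy_vs_nir_test(run, train_labels)
}

#' K-nearest-neighbor classification of a corpus pair
#'
#' Majority vote among the `k` nearest training points in Euclidean
#' distance on the standardized features. Vote ties are broken toward the
#' class with the smaller summed distance among the `k` neighbors.
#'
#' @param split result of [standardize_and_split()].
#' @param k neighbor count (must not exceed the training size).
#' @return a `classification_run`: accuracy, precision, recall, F1 (first
#'   label in sort order is the positive class), NIR and the raw one-sided
#'   exact binomial p-value (see [accuracy_vs_nir_test()]).
#' @export
knn_classify <- function(split, k = 5) {
  train <- split$train
  test <- split$test
  if (k > nrow(train)) stop("k exceeds training-set size")
  xtr <- as.matrix(train[feature_names])
  xte <- as.matrix(test[feature_names])
  labs <- sort(unique(train$corpus_label))
  pred <- vapply(seq_len(nrow(xte)), function(i) {
    d <- sqrt(colSums((t(xtr) - xte[i, ])^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(train$corpus_label[nb], levels = labs))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      return(top)
    }
    sums <- vapply(top, function(l) {
      sum(d[nb][train$corpus_label[nb] == l])
    }, numeric(1))
    top[which.min(sums)]
  }, character(1))
  stats <- confusion_stats(test$corpus_label, pred, positive = labs[1])
  new_classification_run("knn", list(k = k), stats, train$corpus_label)
}

#' Sample random MLP architectures and classify a corpus pair
#'
#' Uniformly samples `n_architectures` hidden-layer layouts with depth 1-4
#' layers and width 1-5 units per layer, trains each (see [mlp_fit()]) on
#' the standardized training partition, and evaluates on the test
#' partition. Architectures whose training loss does not plateau are
#' flagged `converged = FALSE`; summaries should exclude them.
#'
#' @param split result of [standardize_and_split()].
#' @param n_architectures number of architectures to sample.
#' @param seed integer seed for sampling and weight initialization.
#' @param max_depth,max_width architecture caps.
#' @param ... passed to [mlp_fit()].
#' @return list of `classification_run`s, one per sampled architecture.
#' @export
mlp_classify <- function(split, n_architectures = 100, seed = 1,
                         max_depth = 4, max_width = 5, ...) {
  train <- split$train
  test <- split$test
  labs <- sort(unique(train$corpus_label))
  ytr <- as.integer(train$corpus_label == labs[2])
  archs <- with_seed(seed, {
    lapply(seq_len(n_architectures), function(i) {
      sample.int(max_width, sample.int(max_depth, 1), replace = TRUE)
    })
  })
  lapply(seq_along(archs), function(i) {
    fit <- mlp_fit(
      as.matrix(train[feature_names]), ytr, archs[[i]],
      seed = seed + i, ...
    )
    pred <- labs[1 + (mlp_predict(fit, as.matrix(test[feature_names])) > 0.5)]
    stats <- confusion_stats(test$corpus_label, pred, positive = labs[1])
    new_classification_run(
      "mlp", list(architecture = archs[[i]]), stats,
      train$corpus_label,
      converged = fit$converged
    )
  })
}

#' Exact binomial test of accuracy against the no-information rate
#'
#' The no-information rate (NIR) is the accuracy of always predicting the
#' training set's majority label. The test treats each correct test label
#' as a success and asks, one-sided, whether the observed success count
#' exceeds what a Binomial(n_test, NIR) would produce.
#'
#' @param run a `classification_run` with `n_correct` and `n_test`.
#' @param train_labels labels of the training partition (defines the NIR).
#' @return the run with `nir` and `p_raw` filled in.
#' @export
accuracy_vs_nir_test <- function(run, train_labels) {
  nir <- max(table(train_labels)) / length(train_labels)
  run$nir <- as.numeric(nir)
  run$p_raw <- stats::binom.test(
    run$n_correct, run$n_test,
    p = run$nir, alternative = "greater"
  )$p.value
  run
}

#' Bonferroni adjustment across classification runs
#'
#' Multiplies each raw p-value by the number of runs (capped at 1), the
#' correction used when many k values or architectures are tested.
#'
#' @param runs list of `classification_run`s.
#' @return the runs with `p_adjusted` filled in.
#' @export
bonferroni_adjust <- function(runs) {
  m <- length(runs)
  stopifnot(m >= 1)
  lapply(runs, function(r) {
    r$p_adjusted <- min(1, r$p_raw * m)
    r
  })
}

#' Summarize a set of classification runs
#'
#' @param runs list of `classification_run`s (after [bonferroni_adjust()]).
#' @param alpha significance level.
#' @return list with accuracy summary over converged runs, the NIR, and the
#'   percentage of converged runs significant after adjustment.
#' @export
summarize_runs <- function(runs, alpha = 0.05) {
  conv <- Filter(function(r) isTRUE(r$converged), runs)
  acc <- vapply(conv, function(r) r$accuracy, numeric(1))
  padj <- vapply(conv, function(r) r$p_adjusted, numeric(1))
  list(
    n_runs = length(runs),
    n_converged = length(conv),
    nir = if (length(conv) > 0) conv[[1]]$nir else NA_real_,
    accuracy_mean = if (length(acc)) mean(acc) else NA_real_,
    accuracy_median = if (length(acc)) stats::median(acc) else NA_real_,
    accuracy_range = if (length(acc)) range(acc) else c(NA_real_, NA_real_),
    pct_significant = if (length(padj)) 100 * mean(padj < alpha) else NA_real_
  )
}

#' Project the feature space onto its first two principal components
#'
#' Correlation-matrix PCA (features z-scored) so loadings are comparable
#' across the mixed-unit features. For a reproducible orientation, each
#' component's sign is fixed so that the loading of unigram entropy is
#' non-negative (falling back to the first nonzero loading if it is zero).
#'
#' @param features feature data frame (any number of labels, >= 3 rows).
#' @return list with `scores` (source_id, corpus_label, PC1, PC2),
#'   `loadings` (4 x 2), and `explained_variance` (fractions, all
#'   components).
#' @export
pca_project <- function(features) {
  if (nrow(features) < 3) stop("need at least 3 points")
  x <- as.matrix(features[feature_names])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance feature(s): ",
      paste(feature_names[sds == 0], collapse = ", ")
    )
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in 1:2) {
    anchor <- pc$rotation["unigram_entropy", j]
    if (anchor == 0) anchor <- pc$rotation[which(pc$rotation[, j] != 0)[1], j]
    if (anchor < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(
    scores = data.frame(
      source_id = features$source_id,
      corpus_label = features$corpus_label,
      PC1 = pc$x[, 1], PC2 = pc$x[, 2],
      stringsAsFactors = FALSE
    ),
    loadings = pc$rotation[, 1:2, drop = FALSE],
    explained_variance = pc$sdev^2 / sum(pc$sdev^2)
  )
}
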