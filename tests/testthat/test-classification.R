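make_split <- function(n = 100, seed = 5) {
  sp <- separated_specs(n = n)
  standardize_and_split(generate_labeled_dataset(sp$a, sp$b), seed = seed)
}

test_that("a 324-point pair splits 216/108 with stratification", {
  # class sizes 213 + 111, the size of the smallest corpus pair
  sp <- list(
    a = corpus_spec(213, 5, 0.6, length_median = 8, label = "A", seed = 1),
    b = corpus_spec(111, 4, 0.7, length_median = 7, label = "B", seed = 2)
  )
  ft <- generate_labeled_dataset(sp$a, sp$b)
  split <- standardize_and_split(ft, seed = 3)
  expect_equal(nrow(split$train), 216)
  expect_equal(nrow(split$test), 108)
  expect_equal(sum(split$train$corpus_label == "A"), 142)
  expect_equal(sum(split$train$corpus_label == "B"), 74)
})

test_that("z-scoring is fitted on the training partition only", {
  split <- make_split()
  for (f in c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")) {
    expect_equal(mean(split$train[[f]]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(split$train[[f]]), 1, tolerance = 1e-9)
  }
  # the test partition is scaled with the training parameters, so its
  # moments need not be exactly 0/1
  expect_false(isTRUE(all.equal(mean(split$test$ttr), 0, tolerance = 1e-12)))
})

test_that("splits are reproducible and validate their inputs", {
  sp <- separated_specs(n = 40)
  ft <- generate_labeled_dataset(sp$a, sp$b)
  s1 <- standardize_and_split(ft, seed = 11)
  s2 <- standardize_and_split(ft, seed = 11)
  expect_identical(s1$train$source_id, s2$train$source_id)
  expect_error(standardize_and_split(ft[ft$corpus_label == "A", ]), "2 labels")
})

test_that("1-NN returns the label of a coincident training point", {
  split <- make_split(n = 60)
  # plant a test point exactly on a training point
  split$test[1, c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")] <-
    split$train[1, c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")]
  split$test$corpus_label[1] <- split$train$corpus_label[1]
  run <- knn_classify(split, k = 1)
  expect_gte(run$accuracy, 1 / nrow(split$test)) # the planted point is correct
  expect_error(knn_classify(split, k = nrow(split$train) + 1), "exceeds")
})

test_that("KNN separates well-separated synthetic regimes", {
  split <- make_split(n = 100)
  run <- knn_classify(split, k = 5)
  expect_gte(run$accuracy, 0.9)
  expect_lt(run$p_raw, 0.001)
})

test_that("in-package KNN agrees with class::knn at odd k", {
  skip_if_not_installed("class")
  split <- make_split(n = 80, seed = 21)
  xtr <- as.matrix(split$train[c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")])
  xte <- as.matrix(split$test[c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")])
  for (k in c(1, 5, 9)) {
    ours <- knn_classify(split, k = k)
    ref <- class::knn(xtr, xte, cl = split$train$corpus_label, k = k)
    ref_acc <- mean(as.character(ref) == split$test$corpus_label)
    expect_equal(ours$accuracy, ref_acc, info = paste("k =", k))
  }
})

test_that("performance statistics match a hand-computed confusion matrix", {
  # truth:    A A A A B B B B B B
  # pred:     A A B A B B B A B B
  truth <- c(rep("A", 4), rep("B", 6))
  pred <- c("A", "A", "B", "A", "B", "B", "B", "A", "B", "B")
  st <- signstats:::confusion_stats(truth, pred, positive = "A")
  expect_equal(st$accuracy, 8 / 10)
  expect_equal(st$precision, 3 / 4) # 3 true A of 4 predicted A
  expect_equal(st$recall, 3 / 4) # 3 of 4 real A recovered
  expect_equal(st$f1, 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4))
})

test_that("the NIR binomial test is exact and one-sided", {
  run <- structure(
    list(n_correct = 60, n_test = 100, nir = NA_real_, p_raw = NA_real_),
    class = "classification_run"
  )
  # NIR 0.5 from balanced training labels
  run <- accuracy_vs_nir_test(run, rep(c("A", "B"), 50))
  expect_equal(run$nir, 0.5)
  expect_equal(run$p_raw, sum(stats::dbinom(60:100, 100, 0.5)), tolerance = 1e-12)
  expect_equal(round(run$p_raw, 4), 0.0284)

  # observed accuracy equal to the NIR is unremarkable
  run2 <- structure(
    list(n_correct = 66, n_test = 100, nir = NA_real_, p_raw = NA_real_),
    class = "classification_run"
  )
  run2 <- accuracy_vs_nir_test(run2, c(rep("A", 66), rep("B", 34)))
  expect_gt(run2$p_raw, 0.05)

  # perfect accuracy on 108 test points against NIR 0.66
  run3 <- structure(
    list(n_correct = 108, n_test = 108, nir = NA_real_, p_raw = NA_real_),
    class = "classification_run"
  )
  run3 <- accuracy_vs_nir_test(run3, c(rep("A", 66), rep("B", 34)))
  expect_lt(run3$p_raw, 1e-15)
})

test_that("Bonferroni adjustment multiplies by the run count and caps at 1", {
  mk <- function(p) {
    structure(list(p_raw = p, converged = TRUE), class = "classification_run")
  }
  runs <- bonferroni_adjust(c(replicate(99, mk(0.5), simplify = FALSE), list(mk(0.01))))
  expect_equal(runs[[100]]$p_adjusted, 1) # 0.01 * 100, capped
  runs2 <- bonferroni_adjust(c(replicate(99, mk(0.5), simplify = FALSE), list(mk(1e-6))))
  expect_equal(runs2[[100]]$p_adjusted, 1e-4)
  expect_equal(bonferroni_adjust(list(mk(0.03)))[[1]]$p_adjusted, 0.03)
})

test_that("sampled MLP architectures respect the depth and width caps", {
  split <- make_split(n = 40)
  runs <- mlp_classify(split, n_architectures = 12, seed = 31, max_epochs = 200)
  expect_lte(length(runs), 12)
  for (r in runs) {
    arch <- r$config$architecture
    expect_lte(length(arch), 4)
    expect_gte(length(arch), 1)
    expect_true(all(arch >= 1 & arch <= 5))
  }
  # identical seeds give identical architecture samples
  runs2 <- mlp_classify(split, n_architectures = 12, seed = 31, max_epochs = 200)
  expect_identical(
    lapply(runs, function(r) r$config$architecture),
    lapply(runs2, function(r) r$config$architecture)
  )
})

test_that("MLPs learn a separable problem and plateau detection works", {
  split <- make_split(n = 80)
  runs <- bonferroni_adjust(mlp_classify(split, n_architectures = 10, seed = 17))
  s <- summarize_runs(runs)
  expect_gte(s$n_converged, 1)
  expect_gte(s$accuracy_median, 0.95)
})

test_that("in-package MLP matches nnet on a depth-1 architecture", {
  skip_if_not_installed("nnet")
  split <- make_split(n = 80, seed = 13)
  fn <- c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")
  ytr <- as.integer(split$train$corpus_label == "B")
  fit <- mlp_fit(as.matrix(split$train[fn]), ytr, hidden = 3, seed = 2)
  ours <- mean((mlp_predict(fit, as.matrix(split$test[fn])) > 0.5) ==
    (split$test$corpus_label == "B"))
  nn <- nnet::nnet(as.matrix(split$train[fn]), ytr,
    size = 3, trace = FALSE, maxit = 500
  )
  theirs <- mean((predict(nn, as.matrix(split$test[fn])) > 0.5) ==
    (split$test$corpus_label == "B"))
  expect_gte(ours, 0.9)
  expect_gte(theirs, 0.9)
})

test_that("PCA projection is orthonormal, ordered, and sign-stabilized", {
  sp <- separated_specs(n = 80)
  ft <- generate_labeled_dataset(sp$a, sp$b)
  pr <- pca_project(ft)
  ev <- pr$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_gte(min(ev), 0)
  expect_equal(sum(ev), 1)
  expect_equal(crossprod(pr$loadings), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_gte(pr$loadings["unigram_entropy", 1], 0)
  # centroids of the two regimes separate strongly along PC1
  c1 <- mean(pr$scores$PC1[pr$scores$corpus_label == "A"])
  c2 <- mean(pr$scores$PC1[pr$scores$corpus_label == "B"])
  pooled <- stats::sd(pr$scores$PC1)
  expect_gt(abs(c1 - c2) / pooled, 1) # > 2 pooled within-group sd
  w1 <- stats::sd(pr$scores$PC1[pr$scores$corpus_label == "A"])
  w2 <- stats::sd(pr$scores$PC1[pr$scores$corpus_label == "B"])
  expect_gt(abs(c1 - c2), 2 * sqrt((w1^2 + w2^2) / 2))

  ft$ttr <- 0.5 # zero-variance feature is refused by name
  expect_error(pca_project(ft), "ttr")
})

test_that("KNN power is monotone in regime separation", {
  rho_b <- c(0.55, 0.3, 0.05) # separation from rho_a = 0.7 increases
  med_acc <- vapply(seq_along(rho_b), function(j) {
    accs <- vapply(1:10, function(s) {
      a <- corpus_spec(60, 6, 0.7, length_median = 12, label = "A", seed = 1000 + 10 * j + s)
      b <- corpus_spec(60, 6, rho_b[j], length_median = 12, label = "B", seed = 2000 + 10 * j + s)
      split <- standardize_and_split(generate_labeled_dataset(a, b), seed = s)
      knn_classify(split, k = 5)$accuracy
    }, numeric(1))
    stats::median(accs)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= 0))
})
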