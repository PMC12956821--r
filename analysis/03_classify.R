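#!/usr/bin/env Rscript
# Step 3: pairwise classification of corpora from the four features.
# For each pair: a 67/33 stratified split, a KNN sweep over odd k and a
# random sweep of small MLP architectures, accuracies tested against the
# no-information rate with Bonferroni correction. Also exports the PCA
# projection of the pooled feature space.

library(signstats)

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)
pairs <- list(
  c("SignRows", "EarlyTablets"),
  c("SignRows", "ModernText"),
  c("EarlyTablets", "ModernText")
)

rows <- list()
for (pair in pairs) {
  sub <- features[features$corpus_label %in% pair, ]
  split <- standardize_and_split(sub, seed = 41)
  knn_runs <- bonferroni_adjust(
    lapply(seq(1, 25, 2), function(k) knn_classify(split, k = k))
  )
  mlp_runs <- bonferroni_adjust(
    mlp_classify(split, n_architectures = 25, seed = 42)
  )
  s_knn <- summarize_runs(knn_runs)
  s_mlp <- summarize_runs(mlp_runs)
  cat(sprintf(
    "%s vs %s (NIR %.2f):\n  KNN  median acc %.3f, %5.1f%% significant\n  MLP  median acc %.3f, %5.1f%% significant (%d/%d converged)\n",
    pair[1], pair[2], s_knn$nir,
    s_knn$accuracy_median, s_knn$pct_significant,
    s_mlp$accuracy_median, s_mlp$pct_significant,
    s_mlp$n_converged, s_mlp$n_runs
  ))
  for (fam in c("knn", "mlp")) {
    runs <- if (fam == "knn") knn_runs else mlp_runs
    rows <- c(rows, lapply(runs, function(r) {
      data.frame(
        pair = paste(pair, collapse = " vs "), family = r$family,
        config = paste(unlist(r$config), collapse = "-"),
        converged = r$converged, accuracy = r$accuracy, nir = r$nir,
        p_raw = r$p_raw, p_adjusted = r$p_adjusted
      )
    }))
  }
}
write.table(do.call(rbind, rows), "results/classification_runs.csv",
  sep = ",", row.names = FALSE, quote = TRUE
)

pr <- pca_project(features)
write.table(pr$scores, "results/pca_scores.csv",
  sep = ",", row.names = FALSE, quote = TRUE
)
cat(sprintf(
  "\nPCA: PC1 %.0f%%, PC2 %.0f%% of variance; scores in results/pca_scores.csv\n",
  100 * pr$explained_variance[1], 100 * pr$explained_variance[2]
))
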