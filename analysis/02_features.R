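#!/usr/bin/env Rscript
# Step 2: parse the simulated corpora and compute the four per-sequence
# statistics (unigram entropy H, entropy rate h, TTR, repetition rate r).
# Writes results/features.csv and prints per-corpus medians; the modern-
# text corpus is subsampled to at most 1,000 lines before featurizing.

library(signstats)

data_dir <- "results/data"
stopifnot(dir.exists(data_dir)) # run 01_simulate.R first

all_seqs <- list()
for (f in c("signrows.csv", "earlytablets.csv", "moderntext.csv")) {
  parsed <- parse_records(read_corpus_table(file.path(data_dir, f)))
  seqs <- parsed$sequences
  if (parsed$report$n_dropped_empty > 0) {
    cat(sprintf(
      "%s: dropped %d empty sequence(s) during preprocessing\n",
      f, parsed$report$n_dropped_empty
    ))
  }
  if (length(seqs) > 1000) seqs <- subsample_corpus(seqs, 1000, seed = 31)
  all_seqs <- c(all_seqs, seqs)
}

features <- feature_table(all_seqs)
write.table(features, "results/features.csv",
  sep = ",", row.names = FALSE, quote = TRUE
)

cat("\nPer-corpus medians (H, h in bits/sign):\n")
for (lab in unique(features$corpus_label)) {
  sub <- features[features$corpus_label == lab, ]
  cat(sprintf(
    "  %-13s n=%4d  len=%4.0f  H=%.2f  h=%.2f  TTR=%.2f  r=%.2f\n",
    lab, nrow(sub), median(sub$n_tokens), median(sub$unigram_entropy),
    median(sub$entropy_rate), median(sub$ttr), median(sub$repetition_rate)
  ))
}
cat("\nThe repetitive sign-row regime shows low entropies with high\n")
cat("repetition rates; the text-like regime the reverse.\n")
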