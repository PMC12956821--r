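# signstats

Statistical fingerprints of symbol sequences: are rows of abstract signs on
Paleolithic mobile artifacts statistically more like writing — early tablet
notations, modern text — or unlike it?

`signstats` is for researchers in quantitative semiotics, cultural
evolution and computational linguistics who want to compare corpora of
short symbol sequences. It parses three sequence notations into token
sequences, computes four statistics per sequence, classifies corpus pairs
from those features with significance testing against a no-information
baseline, and fits AIC-ranked linear models predicting a sequence's
information density from artifact metadata. A seeded synthetic-data
generator makes every stage testable offline.

## The feature space

For a sequence of $n$ sign tokens over $m$ types with frequencies $f_i$:

| statistic | definition | meaning |
|---|---|---|
| TTR | $m/n$ | type diversity baseline |
| unigram entropy $\hat H$ | $-\sum_i \frac{f_i}{n}\log_2\frac{f_i}{n}$ | diversity weighted by the type distribution (bits/sign) |
| entropy rate $\hat h$ | $\frac{1}{n}\sum_{i=2}^{n}\frac{\log_2 i}{L_i}$ | sequential predictability; $L_i$ is 1 + the longest match into the prefix $1..i-1$ (increasing-window LZ78 estimator) |
| repetition rate $r$ | $r_{\mathrm{adj}}/(n-1)$ | fraction of adjacent identical sign pairs (`lsmo` variant; a `sproat` variant normalizing by $\sum_i(f_i-1)$ is available) |

Writing-like corpora sit at high entropies and low repetition rates;
repetitive sign rows at the opposite corner.

## Worked example

```r
library(signstats)

aur <- parse_aurignacian("XX_vvvvvvvv_vvvv") # cross, notches, group marks
fv <- compute_feature_vector(aur)
round(unlist(fv[1:4]), 2)
#> unigram_entropy    entropy_rate             ttr repetition_rate
#>            1.06            1.04            0.19            0.73

uruk <- parse_protocuneiform("N14 N14 _ N01 N01 N01 _ UDU~a")
round(unlist(compute_feature_vector(uruk)[1:4]), 2)
#> unigram_entropy    entropy_rate             ttr repetition_rate
#>            1.91            1.37            0.50            0.43
```

The sign row's 16 tokens collapse to 3 types (TTR 0.19), and its heavy
adjacent repetition (r = 0.73) drags the entropy rate down to about 1
bit/sign — the profile typical of repetitive marking sequences, not of
text. The tablet line, with numerical notation expanded (`3(N01)` →
`N01 N01 N01`) and underscores kept as group tokens, is already more
diverse.

The `analysis/` scripts run the full study pipeline on synthetic corpora
(generate → featurize → classify → regress), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_features.R
Rscript analysis/03_classify.R
Rscript analysis/04_regress.R
```

Step 2 prints per-corpus medians, e.g. a repetitive sign-row regime at
`H = 1.50, h = 1.18, TTR = 0.43, r = 0.57` against a text-like regime at
`H = 4.19, h = 2.90, TTR = 0.71, r = 0.02`; step 3 separates those two
regimes at median KNN/MLP accuracy ≈ 0.99 (100% of runs significant
against a no-information rate of 0.82 after Bonferroni correction), while
two overlapping regimes stay non-significant; step 4's AIC ladder
recovers the injected object-type effect.

Real corpora enter through the same interfaces: delimited tables of raw
records (`source_id, corpus_label, dialect, raw`) read by
`read_corpus_table()` / `parse_records()`, or a YAML-configured
`run_pipeline()`.

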