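---
title: "Statistical fingerprints of symbol sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical fingerprints of symbol sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signstats)
```

## The problem

Mobile artifacts of the European Upper Paleolithic carry rows of abstract
signs — notches, crosses, lines — that have repeatedly been proposed as
precursors of writing. Whether such rows behave statistically like writing
is an empirical question: genuine writing systems, from protocuneiform
tablets to modern alphabets, occupy a characteristic region of a small
feature space built from information-theoretic and lexical statistics.
`signstats` implements that feature space and the two inferential stages
built on it: pairwise corpus classification with significance testing
against a no-information baseline, and linear models predicting a
sequence's information density from properties of the object that carries
it.

The package operates on *token sequences*: ordered vectors of sign-type
identifiers. Three input notations are supported, each with its own
cleaning rules (character-level sign rows with annotation markup;
whitespace-separated sign-name transliterations with `k(SIGN)` repetition
notation; plain text lines where every UTF-8 character, including internal
whitespace, is a sign). A group-separator token `"_"` marks visual groups
or different faces of one object and is deliberately treated as an
ordinary token in every statistic.

## The four statistics

For a sequence $s = (t'_1, \dots, t'_n)$ with $n$ tokens over $m$ distinct
types with type frequencies $f_i$:

* **Type-token ratio** $\mathrm{TTR} = m/n \in (0, 1]$ — a
  lexical-diversity baseline.
* **Unigram entropy** $\hat H = -\sum_i \hat p_i \log_2 \hat p_i$ with the
  maximum-likelihood plug-in $\hat p_i = f_i / n$, in bits/sign, bounded by
  $\log_2 m$. Only the ML estimator is provided: smoothing estimators are
  strongly correlated with it on language-like data and would add a tuning
  dimension without adding discrimination.
* **Entropy rate**, estimated by the increasing-window LZ78 estimator
  $$\hat h = \frac{1}{n}\sum_{i=2}^{n} \frac{\log_2 i}{L_i},$$
  where $L_i$ is one plus the length of the longest contiguous subsequence
  starting at position $i$ that also occurs *entirely within* positions
  $1..i-1$. Matching is token-exact; the containment rule (a match may not
  extend past position $i-1$) is what the printed worked values pin down.
  The estimator penalizes sequential redundancy that unigram statistics
  cannot see, and is known to overestimate the rate of short repetitive
  sequences because late windows cannot find long matches; no bias
  correction is applied, and `convergence_profile()` exposes the
  stabilization behavior instead.
* **Repetition rate**: the count $r_{\mathrm{adj}}$ of positions with
  $t'_j = t'_{j+1}$, normalized either by $\sum_i (f_i - 1)$ (the `sproat`
  variant) or by $n - 1$ (the modified `lsmo` variant, the default — the
  `sproat` denominator saturates on type-diverse sequences, e.g. giving 1
  for `aabcd`).

Degenerate inputs follow fixed conventions so the features are total:
a single-token sequence has entropy rate 0 and repetition rate 0, and a
zero `sproat` denominator yields 0. All logarithms are base 2; values are
rounded (to 2 decimals) only at presentation, never internally.

The longest-match search is the computational core and is implemented in
C++ (an $O(n^2)$ scan); the test suite holds it to *exact* agreement with
an independent brute-force all-substrings scan in R.

## The synthetic-data generator

No corpus data ships with the package; every downstream stage is
exercised on generated data with known structure. `generate_sign_corpus()`
draws from a first-order Markov source: with probability $\rho$
(`self_repeat_prob`) the previous token is repeated, otherwise a different
type is drawn uniformly. This is the simplest source whose
adjacent-repetition rate is directly the parameter $\rho$, which makes
calibration checks sharp (mean `lsmo` rate of long sequences converges to
$\rho$). Sequence lengths follow a shifted negative binomial (shift 2, so
every sequence has at least one adjacent pair to evaluate) whose median is
matched to a target; the defaults span the observed regime of median
lengths, roughly 7 for early tablet corpora through 28 for modern text
lines. Dispersion `length_size = 3` gives the right-skewed length profile
typical of such corpora.

`generate_artifact_metadata()` samples object type (6 levels, reference
`tool`), material (reference `antler`), site (reference
`Geissenkloesterle`), preservation (3 levels, reference `almost_complete`),
lognormal volumes in cm³ and uniform dates in 30,000–40,000 BP, and builds
the response as a user-specified additive linear predictor plus Gaussian
noise — exactly the model family the regression stage fits, so parameter
recovery is testable against known truth.

What the generator does *not* emulate: realistic sign-type frequency
profiles, autocorrelation beyond first order, length–feature dependence,
or any correlation between a sequence's content and its metadata beyond
the injected linear effects. Passing tests therefore demonstrate that the
machinery is correct and calibrated, not that any archaeological
conclusion holds; conclusions about real corpora require the deposited
data, which the pipeline accepts through the same CSV interfaces.

## Classification protocol

Pairs of corpora are split 2/3 training to 1/3 test ("67% to 33%"),
stratified by label with per-class counts rounded half-up; the 2/3
reading, rather than a literal 0.67, is what makes a 213 + 111 pair split
exactly 216/108. Features are z-scored with training-set parameters only.

*KNN* uses Euclidean distance on the standardized features, with an odd-k
default grid (1, 3, ..., 25); vote ties — possible only at even k — are
broken toward the class with the smaller summed neighbor distance. *MLP*
sweeps randomly sampled feedforward architectures (depth 1–4, width 1–5),
trained full-batch by Adam (learning rate 0.02) on the cross-entropy loss
with tanh hidden units and a logistic output; a run is converged when its
training loss changes by less than $10^{-4}$ over 50 epochs within a
2,000-epoch cap, and non-converged runs are flagged and excluded from
summaries rather than erroring. These small dense nets are implemented in
the package and cross-checked against `nnet` for depth-1 architectures.

Accuracy is tested against the **no-information rate** — the training
set's majority-class fraction — with a one-sided *exact* binomial test
(test sets run down to about a hundred points, where the normal
approximation is dubious; the exact tail sum is the documented choice).
With many runs per pair, p-values are Bonferroni-multiplied by the run
count and capped at 1, and summaries report the percentage significant at
$\alpha = 0.05$.

`pca_project()` uses the correlation-matrix convention (z-scored
features), so loadings are comparable across the mixed-unit features, and
fixes each component's sign so the unigram-entropy loading is
non-negative — PCA orientation is otherwise arbitrary and would flip
between runs.

## Regression protocol

Models are ordinary least squares with treatment coding; the intercept is
the response mean at the reference levels. The model ladder is built in a
fixed theoretical order — continuous predictors (volume, date) first, then
object type, then one alternative categorical predictor at a time, then
interaction variants — and ranked by AIC (Gaussian likelihood including
constants; only differences are interpreted, and the ordering, not the
absolute values, is the assertion). Rank-deficient designs are refused
with the collinear terms named rather than silently dropped.

Effect size for a predictor is the **semipartial $R^2$**: the drop in
$R^2$ when the term is removed from the full model. Its uncertainty is a
nonparametric bootstrap over rows (1,000 replicates by default) reported
as a one-sided interval $[q_{0.05}, 1]$ — matching the one-sided form in
which such effect sizes are conventionally reported; the percentile
bootstrap is a documented choice, not an assertion about how any
published interval was built. Diagnostics (Shapiro–Wilk normality,
Breusch–Pagan homoscedasticity, |residual|-vs-fitted correlation) are
flags, never hard failures; a near-zero residual variance short-circuits
to a degenerate-fit warning, and intercept-only models skip the
Breusch–Pagan test, which needs a regressor.

Responses other than entropy rate can be modeled by passing a different
feature column name; entropy rate is the default because it reflects both
type diversity and sequential structure.

## Numerical and scale choices

Problem sizes in the test suite are chosen to make each statistical check
sharp but quick: calibration loops use 40–50 replicates at 100–400
observations, the oracle-equivalence sweep uses 200 random sequences up to
length 64 over alphabets of 2–8 types, and the i.i.d. convergence check
uses 20 sequences of 2,000 tokens. Seeds are fixed everywhere; generator
outputs are byte-identical under equal specs and seeds, and seeded helpers
restore the caller's RNG state.

Two published-example caveats the implementation makes explicit: the
worked unigram-entropy fractions for the 7-token morpho-syllabic example
evaluate to 2.52 bits/sign (its printed row), not to the 2.89 printed next
to them, which is the value of the 54-token stroke sequence — the tests
assert each number against the sequence it belongs to. And since that
7-token example line itself is not published, the acceptance tests use a
synthetic structural stand-in (`aabcdef`: 7 tokens, 6 types, one adjacent
doubling) that reproduces every one of its published feature values.

## Limitations

* The entropy-rate estimator's short-sequence bias is reported, not
  corrected; comparisons across corpora with very different length
  profiles should be read with the convergence profiles in hand.
* Classification is strictly pairwise; no multiclass protocol is offered.
* The MLP sweep is a fixed-recipe randomized architecture search, not
  hyperparameter optimization.
* The regression stage models sequence-level features from object-level
  metadata with ordinary least squares only; no mixed effects for sites,
  no spatial structure.
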