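#' Maximum-likelihood type probabilities
#'
#' Plug-in estimate of the sign-type distribution of one sequence:
#' `p(t) = f_t / n`, the relative frequency of each type.
#'
#' @param seq a [token_sequence] or character vector of tokens.
#' @return named numeric vector of probabilities over the vocabulary,
#'   summing to 1.
#' @examples
#' type_probabilities(c("a", "a", "b")) # a = 2/3, b = 1/3
#' @export
type_probabilities <- function(seq) {
  toks <- as_tokens(seq)
  if (length(toks) == 0) stop("empty sequence")
  tab <- table(toks)
  stats::setNames(as.numeric(tab) / length(toks), names(tab))
}

#' Type-token ratio
#'
#' Number of distinct sign types divided by the number of sign tokens,
#' `m / n`, in (0, 1]. A lexical-diversity baseline.
#'
#' @inheritParams type_probabilities
#' @return fraction in (0, 1].
#' @examples
#' ttr(strsplit("XX_vvvvvvvv_vvvv", "")[[1]]) # 3/16
#' @export
ttr <- function(seq) {
  toks <- as_tokens(seq)
  if (length(toks) == 0) stop("empty sequence")
  length(unique(toks)) / length(toks)
}

#' Unigram entropy (bits per sign)
#'
#' Shannon entropy of the maximum-likelihood type distribution,
#' `H = -sum p(t) log2 p(t)`. Bounded above by `log2(m)` for a sequence with
#' `m` types (attained at the uniform distribution).
#'
#' @inheritParams type_probabilities
#' @return entropy in bits/sign, >= 0.
#' @export
unigram_entropy <- function(seq) {
  p <- type_probabilities(seq)
  -sum(p * log2(p))
}

#' Increasing-window entropy-rate estimate (bits per sign)
#'
#' LZ78-style estimator of the entropy rate of a finite sequence:
#' \deqn{\hat h = \frac{1}{n} \sum_{i=2}^{n} \frac{\log_2 i}{L_i},}
#' where `L_i` is one plus the length of the longest contiguous subsequence
#' starting at position `i` that also occurs entirely within positions
#' `1..i-1` (the "prefix"). Repetitive structure yields long matches, a large
#' denominator, and hence a low rate; the estimator overestimates for short
#' repetitive sequences because late windows cannot extend past the end.
#'
#' A sequence of length 1 returns 0 by convention.
#'
#' @inheritParams type_probabilities
#' @return estimated entropy rate in bits/sign, >= 0.
#' @examples
#' entropy_rate_lz78(c("N01", "N01", "N01")) # ~0.43
#' @export
entropy_rate_lz78 <- function(seq) {
  toks <- as_tokens(seq)
  n <- length(toks)
  if (n == 0) stop("empty sequence")
  if (n == 1) {
    return(0)
  }
  ids <- match(toks, unique(toks))
  m <- .lz78_match_lengths(ids) # match length at positions 2..n
  sum(log2(2:n) / (m + 1)) / n
}

#' Adjacent-repetition rate
#'
#' Counts positions where a token equals its successor (`r_adj`). The
#' `sproat` variant normalizes by the number of possible repetitions,
#' `sum_i (f_i - 1) = n - m`; the modified `lsmo` (length-minus-one) variant
#' normalizes by `n - 1`. Both lie in [0, 1]; for sequences with many
#' unique types the `sproat` variant is inflated (e.g. "aabcd" gives 1)
#' while `lsmo` stays low (0.25). Zero-denominator cases (single-token
#' sequences; all-unique sequences under `sproat`) return 0.
#'
#' @inheritParams type_probabilities
#' @param variant `"lsmo"` (default) or `"sproat"`.
#' @return fraction in [0, 1].
#' @examples
#' repetition_rate(strsplit("aabcd", "")[[1]]) # 0.25
#' repetition_rate(strsplit("aabcd", "")[[1]], "sproat") # 1
#' @export
repetition_rate <- function(seq, variant = c("lsmo", "sproat")) {
  variant <- match.arg(variant)
  toks <- as_tokens(seq)
  n <- length(toks)
  if (n == 0) stop("empty sequence")
  if (n == 1) {
    return(0)
  }
  r_adj <- sum(toks[-n] == toks[-1])
  denom <- if (variant == "lsmo") n - 1 else n - length(unique(toks))
  if (denom == 0) {
    return(0)
  }
  r_adj / denom
}

#' Compute the four-feature vector of a sequence
#'
#' Assembles unigram entropy, entropy rate, type-token ratio and repetition
#' rate — the coordinates used for classification and ordination.
#'
#' @inheritParams repetition_rate
#' @return object of class `feature_vector`: a list with `unigram_entropy`,
#'   `entropy_rate`, `ttr`, `repetition_rate`, `repetition_variant`,
#'   `n_tokens`, `n_types`.
#' @examples
#' fv <- compute_feature_vector(c("N01", "N01", "N01"))
#' round(unlist(fv[1:4]), 2) # 0, 0.43, 0.33, 1
#' @export
compute_feature_vector <- function(seq, variant = c("lsmo", "sproat")) {
  variant <- match.arg(variant)
  toks <- as_tokens(seq)
  structure(
    list(
      unigram_entropy = unigram_entropy(toks),
      entropy_rate = entropy_rate_lz78(toks),
      ttr = ttr(toks),
      repetition_rate = repetition_rate(toks, variant),
      repetition_variant = variant,
      n_tokens = length(toks),
      n_types = length(unique(toks))
    ),
    class = "feature_vector"
  )
}

feature_names <- c("unigram_entropy", "entropy_rate", "ttr", "repetition_rate")

#' Feature table for a list of sequences
#'
#' One row per sequence: identifiers, token/type counts, and the four
#' statistics.
#'
#' @param sequences list of [token_sequence].
#' @param variant repetition-rate variant, see [repetition_rate()].
#' @return data frame with columns `source_id`, `corpus_label`, `n_tokens`,
#'   `n_types`, `unigram_entropy`, `entropy_rate`, `ttr`, `repetition_rate`.
#' @export
feature_table <- function(sequences, variant = c("lsmo", "sproat")) {
  variant <- match.arg(variant)
  rows <- lapply(sequences, function(s) {
    fv <- compute_feature_vector(s, variant)
    data.frame(
      source_id = s$source_id,
      corpus_label = s$corpus_label,
      n_tokens = fv$n_tokens,
      n_types = fv$n_types,
      unigram_entropy = fv$unigram_entropy,
      entropy_rate = fv$entropy_rate,
      ttr = fv$ttr,
      repetition_rate = fv$repetition_rate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Entropy-rate convergence profile
#'
#' Evaluates the increasing-window estimator on every prefix of the sequence
#' (window lengths 2..n), for qualitative stabilization diagnostics: short
#' repetitive sequences show the estimator's upward bias, long sequences
#' stabilize. The final profile value equals [entropy_rate_lz78()] of the
#' whole sequence.
#'
#' @inheritParams type_probabilities
#' @return data frame with columns `window` and `entropy_rate`.
#' @export
convergence_profile <- function(seq) {
  toks <- as_tokens(seq)
  n <- length(toks)
  if (n == 0) stop("empty sequence")
  if (n == 1) {
    return(data.frame(window = integer(0), entropy_rate = numeric(0)))
  }
  ids <- match(toks, unique(toks))
  m <- .lz78_match_lengths(ids) # uncapped match length at positions 2..n
  lg <- log2(2:n)
  h <- vapply(2:n, function(k) {
    i <- 2:k
    # within a window of length k the match starting at i is capped at k-i+1
    sum(lg[i - 1] / (pmin(m[i - 1], k - i + 1) + 1)) / k
  }, numeric(1))
  data.frame(window = 2:n, entropy_rate = h)
}
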