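#' Specification of a synthetic sign corpus
#'
#' Describes a first-order Markov source over a small vocabulary: with
#' probability `self_repeat_prob` (rho) the previous token is repeated,
#' otherwise a different token is drawn uniformly. This is the simplest
#' source whose adjacent-repetition rate is directly controlled by a single
#' parameter. Sequence lengths follow a shifted negative binomial whose
#' median is set to `length_median` — nonnegative and right-skewed like the
#' observed corpora, whose median lengths range from about 7 (early tablet
#' periods) to about 28 tokens (modern text lines). Optionally, group
#' separators `"_"` are interleaved at rate `group_separator_rate`.
#'
#' @param n_sequences number of sequences to generate.
#' @param vocabulary_size number of sign types (>= 1), excluding `"_"`.
#' @param self_repeat_prob probability rho in [0, 1] of repeating the
#'   previous sign.
#' @param length_median target median sequence length in tokens.
#' @param length_size negative-binomial dispersion (smaller = more skewed).
#' @param group_separator_rate probability of emitting `"_"` at each
#'   position after the first.
#' @param label corpus label attached to every sequence.
#' @param seed integer seed; identical specs and seeds give identical output.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_sequences, vocabulary_size, self_repeat_prob,
                        length_median = 10, length_size = 3,
                        group_separator_rate = 0, label = "synthetic",
                        seed = 1) {
  stopifnot(
    n_sequences >= 1, vocabulary_size >= 1,
    self_repeat_prob >= 0, self_repeat_prob <= 1,
    group_separator_rate >= 0, group_separator_rate <= 1,
    length_median >= 2
  )
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      vocabulary_size = as.integer(vocabulary_size),
      self_repeat_prob = self_repeat_prob,
      length_median = length_median,
      length_size = length_size,
      group_separator_rate = group_separator_rate,
      label = label,
      seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

# Smallest negative-binomial mean whose (shifted) median hits the target.
nb_mu_for_median <- function(median_target, size, shift = 2) {
  target <- median_target - shift
  if (target <= 0) {
    return(1e-8)
  }
  lo <- 1e-6
  hi <- max(4 * target, 2)
  while (stats::qnbinom(0.5, size = size, mu = hi) < target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (stats::qnbinom(0.5, size = size, mu = mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Generate a corpus of synthetic sign sequences
#'
#' Draws `n_sequences` token sequences from the first-order source described
#' by `spec` (see [corpus_spec()]). The expected adjacent-repetition rate of
#' long sequences equals `self_repeat_prob` when no separators are emitted.
#'
#' @param spec a [corpus_spec()].
#' @return list of [token_sequence], with source ids `<label>_0001`, ...
#' @examples
#' seqs <- generate_sign_corpus(corpus_spec(5, 4, 0.5, seed = 7))
#' length(seqs) # 5
#' @export
generate_sign_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- sprintf("s%02d", seq_len(spec$vocabulary_size))
  mu <- nb_mu_for_median(spec$length_median, spec$length_size)
  with_seed(spec$seed, {
    lens <- 2 + stats::rnbinom(spec$n_sequences, size = spec$length_size, mu = mu)
    lapply(seq_len(spec$n_sequences), function(j) {
      n <- lens[j]
      toks <- character(n)
      toks[1] <- sample(vocab, 1)
      for (i in seq_len(n - 1) + 1) {
        prev <- toks[i - 1]
        if (spec$group_separator_rate > 0 &&
          stats::runif(1) < spec$group_separator_rate) {
          toks[i] <- "_"
        } else if (prev != "_" &&
          (spec$vocabulary_size == 1 ||
            stats::runif(1) < spec$self_repeat_prob)) {
          toks[i] <- prev
        } else {
          pool <- setdiff(vocab, prev)
          if (length(pool) == 0) pool <- vocab
          toks[i] <- if (length(pool) == 1) pool else sample(pool, 1)
        }
      }
      token_sequence(toks, spec$label, sprintf("%s_%04d", spec$label, j))
    })
  })
}

# Reference factor levels for artifact metadata (reference level first).
artifact_levels <- list(
  object_type = c(
    "tool", "anthropomorph_figurine", "zoomorph_figurine",
    "tube_flute", "personal_ornament", "other"
  ),
  material = c("antler", "ivory", "bone", "stone"),
  site = c("Geissenkloesterle", "Hohle_Fels", "Vogelherd"),
  preservation = c("almost_complete", "fragmented", "complete")
)

#' Specification of synthetic artifact metadata
#'
#' Describes per-object predictors (object type, material, site,
#' preservation, volume in cm3, maximum date BP) together with an
#' `effect_map` of additive shifts on the response (the sequence's entropy
#' rate): named factor-level shifts like `object_type.zoomorph_figurine`,
#' plus `volume` and `max_date` slopes and an `intercept`. The response is
#' the linear predictor plus Gaussian noise.
#'
#' @param n_objects number of artifacts.
#' @param effect_map named list of additive effects; unnamed effects are 0.
#' @param noise_sd residual standard deviation (> 0).
#' @param level_probs optional named list of level probabilities per factor
#'   (defaults to uniform over the declared levels).
#' @param volume_meanlog,volume_sdlog lognormal volume parameters (cm3).
#' @param date_range range of maximum dates, years BP.
#' @param seed integer seed.
#' @return object of class `metadata_spec`.
#' @export
metadata_spec <- function(n_objects, effect_map = list(intercept = 1),
                          noise_sd = 0.2, level_probs = NULL,
                          volume_meanlog = 2, volume_sdlog = 1,
                          date_range = c(30000, 40000), seed = 1) {
  stopifnot(n_objects >= 1, noise_sd > 0)
  probs <- lapply(artifact_levels, function(lv) {
    rep(1 / length(lv), length(lv))
  })
  if (!is.null(level_probs)) {
    for (nm in names(level_probs)) {
      p <- level_probs[[nm]]
      stopifnot(
        nm %in% names(probs),
        length(p) == length(artifact_levels[[nm]]),
        abs(sum(p) - 1) < 1e-8
      )
      probs[[nm]] <- p
    }
  }
  structure(
    list(
      n_objects = as.integer(n_objects),
      effect_map = effect_map,
      noise_sd = noise_sd,
      level_probs = probs,
      volume_meanlog = volume_meanlog,
      volume_sdlog = volume_sdlog,
      date_range = date_range,
      seed = as.integer(seed)
    ),
    class = "metadata_spec"
  )
}

effect_of <- function(effect_map, key) {
  if (!is.null(effect_map[[key]])) effect_map[[key]] else 0
}

#' Generate synthetic artifact metadata with a linear response
#'
#' Samples factor levels, volumes and dates per [metadata_spec()], and
#' builds the response `entropy_rate` as the additive linear predictor from
#' `effect_map` plus Gaussian noise — the structure assumed by the
#' regression stage, so that coefficient recovery can be tested against
#' known truth.
#'
#' @param spec a [metadata_spec()].
#' @return data frame with `source_id`, the four factors (treatment-coded
#'   factors with the declared reference levels first), `volume`,
#'   `max_date`, and `entropy_rate`; the true linear predictor is kept in
#'   attribute `"linear_predictor"`.
#' @export
generate_artifact_metadata <- function(spec) {
  stopifnot(inherits(spec, "metadata_spec"))
  with_seed(spec$seed, {
    n <- spec$n_objects
    fac <- lapply(names(artifact_levels), function(nm) {
      lv <- artifact_levels[[nm]]
      factor(sample(lv, n, replace = TRUE, prob = spec$level_probs[[nm]]),
        levels = lv
      )
    })
    names(fac) <- names(artifact_levels)
    volume <- stats::rlnorm(n, spec$volume_meanlog, spec$volume_sdlog)
    max_date <- stats::runif(n, spec$date_range[1], spec$date_range[2])
    em <- spec$effect_map
    lp <- rep(effect_of(em, "intercept"), n) +
      effect_of(em, "volume") * volume +
      effect_of(em, "max_date") * max_date
    for (nm in names(artifact_levels)) {
      shifts <- vapply(as.character(fac[[nm]]), function(lev) {
        effect_of(em, paste(nm, lev, sep = "."))
      }, numeric(1))
      lp <- lp + unname(shifts)
    }
    out <- data.frame(
      source_id = sprintf("obj_%04d", seq_len(n)),
      fac,
      volume = volume,
      max_date = max_date,
      entropy_rate = lp + stats::rnorm(n, 0, spec$noise_sd),
      stringsAsFactors = FALSE
    )
    attr(out, "linear_predictor") <- lp
    out
  })
}

#' Generate a labeled two-corpus feature dataset
#'
#' Generates both corpora, computes the four-feature table for each, and
#' concatenates them — the input shape expected by the classification stage.
#'
#' @param spec_a,spec_b two [corpus_spec()]s with distinct labels.
#' @return feature data frame (see [feature_table()]) for both corpora.
#' @export
generate_labeled_dataset <- function(spec_a, spec_b) {
  stopifnot(
    inherits(spec_a, "corpus_spec"), inherits(spec_b, "corpus_spec")
  )
  if (identical(spec_a$label, spec_b$label)) {
    stop("corpus labels must be distinct")
  }
  rbind(
    feature_table(generate_sign_corpus(spec_a)),
    feature_table(generate_sign_corpus(spec_b))
  )
}
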