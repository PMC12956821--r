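# Independent oracles and shared fixtures, deliberately naive: the
# entropy-rate oracle scans all candidate substrings in O(n^3) and never
# shares code with the package's matcher.

oracle_match_length <- function(toks, i) {
  n <- length(toks)
  best <- 0
  for (len in seq_len(n - i + 1)) {
    sub <- toks[i:(i + len - 1)]
    found <- FALSE
    if (i - len >= 1) {
      for (st in seq_len(i - len)) {
        if (all(toks[st:(st + len - 1)] == sub)) {
          found <- TRUE
          break
        }
      }
    }
    if (found) best <- len else break
  }
  best
}

oracle_entropy_rate <- function(toks) {
  n <- length(toks)
  if (n < 2) {
    return(0)
  }
  total <- 0
  for (i in 2:n) {
    total <- total + log2(i) / (oracle_match_length(toks, i) + 1)
  }
  total / n
}

random_tokens <- function(n, alphabet_size) {
  sample(letters[seq_len(alphabet_size)], n, replace = TRUE)
}

chars <- function(x) strsplit(x, "")[[1]]

# The seven example sequences with their printed statistics (2 d.p.).
# The morpho-syllabic (Chinese) example line is not published; "aabcdef" is a
# synthetic structural stand-in that matches every printed cell of that row
# (7 tokens, 6 types, one adjacent doubling).
table1_rows <- list(
  basque = list(
    tokens = chars("Mila esker maitea"),
    n_tokens = 17, n_types = 11, H = 3.29, h = 2.19, TTR = 0.65, r = 0
  ),
  chinese_standin = list(
    tokens = chars("aabcdef"),
    n_tokens = 7, n_types = 6, H = 2.52, h = 1.69, TTR = 0.86, r = 0.17
  ),
  chinese_strokes = list(
    tokens = chars("etao etao aieeeaetn eaaieeeeto taieetso oodtshn etasee"),
    n_tokens = 54, n_types = 10, H = 2.89, h = 1.99, TTR = 0.19, r = 0.17
  ),
  uruk3 = list(
    tokens = c("N01", "_", "NAGA~a", "_", "DU", "_", "PAP~a"),
    n_tokens = 7, n_types = 5, H = 2.13, h = 1.43, TTR = 0.71, r = 0
  ),
  uruk4 = list(
    tokens = c("N14", "N14", "_", "N01", "N01", "N01", "_", "UDU~a"),
    n_tokens = 8, n_types = 4, H = 1.91, h = 1.37, TTR = 0.5, r = 0.43
  ),
  uruk5 = list(
    tokens = c("N01", "N01", "N01"),
    n_tokens = 3, n_types = 1, H = 0, h = 0.43, TTR = 0.33, r = 1
  ),
  aurignacian = list(
    tokens = chars("XX_vvvvvvvv_vvvv"),
    n_tokens = 16, n_types = 3, H = 1.06, h = 1.04, TTR = 0.19, r = 0.73
  )
)

# Two clearly distinct synthetic regimes used by classification tests:
# short, repetitive, small-vocabulary vs. long, diverse, low-repetition.
separated_specs <- function(n = 100, seed_a = 101, seed_b = 202) {
  list(
    a = corpus_spec(n, 5, 0.7, length_median = 15, label = "A", seed = seed_a),
    b = corpus_spec(n, 40, 0.05, length_median = 30, label = "B", seed = seed_b)
  )
}

write_demo_corpus_csv <- function(path, rows) {
  utils::write.table(rows, path,
    sep = ",", row.names = FALSE, quote = TRUE,
    fileEncoding = "UTF-8"
  )
  path
}
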