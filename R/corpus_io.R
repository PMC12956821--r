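#' Parse an Aurignacian sign string
#'
#' Cleans one sign row from a mobile-artifact database and tokenizes it into
#' single UTF-8 characters. Cleaning removes (a) annotation marks such as
#' `"!"` (broken piece), (b) spans in round brackets (signs that are not
#' visually discrete), and (c) spans in square brackets (signs not in linear
#' order). Underscores separate different parts of an object and are kept as
#' ordinary tokens.
#'
#' @param raw UTF-8 string with annotation markup.
#' @param corpus_label,source_id carried onto the result.
#' @return A [token_sequence], or `NULL` (with a catchable
#'   `signstats_empty_sequence` warning) if nothing survives cleaning.
#' @examples
#' parse_aurignacian("XX_vvvvvvvv_vvvv")$n_tokens # 16
#' parse_aurignacian("X(v)[v]v")$tokens # "X" "v"
#' @export
parse_aurignacian <- function(raw, corpus_label = "Aurignacian",
                              source_id = NA_character_) {
  stopifnot(is.character(raw), length(raw) == 1)
  chars <- strsplit(raw, "", fixed = FALSE)[[1]]
  kept <- character(0)
  open <- NA_character_ # currently open bracket, if any
  for (ch in chars) {
    if (ch %in% c("(", "[")) {
      if (!is.na(open)) {
        stop_malformed_record(source_id, "nested or overlapping brackets")
      }
      open <- ch
    } else if (ch %in% c(")", "]")) {
      want <- if (ch == ")") "(" else "["
      if (is.na(open) || open != want) {
        stop_malformed_record(source_id, sprintf("unbalanced '%s'", ch))
      }
      open <- NA_character_
    } else if (is.na(open) && ch != "!" && !grepl("^\\s$", ch)) {
      kept <- c(kept, ch)
    }
  }
  if (!is.na(open)) {
    stop_malformed_record(source_id, sprintf("unclosed '%s'", open))
  }
  if (length(kept) == 0) {
    signal_empty_sequence(source_id)
    return(NULL)
  }
  token_sequence(kept, corpus_label, source_id)
}

# Default annotation characters stripped from protocuneiform sign names:
# damage/uncertainty marks of transliteration conventions. The tilde variant
# marker (e.g. UDU~a) is part of the sign name and is never stripped.
proto_annotation_chars <- "[#?!*\\[\\]]"

#' Parse a protocuneiform transliteration line
#'
#' Tokens are whitespace-separated sign names (e.g. `N01`, `N14`, `UDU~a`).
#' Numerical repetition notation `k(SIGN)` expands to `k` adjacent copies of
#' `SIGN`. Standalone underscores mark visual sign groups and are kept as
#' tokens. Configurable annotation characters are stripped from sign names.
#'
#' @param raw transliteration string.
#' @param corpus_label,source_id carried onto the result.
#' @param annotation_pattern regex character class removed from each token.
#' @return A [token_sequence], or `NULL` with a `signstats_empty_sequence`
#'   warning.
#' @examples
#' parse_protocuneiform("3(N01)")$tokens # "N01" "N01" "N01"
#' parse_protocuneiform("N14 N14 _ N01 N01 N01 _ UDU~a")$n_types # 4
#' @export
parse_protocuneiform <- function(raw, corpus_label = "Uruk",
                                 source_id = NA_character_,
                                 annotation_pattern = proto_annotation_chars) {
  stopifnot(is.character(raw), length(raw) == 1)
  pieces <- strsplit(trimws(raw), "\\s+")[[1]]
  pieces <- gsub(annotation_pattern, "", pieces, perl = TRUE)
  pieces <- pieces[nzchar(pieces)]
  out <- character(0)
  for (tok in pieces) {
    if (grepl("[()]", tok)) {
      m <- regmatches(tok, regexec("^([0-9]+)\\(([^()]+)\\)$", tok))[[1]]
      if (length(m) != 3) {
        stop_malformed_record(
          source_id,
          sprintf("bad repetition notation '%s'", tok)
        )
      }
      k <- as.integer(m[2])
      out <- c(out, rep(m[3], k))
    } else {
      out <- c(out, tok)
    }
  }
  if (length(out) == 0) {
    signal_empty_sequence(source_id)
    return(NULL)
  }
  token_sequence(out, corpus_label, source_id)
}

#' Parse a modern-text line into character tokens
#'
#' Each UTF-8 character is one sign token, including internal whitespace.
#' Unicode punctuation is removed; if `script_charset` is supplied, any
#' non-whitespace character outside it is removed as well (characters not
#' part of the writing system). Case is preserved: upper and lower case are
#' distinct types.
#'
#' @param raw text line.
#' @param corpus_label,source_id carried onto the result.
#' @param script_charset optional character vector of characters that belong
#'   to the writing system.
#' @return A [token_sequence], or `NULL` with a `signstats_empty_sequence`
#'   warning.
#' @examples
#' parse_modern_text("Mila esker maitea")$n_types # 11
#' parse_modern_text("a.")$tokens # "a"
#' @export
parse_modern_text <- function(raw, corpus_label = "Modern",
                              source_id = NA_character_,
                              script_charset = NULL) {
  stopifnot(is.character(raw), length(raw) == 1)
  chars <- strsplit(raw, "")[[1]]
  is_space <- grepl("^\\s$", chars)
  keep <- !grepl("^\\p{P}$", chars, perl = TRUE)
  if (!is.null(script_charset)) {
    keep <- keep & (is_space | chars %in% script_charset)
  }
  chars <- chars[keep]
  is_space <- is_space[keep]
  # trim boundary whitespace; internal whitespace tokens stay
  inner <- which(!is_space)
  if (length(inner) == 0) {
    signal_empty_sequence(source_id)
    return(NULL)
  }
  chars <- chars[inner[1]:inner[length(inner)]]
  token_sequence(chars, corpus_label, source_id)
}

#' Parse a table of raw sequence records
#'
#' Dispatches each row to the parser selected by its `dialect` column
#' (`aurignacian`, `protocuneiform`, or `modern_text`). Sequences that are
#' empty after cleaning are excluded and counted in the preprocessing
#' report rather than silently lost.
#'
#' @param records data frame with columns `source_id`, `corpus_label`,
#'   `dialect`, `raw`.
#' @param script_charset passed to [parse_modern_text()].
#' @return list with `sequences` (list of [token_sequence]) and `report`
#'   (`n_input`, `n_kept`, `n_dropped_empty`, `dropped_ids`).
#' @export
parse_records <- function(records, script_charset = NULL) {
  need <- c("source_id", "corpus_label", "dialect", "raw")
  if (!all(need %in% names(records))) {
    stop(
      "`records` must have columns ",
      paste(setdiff(need, names(records)), collapse = ", ")
    )
  }
  dropped <- character(0)
  seqs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    res <- withCallingHandlers(
      switch(as.character(row$dialect),
        aurignacian = parse_aurignacian(row$raw, row$corpus_label, row$source_id),
        protocuneiform = parse_protocuneiform(row$raw, row$corpus_label, row$source_id),
        modern_text = parse_modern_text(row$raw, row$corpus_label, row$source_id,
          script_charset = script_charset
        ),
        stop("unknown dialect: ", row$dialect)
      ),
      signstats_empty_sequence = function(w) {
        dropped <<- c(dropped, as.character(row$source_id))
        invokeRestart("muffleWarning")
      }
    )
    seqs[[i]] <- res
  }
  seqs <- Filter(Negate(is.null), seqs)
  list(
    sequences = seqs,
    report = list(
      n_input = nrow(records),
      n_kept = length(seqs),
      n_dropped_empty = length(dropped),
      dropped_ids = dropped
    )
  )
}

#' Read a delimited table of raw sequence records
#'
#' Accepts CSV or TSV (by file extension) with columns `source_id`,
#' `corpus_label`, `dialect`, `raw`.
#'
#' @param path file path.
#' @return data frame of raw records.
#' @export
read_corpus_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
    comment.char = ""
  )
}

#' Write cleaned token sequences to a delimited table
#'
#' One row per sequence; tokens joined by `token_delim`.
#'
#' @param sequences list of [token_sequence].
#' @param path output file (CSV by default, TSV if extension is `.tsv`).
#' @param token_delim delimiter placed between tokens.
#' @export
write_token_table <- function(sequences, path, token_delim = " ") {
  df <- data.frame(
    source_id = vapply(sequences, function(s) s$source_id, character(1)),
    corpus_label = vapply(sequences, function(s) s$corpus_label, character(1)),
    n_tokens = vapply(sequences, function(s) s$n_tokens, integer(1)),
    n_types = vapply(sequences, function(s) s$n_types, integer(1)),
    tokens = vapply(sequences, function(s) {
      paste(s$tokens, collapse = token_delim)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path,
    sep = sep, row.names = FALSE, quote = TRUE,
    fileEncoding = "UTF-8"
  )
  invisible(df)
}

#' Serialize a token sequence to its dialect's canonical text
#'
#' Character dialects (`aurignacian`, `modern_text`) concatenate tokens;
#' `protocuneiform` joins sign names with single spaces. Re-parsing the
#' canonical text reproduces the tokens exactly.
#'
#' @param seq a [token_sequence].
#' @param dialect one of `"aurignacian"`, `"protocuneiform"`, `"modern_text"`.
#' @return single string.
#' @export
sequence_to_text <- function(seq, dialect) {
  toks <- as_tokens(seq)
  switch(dialect,
    aurignacian = ,
    modern_text = paste(toks, collapse = ""),
    protocuneiform = paste(toks, collapse = " "),
    stop("unknown dialect: ", dialect)
  )
}

#' Subsample a corpus of sequences
#'
#' Uniform sample without replacement of `min(n_target, length(sequences))`
#' sequences, reproducible under `seed`. Used to balance corpora of very
#' different sizes (e.g. subsamples of 1,000 tablets per period).
#'
#' @param sequences list of [token_sequence].
#' @param n_target number of sequences wanted.
#' @param seed integer seed.
#' @return list of sampled sequences, in sampled order.
#' @export
subsample_corpus <- function(sequences, n_target, seed) {
  stopifnot(n_target >= 1)
  n <- min(n_target, length(sequences))
  idx <- with_seed(seed, sample.int(length(sequences), n))
  sequences[idx]
}
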