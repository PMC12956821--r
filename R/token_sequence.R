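#' Construct a token sequence
#'
#' A token sequence is the unit of analysis: an ordered vector of sign-type
#' identifiers from one object (or text line), plus its corpus label and
#' source id. The group-separator token `"_"` is an ordinary token and enters
#' all statistics.
#'
#' @param tokens character vector of sign tokens, length >= 1.
#' @param corpus_label corpus the sequence belongs to (e.g. "Aurignacian").
#' @param source_id identifier of the originating object or line.
#' @return An object of class `token_sequence` with fields `tokens`,
#'   `corpus_label`, `source_id`, `n_tokens`, `vocabulary`, `n_types`.
#' @examples
#' ts <- token_sequence(c("N01", "N01", "N01"), "UrukV", "tab1")
#' ts$n_types # 1
#' @export
token_sequence <- function(tokens, corpus_label = NA_character_,
                           source_id = NA_character_) {
  if (!is.character(tokens) || length(tokens) < 1 || anyNA(tokens)) {
    stop("`tokens` must be a non-empty character vector without NA")
  }
  if (any(!nzchar(tokens))) {
    stop("`tokens` must not contain empty strings")
  }
  vocab <- unique(tokens)
  structure(
    list(
      tokens = tokens,
      corpus_label = as.character(corpus_label),
      source_id = as.character(source_id),
      n_tokens = length(tokens),
      vocabulary = vocab,
      n_types = length(vocab)
    ),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf(
    "<token_sequence> %s [%s]: %d tokens, %d types\n  %s\n",
    x$source_id, x$corpus_label, x$n_tokens, x$n_types,
    paste(utils::head(x$tokens, 30), collapse = " ")
  ))
  invisible(x)
}

is_token_sequence <- function(x) inherits(x, "token_sequence")

as_tokens <- function(x) {
  if (is_token_sequence(x)) x$tokens else as.character(x)
}
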