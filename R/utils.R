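#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Condition constructors: empty-after-cleaning is a signalled (catchable)
# warning, malformed markup is an error naming the offending record.
signal_empty_sequence <- function(source_id) {
  warning(structure(
    class = c("signstats_empty_sequence", "warning", "condition"),
    list(
      message = sprintf(
        "sequence '%s' is empty after cleaning and was dropped",
        source_id
      ),
      call = NULL,
      source_id = source_id
    )
  ))
}

stop_malformed_record <- function(source_id, detail) {
  stop(structure(
    class = c("signstats_malformed_record", "error", "condition"),
    list(
      message = sprintf("malformed record '%s': %s", source_id, detail),
      call = NULL,
      source_id = source_id
    )
  ))
}

round_half_up <- function(x) floor(x + 0.5)
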