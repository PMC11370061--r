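#' Derive a reproducible per-stage seed from a global seed
#'
#' Fans one global integer seed out into independent named substreams, so that
#' changing the number of random draws in one pipeline stage does not perturb
#' any other stage.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + (h %% 100000) + 7L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
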