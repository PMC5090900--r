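# Condition helpers: every user-facing failure carries a class so callers
# (and the pipeline runner, which maps them to exit codes) can dispatch on it.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "aartools_format_error", ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = "aartools_argument_error", ...)
}

abort_lookup <- function(msg, ...) {
  rlang::abort(msg, class = "aartools_lookup_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "aartools_config_error", ...)
}

abort_undefined <- function(msg, ...) {
  rlang::abort(msg, class = "aartools_undefined_error", ...)
}

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes plus `X` for an ambiguous
#' residue. `X` is accepted in sequences but never counts as a match in
#' identity or scan computations.
#'
#' @return Character vector of allowed residue letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

habitat_levels <- function() c("marine", "freshwater", "both", "unknown")

`%||%` <- function(x, y) if (is.null(x)) y else x
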