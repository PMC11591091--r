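# shared helpers: errors, name normalization, seed threading

dk_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "dk_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Normalize a food name for matching
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Derive a child seed from a base seed and a stream label; stays < 2^31.
dk_child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
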