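#' @keywords internal
"_PACKAGE"

## Imports used across the package
#' @importFrom stats fft predict rnorm runif setNames coef
#' @importFrom utils head read.delim write.table modifyList
NULL

# Stop with a message composed sprintf-style.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical (lexicographic) orientation of a drug pair; vectorised.
canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

# Single pair key used throughout: "a||b" in canonical order.
pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "||")
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
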