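#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up in absolute value
#' (5.5 -> 6, not banker's rounding). Used wherever a count or a reported
#' percentage is rounded, so that e.g. 44.65 prints as 44.7.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 32-bit substream seed from a base seed and string/integer keys.
# Simple multiplicative mixing; collisions are irrelevant at our key counts.
derive_seed <- function(seed, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(paste(k, collapse = "")) else as.integer(k)
  }))
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# position key used throughout the set algebra
pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
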