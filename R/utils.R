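# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when reporting ratios and percentages so that printed values match
#' exact integer arithmetic (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive an independent RNG seed for a labelled output stream from a master
# seed, so adding one generated file never perturbs the others. Kept < 2^31.
stream_seed <- function(master, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 104729L
  (abs(as.integer(master)) %% 1000003L) * 2039L + h
}

# 1-based inclusive -> 0-based half-open (BED) and back.
to_bed_start <- function(start1) as.integer(start1) - 1L
to_bed_end <- function(end1) as.integer(end1)
from_bed_start <- function(start0) as.integer(start0) + 1L
from_bed_end <- function(end0) as.integer(end0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
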