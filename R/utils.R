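#' Round half away from zero
#'
#' Conventional "schoolbook" rounding used throughout the kinetics tables:
#' ties are rounded away from zero (so -1.95 rounds to -2.0 at one decimal),
#' unlike [base::round()]'s round-half-even. A tiny absolute guard absorbs
#' binary floating-point representation error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(-1.95, 1)  # -2.0
#' round_half_away(0.25, 1)   # 0.3
#' @export
round_half_away <- function(x, digits = 0L) {
  scale <- 10^digits
  out <- sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
  out[x == 0] <- 0
  out
}

#' Derive a reproducible substream seed
#'
#' All stochastic stages draw their seeds from one master seed plus a fixed
#' stream offset, so replicates use independent but reproducible streams.
#'
#' @param master_seed integer master seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(master_seed, stream = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  # keep well inside 32-bit integer range
  as.integer((as.double(master_seed) + 100003 * as.double(stream)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
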