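#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when reporting stocking densities,
#' camera-to-cow ratios and percentage metrics: 8.85 rounds to 8.9, not 8.8.
#' Base R's [round()] rounds half to even, which disagrees with printed farm
#' summary tables on exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(8.85, 1)   # 8.9
#' round_half_up(17.857, 1) # 17.9
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  v <- abs(x) * f
  # guard against binary representation error just below a .5 boundary
  sign(x) * floor(v + 0.5 + v * 1e-12 + 1e-12) / f
}

#' Derive a stage-specific seed from a master seed
#'
#' All pipeline randomness flows from one master seed. Each named stage gets a
#' deterministic 31-bit sub-seed so stages can be rerun independently while
#' remaining exactly reproducible.
#'
#' @param seed master seed, a single integer.
#' @param stage stage name, one of the pipeline stage labels.
#' @return an integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # simple multiplicative mix over the stage name's bytes, kept within 31 bits
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# internal: stop with the offending field named
stop_field <- function(field, msg) {
  stop(sprintf("field '%s': %s", field, msg), call. = FALSE)
}
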