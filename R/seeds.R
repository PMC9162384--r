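#' Derive a per-stage child seed from one master seed
#'
#' Every stochastic stage of the pipeline (cohort tables, time series,
#' clinical scores, permutation null, ...) seeds its own RNG stream with a
#' child seed derived deterministically from the master seed and a stage
#' name, so stages can be re-run individually and still reproduce a full
#' pipeline run bit for bit.
#'
#' The scheme is a Lehmer step modulo the Mersenne prime 2^31 - 1 applied to
#' the master seed plus a fixed per-stage offset (the sum of the stage
#' name's character codes); results always fit in a 32-bit integer.
#'
#' @param seed master seed, a single finite integer-valued number
#' @param stage character scalar naming the stage
#' @return an integer seed in [1, 2^31 - 2]
#' @export
#' @examples
#' derive_seed(42, "regional_tables")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  m <- 2147483647               # 2^31 - 1
  off <- sum(utf8ToInt(stage))
  x <- (abs(as.numeric(seed)) + off) %% m
  x <- (x * 48271) %% m         # Lehmer / MINSTD multiplier
  x <- (x * 48271 + 11) %% m
  as.integer(x %% (m - 2) + 1)
}
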