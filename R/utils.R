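# Shared helpers: deterministic rounding, seed substreams, error classes.

#' Round half away from zero
#'
#' Deterministic round-half-up, used wherever printed tables are
#' reproduced (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Integer index from a time in seconds: round-half-up of t * fs, so that
# adjacent half-open segments tile a recording without gap or overlap.
sample_index <- function(t_s, sample_rate) {
  as.integer(floor(t_s * sample_rate + 0.5))
}

# Derive a reproducible substream seed (< 2^31) from a base seed and a
# stream label, so audio / rating / cohort fixtures can be regenerated
# independently of one another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483647L)
}

sca_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "swallowCA_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
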