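# Published reference values for preterm neonates on thin fluids
# (cohort of 80 from three special-care nurseries). These serve as
# generator set-points and as inputs to the reproducible percentage
# computations.

#' Reference presence counts for the preterm cohort
#'
#' Consensus-rating presence counts of the perceptual swallow-sound
#' parameters in a reference cohort of 80 preterm neonates on thin
#' fluids. `n_rateable` is the available-case denominator: one pre-swallow
#' normal-breathing consensus rating was `cannot_be_determined`, so its
#' denominator is 79. The coordination rows count the rule-classified
#' coordinated/uncoordinated swallows.
#'
#' @return `data.frame` with `phase, parameter, n_present, n_rateable`.
#' @export
preterm_reference_counts <- function() {
  pre <- data.frame(
    phase = "pre",
    parameter = BREATH_SOUND_PARAMETERS,
    n_present = c(62L, 14L, 0L, 12L, 0L, 26L, 16L, 0L, 0L),
    n_rateable = c(79L, 80L, 80L, 80L, 80L, 80L, 80L, 80L, 80L),
    stringsAsFactors = FALSE
  )
  during <- data.frame(
    phase = "during",
    parameter = SWALLOW_SOUND_PARAMETERS,
    n_present = c(76L, 80L, 71L, 79L, 80L, 79L, 80L),
    n_rateable = 80L,
    stringsAsFactors = FALSE
  )
  post <- data.frame(
    phase = "post",
    parameter = BREATH_SOUND_PARAMETERS,
    n_present = c(45L, 16L, 0L, 7L, 0L, 33L, 24L, 5L, 1L),
    n_rateable = 80L,
    stringsAsFactors = FALSE
  )
  coord <- data.frame(
    phase = "coordination",
    parameter = c("coordinated", "uncoordinated"),
    n_present = c(65L, 15L),
    n_rateable = 80L,
    stringsAsFactors = FALSE
  )
  rbind(pre, during, post, coord)
}

#' Reference acoustic and cohort set-points for preterm neonates
#'
#' Cohort means and standard deviations used as defaults by the
#' synthetic-data generator: per-swallow acoustic parameters on thin
#' fluids (duration, peak frequency, peak amplitude, peak power) and
#' gestational-age covariates, plus the published positive correlation
#' (r = 0.24) between peak amplitude and the number of medical
#' conditions.
#'
#' @return named list of set-points.
#' @export
preterm_reference_setpoints <- function() {
  list(
    duration_s = c(mean = 0.85, sd = 0.31),
    peak_frequency_hz = c(mean = 1678.3, sd = 413.5),
    peak_amplitude_db = c(mean = 89.67, sd = 1.1),
    peak_power_db = c(mean = 80.83, sd = 4.8),
    birth_gestation_weeks = c(mean = 33.4, sd = 2.6, min = 25, max = 36),
    chronological_gestation_weeks = c(mean = 37, sd = 1.6, min = 34, max = 43),
    amplitude_conditions_r = 0.24,
    n_neonates = 80L
  )
}
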