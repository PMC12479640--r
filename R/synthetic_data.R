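# Synthetic fixtures with analytic ground truth: tonal swallow bursts in
# noise, 2-minute feeding sessions with annotation tables, two-rater
# rating tables, and whole cohorts with a controllable
# comorbidity-amplitude correlation. Realistic swallow physiology is a
# non-goal: the tonal-burst model keeps every ground truth closed-form.

# Truncated-normal draws by inverse CDF (deterministic sample count,
# no rejection loop).
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate one synthetic swallow burst
#'
#' A sum of fixed-frequency tones with random phases plus white Gaussian
#' background noise, quantized to integer PCM. Tone `i` has peak
#' amplitude `amplitude * sqrt(rel_power_i)`, so `rel_power` reads as the
#' fraction of the burst's tonal power (must sum to at most 1). An
#' optional fraction of samples is saturated at full scale to exercise
#' clip handling.
#'
#' @param duration_s burst length in seconds (cohort mean: 0.85 s).
#' @param tones `data.frame` with `freq_hz` and `rel_power`
#'   (default: a single tone at the cohort mean peak frequency 1678.3 Hz).
#' @param amplitude peak tonal amplitude in quantization units.
#' @param noise_db background noise level, dB re 1 LSB (sd of the
#'   Gaussian noise = `10^(noise_db/20)` LSB); `-Inf` for no noise.
#' @param clip_fraction fraction of samples saturated at full scale.
#' @param sample_rate Hz (study standard 44100).
#' @param bit_depth PCM bit depth.
#' @param seed integer seed (deterministic output for a fixed spec+seed).
#' @return list with `signal` (an [audio_signal()]) and `truth`: the
#'   construction ground truth (`peak_frequency_target_hz` = frequency
#'   below which 95% of tonal power lies, `peak_amplitude_db`,
#'   `tone_power`, `n_clipped`).
#' @export
synth_swallow <- function(duration_s = 0.85,
                          tones = data.frame(freq_hz = 1678.3, rel_power = 1),
                          amplitude = 20000, noise_db = 20,
                          clip_fraction = 0, sample_rate = 44100,
                          bit_depth = 16, seed = 1) {
  if (sum(tones$rel_power) > 1 + 1e-12) {
    sca_error("tone rel_power must sum to at most 1", "swallowCA_bad_parameter")
  }
  if (any(tones$freq_hz >= sample_rate / 2)) {
    sca_error("tone frequencies must be below the Nyquist frequency", "swallowCA_bad_parameter")
  }
  if (clip_fraction < 0 || clip_fraction >= 1) {
    sca_error("clip_fraction must lie in [0, 1)", "swallowCA_bad_parameter")
  }
  set.seed(derive_seed(seed, "audio"))

  n <- as.integer(floor(duration_s * sample_rate + 0.5))
  t <- (0:(n - 1)) / sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(tones))) {
    a_i <- amplitude * sqrt(tones$rel_power[i])
    x <- x + a_i * sin(2 * pi * tones$freq_hz[i] * t + stats::runif(1, 0, 2 * pi))
  }
  if (is.finite(noise_db)) {
    x <- x + stats::rnorm(n, 0, 10^(noise_db / 20))
  }
  full_scale <- 2^(bit_depth - 1) - 1
  x <- pmin(pmax(round(x), -full_scale), full_scale)

  n_clip <- as.integer(floor(clip_fraction * n + 0.5))
  if (n_clip > 0) {
    idx <- sample.int(n, n_clip)
    s <- sign(x[idx]); s[s == 0] <- 1
    x[idx] <- s * full_scale
  }

  ord <- order(tones$freq_hz)
  cum <- cumsum(tones$rel_power[ord]) / sum(tones$rel_power)
  target <- tones$freq_hz[ord][which(cum >= 0.95 - 1e-12)[1]]

  sig <- audio_signal(x, sample_rate, bit_depth)
  list(
    signal = sig,
    truth = list(
      peak_frequency_target_hz = target,
      peak_amplitude_db = 20 * log10(max(abs(x))),
      tone_power = amplitude^2 * sum(tones$rel_power) / 2,
      n_clipped = n_clip
    )
  )
}

#' Generate a synthetic feeding session with annotations
#'
#' A 2-minute (by default) background-noise recording containing
#' non-overlapping tonal swallow bursts. Burst durations and tone
#' frequencies are drawn from truncated normals centred on the reference
#' cohort means (0.85 +/- 0.31 s; 1678.3 +/- 413.5 Hz). Burst boundaries
#' are snapped to the sample grid so the returned annotation table cuts
#' each burst exactly.
#'
#' @param n_swallows number of bursts (may be 0 for pure background).
#' @param session_s session length in seconds.
#' @param sample_rate Hz.
#' @param amplitude peak burst amplitude (LSB).
#' @param noise_db background noise level, dB re 1 LSB.
#' @param min_gap_s minimum silence between bursts and at the edges.
#' @param recording_id identifier used in the annotation table.
#' @param seed integer seed.
#' @return list with `signal`, `annotations`
#'   (`recording_id,swallow_id,start_s,end_s`) and `truth` (per-swallow
#'   tone frequency and amplitude).
#' @export
synth_session <- function(n_swallows = 20, session_s = 120, sample_rate = 44100,
                          amplitude = 20000, noise_db = 40, min_gap_s = 0.5,
                          recording_id = "synthetic_session", seed = 1) {
  set.seed(derive_seed(seed, "session"))
  sp <- preterm_reference_setpoints()

  empty_ann <- data.frame(
    recording_id = character(0), swallow_id = character(0),
    start_s = numeric(0), end_s = numeric(0), stringsAsFactors = FALSE
  )

  n_total <- as.integer(session_s * sample_rate)
  noise_sd <- 10^(noise_db / 20)
  x <- stats::rnorm(n_total, 0, noise_sd)

  if (n_swallows == 0) {
    full_scale <- 32767
    sig <- audio_signal(pmin(pmax(round(x), -full_scale), full_scale), sample_rate, 16)
    return(list(signal = sig, annotations = empty_ann, truth = empty_ann))
  }

  durs <- rtrunc_norm(n_swallows, sp$duration_s["mean"], sp$duration_s["sd"], 0.3, 1.5)
  freqs <- rtrunc_norm(n_swallows, sp$peak_frequency_hz["mean"],
                       sp$peak_frequency_hz["sd"], 600, 4000)
  slack <- session_s - sum(durs) - (n_swallows + 1) * min_gap_s
  if (slack < 0) {
    sca_error(
      sprintf("%d swallows do not fit in a %g s session with %g s gaps",
              n_swallows, session_s, min_gap_s),
      "swallowCA_overcrowded"
    )
  }
  w <- stats::runif(n_swallows + 1)
  gaps <- min_gap_s + slack * w / sum(w)

  starts_s <- cumsum(gaps[seq_len(n_swallows)]) +
    c(0, cumsum(durs))[seq_len(n_swallows)]
  start_idx <- sample_index(starts_s, sample_rate)
  len_idx <- sample_index(durs, sample_rate)

  ramp_n <- min(sample_index(0.005, sample_rate), min(len_idx) %/% 4L)
  for (i in seq_len(n_swallows)) {
    n_i <- len_idx[i]
    t <- (0:(n_i - 1)) / sample_rate
    burst <- amplitude * sin(2 * pi * freqs[i] * t + stats::runif(1, 0, 2 * pi))
    if (ramp_n > 1) {
      env <- c(seq(0, 1, length.out = ramp_n), rep(1, n_i - 2 * ramp_n),
               seq(1, 0, length.out = ramp_n))
      burst <- burst * env
    }
    pos <- start_idx[i] + seq_len(n_i)
    x[pos] <- x[pos] + burst
  }

  full_scale <- 32767
  sig <- audio_signal(pmin(pmax(round(x), -full_scale), full_scale), sample_rate, 16)
  ann <- data.frame(
    recording_id = recording_id,
    swallow_id = sprintf("sw%03d", seq_len(n_swallows)),
    start_s = start_idx / sample_rate,
    end_s = (start_idx + len_idx) / sample_rate,
    stringsAsFactors = FALSE
  )
  truth <- cbind(ann, data.frame(tone_hz = freqs, amplitude_lsb = amplitude))
  list(signal = sig, annotations = ann, truth = truth)
}

#' Generate a two-rater nominal rating table
#'
#' Rater A's yes/no ratings are Bernoulli draws at the configured
#' prevalence; rater B equals rater A with the configured agreement
#' probability, independently per subject and parameter.
#'
#' @param n_subjects number of subjects (neonates).
#' @param prevalence probability of `yes`; a single value, or a vector
#'   named `"phase:parameter"`.
#' @param agreement probability that rater B matches rater A.
#' @param parameters `data.frame` with `phase` and `parameter`
#'   (default: the full inventory).
#' @param seed integer seed.
#' @return long `data.frame`
#'   (`neonate_id,rater_id,phase,parameter,value,consistent`) with raters
#'   `rater_a` and `rater_b`.
#' @export
synth_rating_pair <- function(n_subjects = 80, prevalence = 0.5, agreement = 0.9,
                              parameters = perceptual_inventory(), seed = 1) {
  if (any(prevalence < 0 | prevalence > 1) || agreement < 0 || agreement > 1) {
    sca_error("prevalence and agreement must lie in [0, 1]", "swallowCA_bad_parameter")
  }
  set.seed(derive_seed(seed, "ratings"))
  key <- paste(parameters$phase, parameters$parameter, sep = ":")
  prev <- if (length(prevalence) == 1L) {
    stats::setNames(rep(prevalence, length(key)), key)
  } else {
    if (!all(key %in% names(prevalence))) {
      sca_error("named prevalence must cover every parameter", "swallowCA_bad_parameter")
    }
    prevalence[key]
  }

  rows <- vector("list", length(key))
  ids <- sprintf("n%04d", seq_len(n_subjects))
  for (j in seq_along(key)) {
    a <- ifelse(stats::runif(n_subjects) < prev[j], "yes", "no")
    flip <- stats::runif(n_subjects) >= agreement
    b <- ifelse(flip, ifelse(a == "yes", "no", "yes"), a)
    rows[[j]] <- data.frame(
      neonate_id = rep(ids, 2),
      rater_id = rep(c("rater_a", "rater_b"), each = n_subjects),
      phase = parameters$phase[j], parameter = parameters$parameter[j],
      value = c(a, b), consistent = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Correlation between qpois(pnorm(Z), lambda) and Z for standard normal Z,
# by quadrature; used to calibrate the Gaussian-copula latent correlation
# so the Poisson/normal pair hits the target Pearson correlation exactly
# in expectation. Memoised: the constant depends only on lambda.
.attenuation_cache <- new.env(parent = emptyenv())
poisson_normal_attenuation <- function(lambda) {
  key <- format(lambda, digits = 15)
  if (!is.null(.attenuation_cache[[key]])) return(.attenuation_cache[[key]])
  z <- seq(-8, 8, by = 0.001)
  w <- stats::dnorm(z) * 0.001
  x <- stats::qpois(stats::pnorm(z), lambda)
  ex <- sum(x * w); exz <- sum(x * z * w); ex2 <- sum(x^2 * w)
  out <- exz / sqrt(ex2 - ex^2)
  .attenuation_cache[[key]] <- out
  out
}

# Correlated (Poisson count, normal) pair via a Gaussian copula.
# cor(X, Y) = rho_z * attenuation(lambda), so rho_z = target / attenuation.
copula_conditions_amplitude <- function(n, target_r, lambda, amp_mean, amp_sd) {
  c_att <- poisson_normal_attenuation(lambda)
  rho_z <- target_r / c_att
  if (abs(rho_z) > 0.999) {
    sca_error(
      sprintf("target correlation %.3f infeasible for these margins (|r| must be <= %.3f)",
              target_r, 0.999 * c_att),
      "swallowCA_bad_parameter"
    )
  }
  z1 <- stats::rnorm(n)
  z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
  list(
    conditions = stats::qpois(stats::pnorm(z1), lambda),
    amplitude_db = amp_mean + amp_sd * z2
  )
}

#' Generate a synthetic preterm cohort
#'
#' Produces, for `n` neonates: a covariate table (gestational ages and a
#' Poisson comorbidity count), consensus perceptual profiles sampled at
#' the configured per-parameter prevalences (coordination is always
#' assigned by running [classify_coordination()] on the sampled ratings,
#' never drawn directly), and a per-neonate acoustic feature table whose
#' peak amplitude is correlated with the comorbidity count at the target
#' Pearson correlation through a Gaussian copula (Poisson margin for the
#' count, normal margin for the amplitude).
#'
#' @param n number of neonates (reference cohort: 80).
#' @param target_r target Pearson correlation between peak amplitude and
#'   the number of medical conditions (reference: 0.24).
#' @param conditions_mean mean of the Poisson comorbidity count.
#' @param prevalence per-parameter presence probabilities: vector named
#'   `"phase:parameter"`; defaults to the reference cohort rates.
#' @param consistency_prob probability that a present during-swallow
#'   sound is rated consistent.
#' @param with_profiles set `FALSE` to skip the perceptual profiles and
#'   generate the tabular covariates/features only (cheaper for
#'   correlation studies).
#' @param seed integer seed.
#' @return list with `cohort` (covariates + acoustic means, one row per
#'   neonate), `profiles` (list of consensus [perceptual_profile()]s, or
#'   `NULL` when `with_profiles = FALSE`) and `features` (the acoustic
#'   columns alone).
#' @export
synth_cohort <- function(n = 80, target_r = 0.24, conditions_mean = 2.5,
                         prevalence = NULL, consistency_prob = 0.9,
                         with_profiles = TRUE, seed = 1) {
  if (n < 1) sca_error("n must be >= 1", "swallowCA_bad_parameter")
  set.seed(derive_seed(seed, "cohort"))
  sp <- preterm_reference_setpoints()

  if (is.null(prevalence)) {
    ref <- preterm_reference_counts()
    ref <- ref[ref$phase != "coordination", ]
    prevalence <- stats::setNames(ref$n_present / ref$n_rateable,
                                  paste(ref$phase, ref$parameter, sep = ":"))
  }

  cop <- copula_conditions_amplitude(
    n, target_r, conditions_mean,
    sp$peak_amplitude_db["mean"], sp$peak_amplitude_db["sd"]
  )

  gap_mean <- sp$peak_amplitude_db["mean"] - sp$peak_power_db["mean"]
  features <- data.frame(
    neonate_id = sprintf("n%04d", seq_len(n)),
    duration_s = rtrunc_norm(n, sp$duration_s["mean"], sp$duration_s["sd"], 0.2, 2),
    peak_frequency_hz = rtrunc_norm(n, sp$peak_frequency_hz["mean"],
                                    sp$peak_frequency_hz["sd"], 400, 4000),
    peak_amplitude_db = cop$amplitude_db,
    stringsAsFactors = FALSE
  )
  # peak power sits below peak amplitude by a positive margin, so the
  # mean-square <= max-square ordering holds row-wise by construction
  features$peak_power_db <- features$peak_amplitude_db -
    rtrunc_norm(n, gap_mean, sp$peak_power_db["sd"], 0.5, Inf)

  cohort <- data.frame(
    neonate_id = features$neonate_id,
    birth_gestation_weeks = rtrunc_norm(
      n, sp$birth_gestation_weeks["mean"], sp$birth_gestation_weeks["sd"],
      sp$birth_gestation_weeks["min"], sp$birth_gestation_weeks["max"]
    ),
    chronological_gestation_weeks = rtrunc_norm(
      n, sp$chronological_gestation_weeks["mean"], sp$chronological_gestation_weeks["sd"],
      sp$chronological_gestation_weeks["min"], sp$chronological_gestation_weeks["max"]
    ),
    n_medical_conditions = cop$conditions,
    stringsAsFactors = FALSE
  )

  inv <- perceptual_inventory()
  key <- paste(inv$phase, inv$parameter, sep = ":")
  prev <- prevalence[key]
  if (anyNA(prev)) {
    sca_error("prevalence must be named 'phase:parameter' and cover the inventory",
              "swallowCA_bad_parameter")
  }
  profiles <- if (!with_profiles) NULL else lapply(seq_len(n), function(i) {
    value <- ifelse(stats::runif(nrow(inv)) < prev, "yes", "no")
    consistent <- rep(NA_character_, nrow(inv))
    during_yes <- inv$phase == "during" & value == "yes"
    consistent[during_yes] <- ifelse(
      stats::runif(sum(during_yes)) < consistency_prob, "yes", "no"
    )
    perceptual_profile(
      features$neonate_id[i], "consensus",
      data.frame(phase = inv$phase, parameter = inv$parameter,
                 value = value, consistent = consistent, stringsAsFactors = FALSE)
    )
  })

  list(
    cohort = merge(cohort, features, by = "neonate_id", sort = TRUE),
    profiles = profiles,
    features = features
  )
}
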