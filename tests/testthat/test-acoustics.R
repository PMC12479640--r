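# Acoustic feature pipeline: filter response, framing, Welch spectra,
# and the four per-swallow parameters.

test_that("high-pass filter rejects DC and matches the Butterworth magnitude response", {
  dc <- highpass(rep(1000, FS), sample_rate = FS)
  expect_lt(max(abs(dc[(FS / 2):FS])), 1)  # <= 1 LSB after the transient

  gain_db <- function(f) {
    x <- sin(2 * pi * f * (0:(FS - 1)) / FS)
    y <- highpass(x, sample_rate = FS)
    idx <- (FS / 2):FS  # steady state
    20 * log10(stats::sd(y[idx]) / stats::sd(x[idx]))
  }
  expect_equal(gain_db(400), -3.01, tolerance = 0.2 / 3.01)

  closed_form <- function(f, fc = 400) 10 * log10((f / fc)^8 / (1 + (f / fc)^8))
  expect_lt(abs(gain_db(2000) - closed_form(2000)), 0.1)
  expect_lt(abs(gain_db(800) - closed_form(800)), 0.1)

  expect_error(highpass(rnorm(100), filter_spec(cutoff_hz = 30000), sample_rate = FS),
               class = "swallowCA_bad_parameter")
  expect_error(highpass(rnorm(10), sample_rate = FS), class = "swallowCA_too_short")
})

test_that("framing yields 1 + floor((N - L)/hop) frames and drops the tail", {
  expect_equal(ncol(frame_signal(numeric(882), FS)), 1)
  expect_equal(ncol(frame_signal(numeric(1764), FS)), 3)
  # 0.85 s at 44.1 kHz (the cohort mean duration): 84 frames
  expect_equal(ncol(frame_signal(numeric(37485), FS)), 84)
  expect_equal(nrow(frame_signal(numeric(37485), FS)), 882)
  expect_error(frame_signal(numeric(500), FS), class = "swallowCA_too_short")
})

test_that("welch_psd normalizes to unit sum and localizes tones", {
  set.seed(21)
  for (i in 1:5) {
    est <- welch_psd(rnorm(882) * 10^runif(1, 0, 4), FS)
    expect_equal(sum(est$psd), 1, tolerance = 1e-9)
    expect_true(all(est$psd >= 0))
    expect_equal(range(est$frequencies_hz), c(0, FS / 2), tolerance = BIN_HZ / FS)
  }

  tone <- sin(2 * pi * 1000 * (0:881) / FS) * 5000
  est <- welch_psd(tone, FS)
  expect_lt(abs(est$frequencies_hz[which.max(est$psd)] - 1000), BIN_HZ)

  zero <- welch_psd(numeric(882), FS)
  expect_true(zero$zero_energy)
  expect_false(zero$normalized)
})

test_that("welch_psd matches the explicit-DFT oracle to 1e-9 relative", {
  set.seed(22)
  for (L in c(512, 882, 1024)) {
    x <- rnorm(L) * 300
    got <- welch_psd(x, FS)
    want <- welch_oracle(x, FS)
    expect_equal(got$frequencies_hz, want$frequencies_hz)
    expect_lt(max(abs(got$psd - want$psd) / want$psd), 1e-9)
  }
})

test_that("Welch averaging flattens a white-noise spectrum", {
  set.seed(23)
  avg <- Reduce(`+`, lapply(1:200, function(i) welch_psd(rnorm(882), FS)$psd)) / 200
  q <- stats::quantile(avg, c(0.05, 0.95))
  expect_lt(q[[2]] / q[[1]], 4)
})

test_that("peak frequency finds the cumulative-power crossing", {
  # single tone well above the noise floor
  sw <- synth_swallow(tones = data.frame(freq_hz = 1500, rel_power = 1),
                      amplitude = 15000, noise_db = 43.5, seed = 31)
  expect_lt(abs(peak_frequency(sw$signal) - 1500), 2 * BIN_HZ)

  # 96% of power at 1 kHz: the CDF crosses 0.95 inside the first peak
  two <- synth_swallow(tones = data.frame(freq_hz = c(1000, 5000),
                                          rel_power = c(0.96, 0.04)),
                       amplitude = 15000, noise_db = -Inf, seed = 32)
  expect_lt(abs(peak_frequency(two$signal) - 1000), 2 * BIN_HZ)

  expect_error(peak_frequency(audio_signal(integer(37485), FS)),
               class = "swallowCA_zero_energy")
})

test_that("peak frequency of band-limited noise sits at the band's 95th percentile", {
  # uniform power over 400-2000 Hz: 95% of power lies below 1920 Hz
  n <- round(0.85 * FS)
  tt <- (0:(n - 1)) / FS
  freqs <- seq(400, 2000, by = 8)
  pf <- vapply(1:30, function(s) {
    set.seed(s)
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    x <- rowSums(vapply(seq_along(freqs),
                        function(i) sin(2 * pi * freqs[i] * tt + ph[i]), numeric(n)))
    peak_frequency(audio_signal(round(x / max(abs(x)) * 15000), FS))
  }, numeric(1))
  expect_lt(abs(mean(pf) - 1920), 100)
})

test_that("peak frequency is scale-invariant; dB features shift by 20*log10(c)", {
  sw <- synth_swallow(amplitude = 8000, noise_db = 20, seed = 33)
  sig1 <- sw$signal
  sig2 <- audio_signal(sig1$samples * 3, FS)
  expect_equal(peak_frequency(sig1), peak_frequency(sig2))
  expect_equal(peak_amplitude_db(sig2) - peak_amplitude_db(sig1), 20 * log10(3),
               tolerance = 1e-12)
  d_power <- peak_power_db(sig2)$peak_power_db - peak_power_db(sig1)$peak_power_db
  expect_equal(d_power, 20 * log10(3), tolerance = 1e-12)
})

test_that("peak amplitude is 20*log10(max |sample|) re 1 LSB", {
  expect_equal(peak_amplitude_db(audio_signal(c(0, 32767, -5), FS)),
               90.31, tolerance = 1e-3)
  expect_equal(peak_amplitude_db(audio_signal(c(0, 1), FS)), 0)
  expect_equal(peak_amplitude_db(audio_signal(c(-16384, 7), FS)),
               84.29, tolerance = 1e-4)
  expect_error(peak_amplitude_db(audio_signal(integer(10), FS)),
               class = "swallowCA_zero_energy")
})

test_that("peak power equals the max per-frame mean square in dB", {
  # 2 kHz sine, 40 cycles per 20 ms frame: frame mean square = A^2/2 exactly
  sig <- sine_signal(2000, 0.85, 30000)
  got <- peak_power_db(sig)
  expect_equal(got$peak_power_db, 10 * log10(30000^2 / 2), tolerance = 0.1 / 86.5)
  expect_equal(got$n_clipped_removed, 0)

  # constant 1-LSB signal: power 1 -> 0 dB reference
  expect_equal(peak_power_db(audio_signal(rep(1, 2000), FS))$peak_power_db, 0)
})

test_that("clipped samples are excluded from energy and effective duration", {
  n <- round(0.85 * FS)
  base <- rep(c(12000, -12000), length.out = n)
  p_clean <- peak_power_db(audio_signal(base, FS))$peak_power_db

  x <- base
  set.seed(41)
  idx <- sample(n, n %/% 2)
  x[idx] <- sign(x[idx]) * 32767
  got <- peak_power_db(audio_signal(x, FS))
  expect_lt(abs(got$peak_power_db - p_clean), 0.1)
  expect_equal(got$n_clipped_removed, n %/% 2)

  all_clipped <- audio_signal(rep(c(32767, -32767), length.out = n), FS)
  expect_error(peak_power_db(all_clipped), class = "swallowCA_all_clipped")
})

test_that("peak power never exceeds peak amplitude on clip-free signals", {
  set.seed(42)
  for (i in 1:6) {
    sw <- synth_swallow(amplitude = runif(1, 2000, 25000),
                        noise_db = runif(1, 10, 40), seed = 100 + i)
    expect_lte(peak_power_db(sw$signal)$peak_power_db,
               peak_amplitude_db(sw$signal))
  }
})

test_that("extract_profile assembles the four parameters and flags failures", {
  iv <- swallow_interval("rec", "s1", 1.00, 1.85)
  sw <- synth_swallow(duration_s = 0.85, amplitude = 20000, noise_db = 20, seed = 51)
  prof <- extract_profile(sw$signal, iv)
  expect_equal(prof$duration_s, 0.85)
  expect_lt(abs(prof$peak_frequency_hz - 1678.3), 2 * BIN_HZ)
  expect_equal(prof$peak_amplitude_db, sw$truth$peak_amplitude_db)
  expect_lte(prof$peak_power_db, prof$peak_amplitude_db)

  silent <- extract_profile(audio_signal(integer(37485), FS), iv)
  expect_true(is.na(silent$peak_frequency_hz))
  expect_true(is.na(silent$peak_amplitude_db))
  expect_named(attr(silent, "reasons"))
  expect_true("peak_frequency_hz" %in% names(attr(silent, "reasons")))
})

test_that("extract_features returns one row per annotated swallow", {
  ses <- synth_session(n_swallows = 4, session_s = 20, seed = 52)
  feats <- extract_features(ses$signal, ses$annotations)
  expect_equal(nrow(feats), 4)
  expect_equal(feats$swallow_id, ses$annotations$swallow_id)
  expect_equal(feats$duration_s, ses$annotations$end_s - ses$annotations$start_s)
  expect_true(all(is.finite(feats$peak_frequency_hz)))
})
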