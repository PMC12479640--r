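# Shared fixtures: brute-force spectral oracle, rating-table builders,
# and small signal constructors. Everything is generated in code at test
# time; no binary fixtures.

FS <- 44100

# Integer sine wave in quantization units.
sine_signal <- function(freq_hz, duration_s, amplitude, fs = FS, phase = 0) {
  n <- round(duration_s * fs)
  audio_signal(round(amplitude * sin(2 * pi * freq_hz * (0:(n - 1)) / fs + phase)), fs)
}

# Independent Welch oracle: explicit DFT per Hann-windowed sub-frame
# (no fft), averaged and normalized. Mirrors only the published recipe
# (10 half-overlapping sub-frames tiling the frame), not the package code.
welch_oracle <- function(x, fs, subframes = 10, ov = 0.5) {
  L <- length(x)
  Ls <- floor(L / (1 + (subframes - 1) * (1 - ov)))
  hop <- floor(Ls * (1 - ov))
  k <- 1 + (L - Ls) %/% hop
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(Ls - 1)) / (Ls - 1))
  nf <- Ls %/% 2 + 1
  acc <- numeric(nf)
  for (j in seq_len(k)) {
    seg <- x[((j - 1) * hop + 1):((j - 1) * hop + Ls)] * w
    X <- vapply(
      0:(nf - 1),
      function(kk) sum(seg * exp(-2i * pi * kk * (0:(Ls - 1)) / Ls)),
      complex(1)
    )
    p <- Mod(X)^2 / (sum(w^2) * fs)
    last <- if (Ls %% 2 == 0) nf - 1 else nf
    if (last >= 2) p[2:last] <- 2 * p[2:last]
    acc <- acc + p
  }
  psd <- acc / k
  list(frequencies_hz = (0:(nf - 1)) * fs / Ls, psd = psd / sum(psd))
}

# Welch frequency-bin width for the default 20 ms frame at 44.1 kHz:
# sub-frame length floor(882 / 5.5) = 160 samples -> 275.625 Hz.
BIN_HZ <- FS / floor(round(0.020 * FS) / 5.5)

# Full-inventory rating table; overrides are named "phase:parameter".
# During-swallow parameters rated yes get consistent = "yes".
make_ratings <- function(..., default = "no") {
  overrides <- list(...)
  inv <- perceptual_inventory()
  value <- rep(default, nrow(inv))
  key <- paste(inv$phase, inv$parameter, sep = ":")
  for (k in names(overrides)) {
    i <- match(k, key)
    stopifnot(!is.na(i))
    value[i] <- overrides[[k]]
  }
  consistent <- ifelse(inv$phase == "during" & value == "yes", "yes", NA_character_)
  data.frame(phase = inv$phase, parameter = inv$parameter,
             value = value, consistent = consistent, stringsAsFactors = FALSE)
}

make_profile <- function(neonate_id = "n1", rater_id = "consensus", ..., default = "no") {
  perceptual_profile(neonate_id, rater_id, make_ratings(..., default = default))
}

# 80 consensus profiles engineered so each parameter's presence count
# matches a target count table (columns phase, parameter, n_present,
# n_rateable out of n profiles); ratings beyond n_rateable are
# cannot_be_determined (except during-swallow BTS, kept determinate).
profiles_from_counts <- function(counts, n = 80) {
  inv <- perceptual_inventory()
  key <- paste(inv$phase, inv$parameter)
  ck <- paste(counts$phase, counts$parameter)
  lapply(seq_len(n), function(i) {
    value <- vapply(seq_len(nrow(inv)), function(j) {
      row <- match(key[j], ck)
      if (is.na(row)) return("no")
      if (i <= counts$n_present[row]) "yes"
      else if (i <= counts$n_rateable[row]) "no"
      else "cannot_be_determined"
    }, character(1))
    consistent <- ifelse(inv$phase == "during" & value == "yes", "yes", NA_character_)
    perceptual_profile(
      sprintf("n%03d", i), "consensus",
      data.frame(phase = inv$phase, parameter = inv$parameter,
                 value = value, consistent = consistent, stringsAsFactors = FALSE)
    )
  })
}
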