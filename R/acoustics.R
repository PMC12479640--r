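# Per-swallow acoustic profile: duration, peak frequency (cumulative
# spectral power criterion), peak amplitude and clip-corrected peak
# power. Decibels are referenced to one quantization unit of the PCM
# encoding (0 dB = 1 LSB; the 16-bit ceiling is 20*log10(32767) = 90.31
# dB), the only common reference consistent with reported neonatal peak
# amplitudes just under that ceiling.

#' High-pass filter settings
#'
#' Defaults follow the study pipeline: 4th-order Butterworth high-pass at
#' 400 Hz, removing the large low-frequency energy components (breathing,
#' handling noise) below the swallow-sound band.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param order filter order.
#' @param zero_phase if `TRUE`, filter forward and backward
#'   (zero phase lag, magnitude response squared — effectively 8th
#'   order); default is causal forward-only filtering.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 400, order = 4, zero_phase = FALSE) {
  if (cutoff_hz <= 0) sca_error("cutoff_hz must be positive", "swallowCA_bad_parameter")
  if (order < 1) sca_error("order must be >= 1", "swallowCA_bad_parameter")
  structure(
    list(cutoff_hz = cutoff_hz, order = as.integer(order), zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Short-time framing and Welch settings
#'
#' Defaults follow the study pipeline: 20 ms frames with 50% overlap; the
#' power spectral density of each frame is a Welch estimate over 10
#' Hann-windowed sub-frames with 50% overlap.
#'
#' @param frame_ms frame length in milliseconds.
#' @param overlap fraction of frame overlap in `[0, 1)`.
#' @param welch_subframes number of Welch sub-frames per frame (>= 2).
#' @param welch_overlap sub-frame overlap fraction in `[0, 1)`.
#' @param cdf_threshold cumulative-power fraction defining the peak
#'   frequency (default 0.95).
#' @return list of class `frame_spec`.
#' @export
frame_spec <- function(frame_ms = 20, overlap = 0.5, welch_subframes = 10,
                       welch_overlap = 0.5, cdf_threshold = 0.95) {
  if (overlap < 0 || overlap >= 1 || welch_overlap < 0 || welch_overlap >= 1) {
    sca_error("overlap fractions must lie in [0, 1)", "swallowCA_bad_parameter")
  }
  if (welch_subframes < 2) {
    sca_error("welch_subframes must be >= 2", "swallowCA_bad_parameter")
  }
  if (cdf_threshold <= 0 || cdf_threshold > 1) {
    sca_error("cdf_threshold must lie in (0, 1]", "swallowCA_bad_parameter")
  }
  structure(
    list(
      frame_ms = frame_ms, overlap = overlap,
      welch_subframes = as.integer(welch_subframes),
      welch_overlap = welch_overlap, cdf_threshold = cdf_threshold
    ),
    class = "frame_spec"
  )
}

as_samples <- function(signal) {
  if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
}

#' High-pass filter a signal
#'
#' Causal (forward-only) Butterworth IIR filtering via [signal::butter()]
#' and [signal::filter()]; output length equals input length. With
#' `zero_phase = TRUE` in the filter settings, [signal::filtfilt()] is
#' used instead.
#'
#' @param signal an [audio_signal()] or numeric vector.
#' @param sample_rate required when `signal` is a bare vector.
#' @param fspec a [filter_spec()].
#' @return numeric vector of filtered (real-valued) samples.
#' @export
highpass <- function(signal, fspec = filter_spec(), sample_rate = NULL) {
  x <- as_samples(signal)
  fs <- if (inherits(signal, "audio_signal")) signal$sample_rate else sample_rate
  if (is.null(fs)) sca_error("sample_rate required for bare vectors", "swallowCA_bad_parameter")
  if (fspec$cutoff_hz >= fs / 2) {
    sca_error("cutoff frequency must be below the Nyquist frequency", "swallowCA_bad_parameter")
  }
  if (length(x) <= 3 * fspec$order) {
    sca_error("signal too short to filter (need > 3x filter order samples)",
              "swallowCA_too_short")
  }
  bf <- signal::butter(fspec$order, fspec$cutoff_hz / (fs / 2), type = "high")
  if (fspec$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Split a signal into overlapping short-time frames
#'
#' Frame length is `round(frame_ms * fs / 1000)` samples; the hop is
#' `frame_length * (1 - overlap)`. A trailing partial frame is dropped,
#' so the frame count is `1 + floor((N - L) / hop)`.
#'
#' @param x numeric vector.
#' @param sample_rate Hz.
#' @param frspec a [frame_spec()].
#' @return numeric matrix, one column per frame.
#' @export
frame_signal <- function(x, sample_rate, frspec = frame_spec()) {
  x <- as_samples(x)
  L <- as.integer(floor(frspec$frame_ms * sample_rate / 1000 + 0.5))
  hop <- max(1L, as.integer(floor(L * (1 - frspec$overlap) + 0.5)))
  n <- length(x)
  if (n < L) {
    sca_error(
      sprintf("signal (%d samples) is shorter than one %d-sample frame; pad or reject", n, L),
      "swallowCA_too_short"
    )
  }
  k <- 1L + (n - L) %/% hop
  starts <- (seq_len(k) - 1L) * hop
  idx <- outer(seq_len(L), starts, `+`)
  matrix(x[idx], nrow = L, ncol = k)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density of one frame
#'
#' Averages Hann-windowed modified periodograms over overlapping
#' sub-frames; the sub-frame length is chosen so that the requested
#' number of half-overlapping sub-frames tiles the frame
#' (`floor(L / 5.5)` for 10 sub-frames at 50% overlap). The one-sided
#' estimate is normalized to unit sum, so it reads as the fraction of
#' signal power per frequency bin.
#'
#' @param frame numeric vector (one short-time frame).
#' @param sample_rate Hz.
#' @param frspec a [frame_spec()].
#' @return list of class `spectral_estimate`: `frequencies_hz` (bin
#'   centers, `0 .. fs/2`), `psd` (unit-sum when not zero-energy),
#'   `normalized`, `zero_energy`.
#' @export
welch_psd <- function(frame, sample_rate, frspec = frame_spec()) {
  x <- as.numeric(frame)
  L <- length(x)
  denom <- 1 + (frspec$welch_subframes - 1) * (1 - frspec$welch_overlap)
  Ls <- as.integer(floor(L / denom))
  if (Ls < 8L) {
    sca_error(
      sprintf("frame too short for Welch estimate (sub-frame length %d < 8)", Ls),
      "swallowCA_too_short"
    )
  }
  hop <- max(1L, as.integer(floor(Ls * (1 - frspec$welch_overlap))))
  k <- 1L + (L - Ls) %/% hop
  w <- hann_window(Ls)
  wnorm <- sum(w^2)
  nf <- Ls %/% 2L + 1L

  acc <- numeric(nf)
  for (j in seq_len(k)) {
    seg <- x[((j - 1L) * hop + 1L):((j - 1L) * hop + Ls)] * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_len(nf)])^2 / (wnorm * sample_rate)
    # one-sided: double everything except DC and (for even Ls) Nyquist
    last_dbl <- if (Ls %% 2L == 0L) nf - 1L else nf
    if (last_dbl >= 2L) p[2:last_dbl] <- 2 * p[2:last_dbl]
    acc <- acc + p
  }
  psd <- acc / k
  total <- sum(psd)
  zero_energy <- total <= 0
  if (!zero_energy) psd <- psd / total

  structure(
    list(
      frequencies_hz = (0:(nf - 1L)) * sample_rate / Ls,
      psd = psd,
      normalized = !zero_energy,
      zero_energy = zero_energy
    ),
    class = "spectral_estimate"
  )
}

frame_energies <- function(frames) colSums(frames^2)

cdf_crossing <- function(est, threshold) {
  cdf <- cumsum(est$psd)
  idx <- which(cdf >= threshold - 1e-12)[1]
  est$frequencies_hz[idx]
}

#' Peak frequency of a swallow segment
#'
#' The frequency below which a set fraction (default 95%) of the
#' normalized spectral power lies. Pipeline: high-pass filter, short-time
#' framing, selection of the maximum-energy frame, Welch PSD, cumulative
#' sum from low to high frequency, and the smallest bin whose cumulative
#' power reaches the threshold (reported as that bin's center frequency).
#'
#' @param segment an [audio_signal()].
#' @param fspec a [filter_spec()].
#' @param frspec a [frame_spec()].
#' @param mode `"max_energy_frame"` (default) computes the CDF on the
#'   maximum-energy frame's PSD; `"pooled"` pools (averages) the PSDs of
#'   all frames before the CDF; `"per_frame_max"` evaluates every frame
#'   and reports the maximum crossing.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(segment, fspec = filter_spec(), frspec = frame_spec(),
                           mode = c("max_energy_frame", "pooled", "per_frame_max")) {
  mode <- match.arg(mode)
  fs <- segment$sample_rate
  xf <- highpass(segment, fspec)
  frames <- frame_signal(xf, fs, frspec)
  en <- frame_energies(frames)
  if (all(en <= 0)) {
    sca_error("zero-energy segment: peak frequency undefined", "swallowCA_zero_energy")
  }
  if (mode == "max_energy_frame") {
    est <- welch_psd(frames[, which.max(en)], fs, frspec)
    cdf_crossing(est, frspec$cdf_threshold)
  } else if (mode == "pooled") {
    ests <- lapply(seq_len(ncol(frames))[en > 0], function(j) welch_psd(frames[, j], fs, frspec))
    pooled <- ests[[1]]
    pooled$psd <- rowMeans(vapply(ests, `[[`, numeric(length(pooled$psd)), "psd"))
    pooled$psd <- pooled$psd / sum(pooled$psd)
    cdf_crossing(pooled, frspec$cdf_threshold)
  } else {
    max(vapply(
      seq_len(ncol(frames))[en > 0],
      function(j) cdf_crossing(welch_psd(frames[, j], fs, frspec), frspec$cdf_threshold),
      numeric(1)
    ))
  }
}

#' Peak amplitude in decibels
#'
#' `20 * log10(max |sample|)` on the raw (unfiltered) segment, with
#' samples in quantization units, i.e. dB re 1 LSB. Full-scale 16-bit
#' PCM gives 90.31 dB.
#'
#' @param segment an [audio_signal()].
#' @return peak amplitude in dB.
#' @export
peak_amplitude_db <- function(segment) {
  m <- max(abs(as_samples(segment)))
  if (m <= 0) {
    sca_error("all-zero segment: peak amplitude undefined", "swallowCA_zero_energy")
  }
  20 * log10(m)
}

#' Clip-corrected peak power in decibels
#'
#' For each short-time frame the signal power is the frame energy divided
#' by the frame duration, i.e. the mean squared sample value; clipped
#' samples are excluded from both the energy and the effective duration
#' so saturation does not bias the estimate. Frames retaining under 50%
#' unclipped samples are discarded. The peak power is
#' `10 * log10(max frame power)`, dB re 1 LSB^2.
#'
#' Power is computed on the raw segment by default: clip exclusion is
#' only well defined before filtering, because an IIR filter smears a
#' saturated sample's energy into its unclipped neighbours. Set
#' `on_filtered = TRUE` to measure power on the high-pass filtered
#' frames instead (with clip positions carried through).
#'
#' @param segment an [audio_signal()].
#' @param frspec a [frame_spec()].
#' @param clip a clip mask from [detect_clips()]; computed with the
#'   default full-scale threshold when `NULL`.
#' @param on_filtered compute frame powers on the filtered signal.
#' @param fspec a [filter_spec()] (used only when `on_filtered`).
#' @return list with `peak_power_db` and `n_clipped_removed`.
#' @export
peak_power_db <- function(segment, frspec = frame_spec(), clip = NULL,
                          on_filtered = FALSE, fspec = filter_spec()) {
  fs <- segment$sample_rate
  if (is.null(clip)) clip <- detect_clips(segment)
  clipped <- logical(length(segment$samples))
  clipped[clip$indices] <- TRUE

  x <- if (on_filtered) highpass(segment, fspec) else as_samples(segment)

  L <- as.integer(floor(frspec$frame_ms * fs / 1000 + 0.5))
  hop <- max(1L, as.integer(floor(L * (1 - frspec$overlap) + 0.5)))
  n <- length(x)
  if (n < L) {
    sca_error("segment shorter than one frame: peak power undefined", "swallowCA_too_short")
  }
  k <- 1L + (n - L) %/% hop

  powers <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + L)
    keep <- !clipped[idx]
    if (sum(keep) >= L / 2) {
      powers[j] <- sum(x[idx][keep]^2) / sum(keep)
    }
  }
  if (all(is.na(powers))) {
    sca_error("every frame is majority-clipped: peak power undefined",
              "swallowCA_all_clipped")
  }
  pmax_ <- max(powers, na.rm = TRUE)
  if (pmax_ <= 0) {
    sca_error("zero-energy segment: peak power undefined", "swallowCA_zero_energy")
  }
  list(peak_power_db = 10 * log10(pmax_), n_clipped_removed = length(clip$indices))
}

#' Acoustic profile of one annotated swallow
#'
#' Computes the four per-swallow acoustic parameters: duration (annotated
#' end minus start), peak frequency, peak amplitude and clip-corrected
#' peak power. A feature that cannot be computed (e.g. a zero-energy or
#' too-short segment) is reported as `NA` with a reason code, never
#' silently dropped.
#'
#' @param segment the cut [audio_signal()] for this swallow.
#' @param interval the matching [swallow_interval()].
#' @param fspec a [filter_spec()].
#' @param frspec a [frame_spec()].
#' @param clip_threshold passed to [detect_clips()] (`NULL` = full scale).
#' @return one-row `data.frame` with columns `recording_id, swallow_id,
#'   duration_s, peak_frequency_hz, peak_amplitude_db, peak_power_db,
#'   n_clipped_removed` plus a `reasons` attribute naming failed features.
#' @export
extract_profile <- function(segment, interval, fspec = filter_spec(),
                            frspec = frame_spec(), clip_threshold = NULL) {
  reasons <- character(0)
  try_feature <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      reasons[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  clip <- detect_clips(segment, clip_threshold)
  pf <- try_feature("peak_frequency_hz", peak_frequency(segment, fspec, frspec))
  pa <- try_feature("peak_amplitude_db", peak_amplitude_db(segment))
  pp <- try_feature("peak_power_db", peak_power_db(segment, frspec, clip)$peak_power_db)
  out <- data.frame(
    recording_id = as.character(interval$recording_id),
    swallow_id = as.character(interval$swallow_id),
    duration_s = interval$end_s - interval$start_s,
    peak_frequency_hz = pf,
    peak_amplitude_db = pa,
    peak_power_db = pp,
    n_clipped_removed = length(clip$indices),
    stringsAsFactors = FALSE
  )
  attr(out, "reasons") <- reasons
  out
}

#' Acoustic profiles for every annotated swallow of a recording
#'
#' @param signal an [audio_signal()] (a full feeding-session recording)
#'   or a path to a WAV file.
#' @param annotations annotation `data.frame`
#'   (`recording_id,swallow_id,start_s,end_s`) or a CSV path.
#' @inheritParams extract_profile
#' @return `data.frame` with one row per annotated swallow (the features
#'   CSV layout).
#' @export
extract_features <- function(signal, annotations, fspec = filter_spec(),
                             frspec = frame_spec(), clip_threshold = NULL) {
  if (is.character(signal)) signal <- read_wav(signal)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    iv <- annotations[i, ]
    seg <- extract_segment(signal, iv)
    extract_profile(seg, iv, fspec, frspec, clip_threshold)
  })
  do.call(rbind, rows)
}
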