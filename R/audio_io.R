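# Audio ingestion: integer PCM WAV in/out, swallow-interval cutting,
# clipped-sample detection. Samples are kept in integer quantization
# units (LSB) throughout so that the decibel reference (0 dB = 1 LSB)
# stays well defined.

#' Construct an audio signal
#'
#' Container for a single-channel integer PCM signal. Samples are stored
#' in quantization units (least significant bits, LSB) of the original
#' encoding; a 16-bit recording therefore has samples in
#' \code{[-32768, 32767]}.
#'
#' @param samples integer vector of PCM samples (quantization units).
#' @param sample_rate sampling rate in Hz.
#' @param bit_depth bits per sample of the source encoding (default 16).
#' @return An object of class `audio_signal`: a list with elements
#'   `samples`, `sample_rate`, `bit_depth`.
#' @examples
#' sig <- audio_signal(c(0L, 100L, -100L), 44100)
#' duration(sig)
#' @export
audio_signal <- function(samples, sample_rate, bit_depth = 16) {
  if (length(samples) < 1L) {
    sca_error("audio signal must contain at least one sample", "swallowCA_empty_signal")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    sca_error("sample_rate must be a single positive number", "swallowCA_bad_parameter")
  }
  if (!bit_depth %in% c(8L, 16L, 24L, 32L)) {
    sca_error("bit_depth must be one of 8, 16, 24, 32", "swallowCA_bad_parameter")
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) {
    sca_error("samples must not contain NA", "swallowCA_bad_parameter")
  }
  full_scale <- 2^(bit_depth - 1)
  if (any(samples > full_scale - 1 | samples < -full_scale)) {
    sca_error(
      sprintf("samples exceed the %d-bit signed PCM range", bit_depth),
      "swallowCA_range_error"
    )
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, bit_depth = as.integer(bit_depth)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %g Hz (%d-bit), duration %.4f s, max |sample| %g\n",
    length(x$samples), x$sample_rate, x$bit_depth,
    duration(x), max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an [audio_signal()].
#' @return length in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate
}

#' Read an integer PCM WAV file
#'
#' Reads RIFF/WAVE files with integer PCM encoding (format tag 1). IEEE
#' float (format tag 3) and compressed encodings are rejected: rescaling
#' float audio would destroy the quantization-unit decibel reference.
#' Stereo input is reduced to channel 1 (the recording chain uses a
#' single neck-mounted microphone) with a warning.
#'
#' @param path path to a WAV file.
#' @return An [audio_signal()] with bit-exact integer samples.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    sca_error(sprintf("WAV file not found: %s", path), "swallowCA_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    sca_error(sprintf("not a RIFF file: %s", path), "swallowCA_unsupported_format")
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    sca_error(sprintf("not a WAVE file: %s", path), "swallowCA_unsupported_format")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * c(1, 256, 65536, 16777216))
      fmt <- list(
        audio_format = u16(0), channels = u16(2),
        sample_rate = u32(4), bits = u16(14)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip ancillary chunk
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  if (is.null(fmt) || is.null(data_raw)) {
    sca_error(sprintf("missing fmt/data chunk in %s", path), "swallowCA_unsupported_format")
  }
  if (fmt$audio_format != 1L) {
    sca_error(
      sprintf(
        "unsupported WAV encoding (format tag %d) in %s: only integer PCM is supported",
        fmt$audio_format, path
      ),
      "swallowCA_unsupported_format"
    )
  }
  if (!fmt$bits %in% c(8L, 16L)) {
    sca_error(
      sprintf("unsupported PCM bit depth %d in %s (8 or 16 supported)", fmt$bits, path),
      "swallowCA_unsupported_format"
    )
  }
  if (length(data_raw) == 0L) {
    sca_error(sprintf("empty data chunk in %s", path), "swallowCA_empty_signal")
  }

  if (fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    samples <- readBin(data_raw, "integer", n, size = 2, signed = TRUE, endian = "little")
  } else {
    # 8-bit WAV PCM is unsigned with midpoint 128
    samples <- as.integer(data_raw) - 128L
  }

  if (fmt$channels > 1L) {
    warning(sprintf(
      "%d-channel WAV: keeping channel 1 only (single-microphone convention)",
      fmt$channels
    ))
    samples <- samples[seq(1L, length(samples), by = fmt$channels)]
  }

  audio_signal(samples, fmt$sample_rate, bit_depth = fmt$bits)
}

#' Write an integer PCM WAV file
#'
#' @param signal an [audio_signal()] (bit depth 8 or 16).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!signal$bit_depth %in% c(8L, 16L)) {
    sca_error("write_wav supports 8- and 16-bit PCM only", "swallowCA_unsupported_format")
  }
  n <- length(signal$samples)
  bytes_per <- signal$bit_depth %/% 8L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                      # PCM
  writeBin(1L, con, size = 2, endian = "little")                      # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(signal$bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (signal$bit_depth == 16L) {
    writeBin(as.integer(signal$samples), con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(as.integer(signal$samples) + 128L), con)
  }
  invisible(path)
}

#' Construct a swallow interval
#'
#' An annotated swallow: identifiers plus start/end times in seconds
#' relative to the start of the recording.
#'
#' @param recording_id,swallow_id character identifiers.
#' @param start_s,end_s interval bounds in seconds, `0 <= start_s < end_s`.
#' @return A one-row `data.frame` of class `swallow_interval`.
#' @export
swallow_interval <- function(recording_id, swallow_id, start_s, end_s) {
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 || start_s >= end_s) {
    sca_error("swallow interval requires 0 <= start_s < end_s", "swallowCA_bad_interval")
  }
  structure(
    data.frame(
      recording_id = as.character(recording_id),
      swallow_id = as.character(swallow_id),
      start_s = start_s, end_s = end_s,
      stringsAsFactors = FALSE
    ),
    class = c("swallow_interval", "data.frame")
  )
}

#' Cut an annotated segment from a recording
#'
#' Uses a half-open sample window `[round(start_s * fs), round(end_s * fs))`
#' with round-half-up, so adjacent intervals tile a recording without gap
#' or overlap and the returned length is pure index arithmetic,
#' `round(end_s * fs) - round(start_s * fs)`.
#'
#' @param signal an [audio_signal()].
#' @param interval a [swallow_interval()] (or any list with `start_s`, `end_s`).
#' @return An [audio_signal()] holding the cut samples.
#' @export
extract_segment <- function(signal, interval) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  i0 <- sample_index(interval$start_s, fs)
  i1 <- sample_index(interval$end_s, fs)
  n <- length(signal$samples)
  if (i0 < 0L || i1 > n || i0 >= i1) {
    sca_error(
      sprintf(
        "interval [%g, %g] s is outside the recording (duration %g s)",
        interval$start_s, interval$end_s, n / fs
      ),
      "swallowCA_out_of_range"
    )
  }
  audio_signal(signal$samples[(i0 + 1L):i1], fs, signal$bit_depth)
}

#' Detect clipped samples
#'
#' Flags every sample whose absolute value reaches `clip_threshold`.
#' The default threshold is full scale for the signal's bit depth
#' (`2^(bit_depth - 1) - 1`, i.e. 32767 for 16-bit); lower it for
#' recorders that saturate below full scale.
#'
#' @param signal an [audio_signal()].
#' @param clip_threshold quantization units, `>= 1`.
#' @return A `clip_mask`: list with integer `indices` (1-based positions
#'   of clipped samples) and `clip_threshold`.
#' @export
detect_clips <- function(signal, clip_threshold = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.null(clip_threshold)) {
    clip_threshold <- 2^(signal$bit_depth - 1) - 1
  }
  if (clip_threshold < 1) {
    sca_error("clip_threshold must be >= 1 quantization unit", "swallowCA_bad_parameter")
  }
  structure(
    list(
      indices = which(abs(signal$samples) >= clip_threshold),
      clip_threshold = clip_threshold
    ),
    class = "clip_mask"
  )
}

#' Read a swallow annotation table
#'
#' CSV with header `recording_id,swallow_id,start_s,end_s`, '.' decimal
#' separator. Rows are validated against the interval invariants.
#'
#' @param path CSV path.
#' @return `data.frame` with the four annotation columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    sca_error(sprintf("annotation file not found: %s", path), "swallowCA_io_error")
  }
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("recording_id", "swallow_id", "start_s", "end_s")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    sca_error(
      sprintf("%s: missing annotation column(s): %s", path, paste(missing, collapse = ", ")),
      "swallowCA_bad_table"
    )
  }
  bad <- which(!(ann$start_s >= 0 & ann$start_s < ann$end_s))
  if (length(bad)) {
    sca_error(
      sprintf("%s: invalid interval at row(s) %s (need 0 <= start_s < end_s)",
              path, paste(bad, collapse = ", ")),
      "swallowCA_bad_interval"
    )
  }
  ann[required]
}

#' Write a swallow annotation table
#' @param annotations data.frame with `recording_id,swallow_id,start_s,end_s`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
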