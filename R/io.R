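#' Read an acoustic time series
#'
#' Reads a recording from a WAV file (PCM 16/24/32-bit or IEEE float 32/64;
#' sampling rate taken from the header) or from a single-column numeric CSV
#' (sampling rate must be supplied). No resampling or filtering is applied;
#' by default the sample mean is removed, which is the only detrending the
#' spectral chain expects.
#'
#' @param path Path to a `.wav` or `.csv` file.
#' @param sampling_rate Sampling rate in Hz; required for CSV input,
#'   overrides the header if given for WAV input.
#' @param patient_id Optional label attached to the recording.
#' @param remove_mean Subtract the sample mean (default `TRUE`).
#' @return A `recording` object: list with `samples`, `sampling_rate` (Hz),
#'   `duration` (s) and `patient_id`.
#' @export
read_timeseries <- function(path, sampling_rate = NULL, patient_id = NA_character_,
                            remove_mean = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- read_wav(path)
    fs <- if (is.null(sampling_rate)) w$sampling_rate else sampling_rate
    x <- w$samples
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate must be supplied for CSV time series")
    fs <- sampling_rate
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    x <- suppressWarnings(as.numeric(lines))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      stop("non-numeric value in ", path, " at line ", bad, ": '", lines[bad], "'")
    }
  }
  new_recording(if (remove_mean) x - mean(x) else x, fs, patient_id)
}

#' Construct a recording from samples in memory
#'
#' @param samples Numeric vector of acceleration samples (arbitrary linear
#'   units).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param patient_id Optional label.
#' @return A `recording` object.
#' @export
new_recording <- function(samples, sampling_rate, patient_id = NA_character_) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         duration = length(samples) / sampling_rate, patient_id = patient_id),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording%s: %d samples @ %g Hz (%.3f s)>\n",
              if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id),
              length(x$samples), x$sampling_rate, x$duration))
  invisible(x)
}

#' Write a harmonic power feature table to CSV
#'
#' CSV schema: `patient_id,P_FF,P_2H,...,P_12H,outcome`, comma-separated,
#' '.' decimal, UTF-8. Reading back with [read_feature_table()] reproduces
#' the table at the written precision.
#'
#' @param profiles Data frame passing [validate_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(profiles, path) {
  if (nrow(profiles) == 0) stop("feature table must be non-empty")
  validate_profiles(profiles)
  profiles <- profiles[, c("patient_id", harmonic_variables(), "outcome")]
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a harmonic power feature table from CSV
#'
#' @param path CSV written by [write_feature_table()] (or any file with the
#'   same schema). A missing or extra column, a duplicate `patient_id`, or an
#'   outcome outside `{YES, NO}` raises an error naming the offender.
#' @return Validated data frame of profiles.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  validate_profiles(df)
  df
}

# --- Minimal RIFF/WAVE I/O -------------------------------------------------
# Supports the subset of WAV used for acoustic recordings: mono or first
# channel of multichannel, PCM 16/24/32-bit integer and IEEE float 32/64.

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  bytes <- fmt$bits / 8
  n_frames <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (fmt$audio_format == 1) {            # integer PCM
    if (fmt$bits == 16) {
      x <- readBin(data_raw, "integer", n_frames * fmt$n_channels, 2,
                   signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw[seq_len(n_frames * fmt$n_channels * 3)]),
                  nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else if (fmt$bits == 32) {
      x <- readBin(data_raw, "integer", n_frames * fmt$n_channels, 4,
                   endian = "little") / 2^31
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$audio_format == 3) {     # IEEE float
    x <- readBin(data_raw, "double", n_frames * fmt$n_channels, bytes,
                 endian = "little")
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)
  if (fmt$n_channels > 1)
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  list(samples = x, sampling_rate = fmt$sample_rate)
}

#' Write a recording to a WAV file
#'
#' @param rec A `recording` (or numeric vector with `sampling_rate` given).
#' @param path Output path.
#' @param sampling_rate Required when `rec` is a bare numeric vector.
#' @param format `"float32"` (default; preserves samples to single
#'   precision) or `"pcm16"` (samples must lie in \[-1, 1\]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sampling_rate = NULL,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(rec, "recording")) {
    x <- rec$samples; fs <- rec$sampling_rate
  } else {
    if (is.null(sampling_rate)) stop("sampling_rate required for numeric input")
    x <- as.numeric(rec); fs <- sampling_rate
  }
  bytes <- if (format == "float32") 4L else 2L
  fmt_code <- if (format == "float32") 3L else 1L
  data_size <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")              # block align
  writeBin(8L * bytes, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, 4, endian = "little")
  } else {
    if (any(abs(x) > 1)) stop("pcm16 output requires samples in [-1, 1]")
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con, 2,
             endian = "little")
  }
  invisible(path)
}
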