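#' Pump fundamental frequency from rotational speed
#'
#' The pump's fundamental acoustic frequency (FF) is its rotation rate:
#' `rpm / 60` Hz. Higher harmonics (2H, 3H, ...) are integer multiples of FF.
#'
#' @param pump_speed Pump speed in rpm (> 0), vectorized.
#' @return Fundamental frequency in Hz.
#' @examples
#' fundamental_from_rpm(2560) # 42.67 Hz
#' @export
fundamental_from_rpm <- function(pump_speed) {
  if (any(pump_speed <= 0)) stop("pump_speed must be positive")
  pump_speed / 60
}

new_psd <- function(freq, psd, bin_width, method, ...) {
  structure(list(freq = freq, psd = psd, bin_width = bin_width,
                 method = method, meta = list(...)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate (%s): %d bins, df = %.5g Hz, range [0, %.5g] Hz>\n",
              x$method, length(x$freq), x$bin_width, max(x$freq)))
  invisible(x)
}

# One-sided PSD of one (windowed) block, power per Hz.
# Scaling: sum(psd) * (fs/N) equals the mean square of the windowed block
# divided by the window's mean square, so Parseval holds for the
# rectangular window exactly.
.block_psd <- function(x, fs, window) {
  n <- length(x)
  w <- switch(window,
              rectangular = rep(1, n),
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n),
              stop("unknown window: ", window))
  X <- stats::fft(x * w)
  nb <- floor(n / 2) + 1
  p <- (Mod(X[seq_len(nb)])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, nb); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  p * dbl
}

#' Full-record periodogram PSD estimate
#'
#' One-sided power spectral density over the full record length, so the
#' frequency resolution is `sampling_rate / n_samples` (about 1/60 Hz for a
#' 60 s record). Satisfies Parseval's relation: the PSD integrates to the
#' mean square of the (mean-removed) signal.
#'
#' @param rec A `recording` (mean removal is applied if needed).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A `psd_estimate`: `freq` (Hz, from 0), `psd` (power/Hz),
#'   `bin_width` (Hz), `method`.
#' @export
compute_periodogram <- function(rec, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  stopifnot(inherits(rec, "recording"))
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  if (n < 2) stop("recording must contain at least 2 samples")
  fs <- rec$sampling_rate
  nb <- floor(n / 2) + 1
  new_psd(freq = (seq_len(nb) - 1) * fs / n,
          psd = .block_psd(x, fs, window),
          bin_width = fs / n, method = "periodogram", window = window)
}

#' Welch-averaged PSD estimate
#'
#' Averaged modified periodogram over overlapping windowed segments
#' (defaults: 1 s segments, 50% overlap, Hann window), trading frequency
#' resolution (`bin_width = 1/segment_seconds`) for reduced estimator
#' variance.
#'
#' @param rec A `recording`.
#' @param segment_seconds Segment length in seconds (default 1).
#' @param overlap_fraction Fractional overlap between segments (default 0.5).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @return A `psd_estimate`.
#' @export
compute_welch <- function(rec, segment_seconds = 1, overlap_fraction = 0.5,
                          window = c("hann", "rectangular")) {
  window <- match.arg(window)
  stopifnot(inherits(rec, "recording"),
            overlap_fraction >= 0, overlap_fraction < 1)
  x <- rec$samples - mean(rec$samples)
  fs <- rec$sampling_rate
  L <- round(segment_seconds * fs)
  if (L < 2 || L > length(x))
    stop("segment length (", L, " samples) must be >= 2 and <= record length")
  step <- max(1, round(L * (1 - overlap_fraction)))
  starts <- seq(1, length(x) - L + 1, by = step)
  nb <- floor(L / 2) + 1
  acc <- numeric(nb)
  for (s in starts) acc <- acc + .block_psd(x[s:(s + L - 1)], fs, window)
  new_psd(freq = (seq_len(nb) - 1) * fs / L,
          psd = acc / length(starts),
          bin_width = fs / L, method = "welch",
          window = window, segment_seconds = segment_seconds,
          overlap_fraction = overlap_fraction, n_segments = length(starts))
}

#' Detect the pump fundamental from a PSD
#'
#' Frequency of the maximum PSD bin within a search band, refined by
#' parabolic interpolation over the three bins around the peak. Used when
#' the pump speed is not available; otherwise prefer
#' [fundamental_from_rpm()]. The result carries a `low_confidence`
#' attribute, set when the peak is weaker than 3 times the band's median
#' PSD (e.g. on noise-only input).
#'
#' @param spec A `psd_estimate`.
#' @param search_band Two-element Hz interval, default `c(35, 55)`.
#' @return Estimated fundamental in Hz with attribute `low_confidence`.
#' @export
detect_fundamental <- function(spec, search_band = c(35, 55)) {
  stopifnot(inherits(spec, "psd_estimate"), length(search_band) == 2)
  idx <- which(spec$freq >= search_band[1] & spec$freq <= search_band[2])
  if (length(idx) == 0) stop("search band contains no spectrum bins")
  i <- idx[which.max(spec$psd[idx])]
  f <- spec$freq[i]
  if (i > 1 && i < length(spec$freq)) {
    y1 <- spec$psd[i - 1]; y2 <- spec$psd[i]; y3 <- spec$psd[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      f <- f + max(-0.5, min(0.5, delta)) * spec$bin_width
    }
  }
  low <- spec$psd[i] < 3 * stats::median(spec$psd[idx])
  structure(f, low_confidence = low)
}

#' Harmonic power: PSD area in a window around one harmonic
#'
#' Area under the PSD curve over a `width` Hz wide closed interval centered
#' on `center`, computed by the trapezoid rule over the bins falling in the
#' interval. This is the per-harmonic power statistic the feature profiles
#' are built from.
#'
#' @param spec A `psd_estimate`.
#' @param center Window center in Hz (typically `n * ff`).
#' @param width Window width in Hz, default 1.
#' @return Linear power (non-negative scalar).
#' @export
harmonic_power <- function(spec, center, width = 1) {
  stopifnot(inherits(spec, "psd_estimate"), width > 0)
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < min(spec$freq) || hi > max(spec$freq))
    stop(sprintf("window [%.2f, %.2f] Hz outside spectrum range [0, %.2f] Hz",
                 lo, hi, max(spec$freq)))
  idx <- which(spec$freq >= lo & spec$freq <= hi)
  if (length(idx) < 2) return(spec$psd[idx] * spec$bin_width)
  f <- spec$freq[idx]; p <- spec$psd[idx]
  sum((p[-1] + p[-length(p)]) / 2 * diff(f))
}

#' Normalize a harmonic power profile to a 0 dB sum
#'
#' Shifts a vector of harmonic power dB values so that the linearized powers
#' sum to exactly 1 (the FF-12H total is the 0 dB reference). Idempotent and
#' invariant to any overall gain applied to the recording.
#'
#' @param powers_db Numeric vector of dB values (`-Inf` entries allowed).
#' @return dB vector of the same length whose linear powers sum to 1.
#' @export
normalize_profile <- function(powers_db) {
  lin <- 10^(powers_db / 10)
  total <- sum(lin)
  if (!is.finite(total) || total <= 0)
    stop("profile is degenerate: no finite harmonic power")
  powers_db - 10 * log10(total)
}

#' Extract a normalized harmonic power profile from a recording
#'
#' Runs the full feature chain: PSD estimation (full-record periodogram by
#' default), integration of the PSD over a 1 Hz window centered on each of
#' the first `n_harmonics` integer multiples of the fundamental, conversion
#' to dB, and 0 dB-sum normalization. Linear powers are clipped at
#' `db_floor_linear` before the log to avoid `-Inf`.
#'
#' @param rec A `recording`.
#' @param ff Fundamental frequency in Hz (e.g. from
#'   [fundamental_from_rpm()]); if `NULL`, estimated with
#'   [detect_fundamental()].
#' @param n_harmonics Number of harmonics, default 12.
#' @param width Integration window width in Hz, default 1.
#' @param estimator `"periodogram"` (default) or `"welch"`.
#' @param db_floor_linear Clip for linear powers before log conversion.
#' @return Named numeric vector of normalized dB values
#'   (`P_FF`, `P_2H`, ...).
#' @export
extract_profile <- function(rec, ff = NULL, n_harmonics = 12, width = 1,
                            estimator = c("periodogram", "welch"),
                            db_floor_linear = 1e-12) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(rec, "recording"))
  spec <- switch(estimator,
                 periodogram = compute_periodogram(rec),
                 welch = compute_welch(rec))
  if (is.null(ff)) ff <- as.numeric(detect_fundamental(spec))
  if (n_harmonics * ff >= rec$sampling_rate / 2)
    stop(sprintf("harmonic %d at %.1f Hz is at or above Nyquist (%.1f Hz)",
                 n_harmonics, n_harmonics * ff, rec$sampling_rate / 2))
  lin <- vapply(seq_len(n_harmonics),
                function(n) harmonic_power(spec, n * ff, width), numeric(1))
  lin <- pmax(lin, db_floor_linear)
  db <- 10 * log10(lin)
  out <- normalize_profile(db)
  names(out) <- harmonic_variables()[seq_len(n_harmonics)]
  out
}
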