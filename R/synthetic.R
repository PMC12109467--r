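#' Generate a synthetic pump-like acoustic recording
#'
#' Builds a rotary-pump acoustic signature with prescribed harmonic power
#' structure: a sum of sinusoids at integer multiples of the fundamental,
#' with linear powers proportional to the requested normalized dB profile
#' and seeded uniform random phases, plus white Gaussian noise at a
#' prescribed level relative to the total harmonic power. Feeding the
#' result through [extract_profile()] recovers `harmonic_db` (to within the
#' noise), which is how the spectral chain is tested end to end.
#'
#' Defaults are sized for fast tests (6 kHz, 12 s); a clinical-scale
#' 60 kHz / 60 s recording is obtained by passing those values. The default
#' fundamental is `2560/60` Hz (a typical pump speed of 2560 rpm), and the
#' default duration is a multiple of 3 s so that every harmonic of that
#' fundamental completes an integer number of cycles and falls exactly on a
#' periodogram bin — the same self-consistency the clinical protocol has,
#' where a 60 s record puts `rpm/60` Hz exactly on its 1/60 Hz grid. An
#' off-grid fundamental adds spectral leakage from the strong fundamental
#' into the weak harmonic windows.
#'
#' @param ff Fundamental frequency in Hz (default `2560/60`).
#' @param harmonic_db Vector of target harmonic powers in dB; normalized to
#'   a 0 dB sum internally. Default: the embedded HW-A profile.
#' @param total_power Variance of the harmonic component (default 1).
#' @param noise_db Broadband noise power relative to total harmonic power,
#'   in dB (default -30); `-Inf` disables noise.
#' @param sampling_rate Hz (default 6000).
#' @param duration Seconds (default 10, minimum 2).
#' @param phase_seed,noise_seed Integer seeds for the harmonic phases and
#'   the noise draw.
#' @param patient_id Optional label.
#' @return A `recording`, with the generating parameters attached as the
#'   `synthetic_spec` attribute.
#' @export
generate_recording <- function(ff = 2560 / 60,
                               harmonic_db = unlist(.hvad_profiles()[1, harmonic_variables()]),
                               total_power = 1, noise_db = -30,
                               sampling_rate = 6000, duration = 12,
                               phase_seed = 1L, noise_seed = 2L,
                               patient_id = NA_character_) {
  n_harm <- length(harmonic_db)
  if (n_harm * ff >= sampling_rate / 2)
    stop(sprintf("aliasing: harmonic %d at %.1f Hz is at or above Nyquist (%.1f Hz)",
                 n_harm, n_harm * ff, sampling_rate / 2))
  if (duration < 2) stop("duration must be at least 2 s")
  harmonic_db <- normalize_profile(harmonic_db)
  p_lin <- 10^(harmonic_db / 10) * total_power
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(phase_seed)
  phases <- stats::runif(n_harm, 0, 2 * pi)
  x <- numeric(length(t))
  for (nh in seq_len(n_harm)) {
    if (p_lin[nh] > 0)
      x <- x + sqrt(2 * p_lin[nh]) * sin(2 * pi * nh * ff * t + phases[nh])
  }
  if (is.finite(noise_db)) {
    set.seed(noise_seed)
    x <- x + stats::rnorm(length(t), sd = sqrt(total_power * 10^(noise_db / 10)))
  }
  rec <- new_recording(x, sampling_rate, patient_id)
  attr(rec, "synthetic_spec") <- list(ff = ff, harmonic_db = harmonic_db,
                                      total_power = total_power,
                                      noise_db = noise_db,
                                      phase_seed = phase_seed,
                                      noise_seed = noise_seed)
  rec
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labeled two-class synthetic feature cohort
#'
#' Draws seeded multivariate-normal harmonic power rows for each class
#' (`NO` then `YES`), with per-class mean vectors and a shared covariance.
#' Used to test the cross-validation engine under controlled class
#' geometry.
#'
#' @param n_no,n_yes Rows per class (>= 1 each).
#' @param mean_no,mean_yes Per-variable mean dB vectors (same length).
#' @param cov Shared covariance matrix (symmetric positive semi-definite),
#'   or a scalar for isotropic covariance.
#' @param variables Variable names; default the first `length(mean_no)`
#'   harmonic variables.
#' @param seed Integer seed.
#' @return A feature table with `patient_id`, the variables, and `outcome`.
#' @export
generate_cohort <- function(n_no = 8, n_yes = 3,
                            mean_no = c(-0.5, -25, -36),
                            mean_yes = c(-0.7, -13, -24),
                            cov = 1, variables = NULL, seed = 1L) {
  stopifnot(n_no >= 1, n_yes >= 1, length(mean_no) == length(mean_yes))
  d <- length(mean_no)
  if (is.null(variables)) variables <- harmonic_variables()[seq_len(d)]
  if (length(cov) == 1) cov <- diag(cov, d)
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-8) ||
      min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("cov must be symmetric positive semi-definite")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows_no <- MASS::mvrnorm(n_no, mean_no, cov)
  rows_yes <- MASS::mvrnorm(n_yes, mean_yes, cov)
  x <- rbind(matrix(rows_no, nrow = n_no), matrix(rows_yes, nrow = n_yes))
  colnames(x) <- variables
  df <- data.frame(patient_id = sprintf("SYN-%02d", seq_len(n_no + n_yes)),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  df$outcome <- c(rep("NO", n_no), rep("YES", n_yes))
  df
}

#' Generate a cohort-shaped synthetic feature table
#'
#' An 11-row, 12-variable synthetic stand-in for the embedded cohort's
#' class geometry: 3 thrombosis `YES` rows clustered together in
#' (`P_FF`, `P_2H`, `P_3H`) space, 6 well-separated `NO` rows, and 2
#' "confuser" `NO` rows placed adjacent to the `YES` cluster — the geometry
#' that makes the leave-two-out split holding out both confusers the
#' model's failure mode. Each row is renormalized to a 0 dB sum.
#'
#' @param seed Integer seed.
#' @param confuser_offset dB offset of the confuser rows from the `YES`
#'   cluster mean (small = harder).
#' @return A feature table; the two confuser ids carry the attribute
#'   `confusers`.
#' @export
paperlike_cohort <- function(seed = 1L, confuser_offset = 1.5) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mk <- function(lead3, jitter = 1) {
    c(lead3 + stats::rnorm(3, sd = jitter), -19 + stats::rnorm(1, sd = 2),
      c(-40, -41, -42, -35, -43, -44, -45, -42) + stats::rnorm(8, sd = 1.5))
  }
  no_main <- t(vapply(1:6, function(i) mk(c(-0.2, -26, -37)), numeric(12)))
  yes_rows <- t(vapply(1:3, function(i) mk(c(-1.0, -12.5, -23.5)), numeric(12)))
  confusers <- t(vapply(1:2, function(i)
    mk(c(-1.0, -12.5, -23.5) + confuser_offset), numeric(12)))
  x <- rbind(no_main, confusers, yes_rows)
  x <- t(apply(x, 1, normalize_profile))
  colnames(x) <- harmonic_variables()
  df <- data.frame(patient_id = sprintf("SYN-%02d", 1:11), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$outcome <- c(rep("NO", 8), rep("YES", 3))
  attr(df, "confusers") <- df$patient_id[7:8]
  df
}
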