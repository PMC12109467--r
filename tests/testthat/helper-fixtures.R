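# Shared fixtures built in code.

cohort_profiles <- function() load_embedded_cohort()$profiles

# A short pure-tone recording at an exact periodogram bin frequency.
sine_recording <- function(freq = 50, amplitude = 1, fs = 6000, duration = 10,
                           phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  new_recording(amplitude * sin(2 * pi * freq * t + phase), fs)
}

noise_recording <- function(sd = 1, fs = 6000, duration = 10, seed = 1) {
  withr::with_seed(seed, new_recording(rnorm(fs * duration, sd = sd), fs))
}

total_psd_power <- function(spec) sum(spec$psd) * spec$bin_width

# Linear power implied by a normalized dB profile row.
linear_power_sum <- function(row_db) sum(10^(row_db / 10))
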