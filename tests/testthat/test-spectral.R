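test_that("periodogram satisfies Parseval for tones and noise", {
  rec <- sine_recording(freq = 50, amplitude = 1)
  spec <- compute_periodogram(rec)
  expect_equal(total_psd_power(spec), 0.5, tolerance = 0.01)
  expect_equal(spec$bin_width, rec$sampling_rate / length(rec$samples))
  expect_true(all(spec$psd >= 0))
  expect_equal(spec$freq[1], 0)

  noise <- noise_recording(sd = 2, seed = 42)
  spec <- compute_periodogram(noise)
  x <- noise$samples - mean(noise$samples)
  expect_equal(total_psd_power(spec), mean(x^2), tolerance = 0.02)

  zero <- new_recording(rep(0, 1000), 1000)
  expect_true(all(compute_periodogram(zero)$psd == 0))
  expect_error(compute_periodogram(new_recording(1, 10)), "2 samples")
})

test_that("Welch estimate preserves total power and locates the peak", {
  rec <- sine_recording(freq = 50)
  w <- compute_welch(rec)
  expect_equal(w$bin_width, 1)
  expect_equal(w$freq[which.max(w$psd)], 50)
  expect_equal(total_psd_power(w), 0.5, tolerance = 0.02)
  expect_equal(total_psd_power(w), total_psd_power(compute_periodogram(rec)),
               tolerance = 0.02)
  expect_error(compute_welch(new_recording(rnorm(100), 1000),
                             segment_seconds = 1), "segment length")
})

test_that("Welch averaging reduces estimator variance on stationary noise", {
  per_bin <- c(); welch_bin <- c()
  for (seed in 1:20) {
    noise <- noise_recording(fs = 2000, duration = 4, seed = seed)
    p <- compute_periodogram(noise)
    w <- compute_welch(noise)
    # matched frequency: 100 Hz exists on both grids
    per_bin <- c(per_bin, p$psd[which.min(abs(p$freq - 100))])
    welch_bin <- c(welch_bin, w$psd[which.min(abs(w$freq - 100))])
  }
  expect_lt(var(welch_bin), var(per_bin))
})

test_that("harmonic power integrates the PSD window", {
  rec <- sine_recording(freq = 50)
  spec <- compute_periodogram(rec)
  expect_equal(harmonic_power(spec, 50), 0.5, tolerance = 0.02)

  noise <- noise_recording(sd = 1, fs = 6000, duration = 60, seed = 3)
  w <- compute_welch(noise)
  n0 <- 1 / (6000 / 2) # flat one-sided density for unit variance
  expect_equal(harmonic_power(w, 100), n0, tolerance = 0.25)

  expect_error(harmonic_power(spec, 1e6), "outside")
})

test_that("two-tone window powers recover the prescribed ratio", {
  fs <- 6000; t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sqrt(2) * sin(2 * pi * 45 * t) + sqrt(2 * 0.1) * sin(2 * pi * 90 * t)
  spec <- compute_periodogram(new_recording(x, fs))
  ratio_db <- 10 * log10(harmonic_power(spec, 45) / harmonic_power(spec, 90))
  expect_equal(ratio_db, 10, tolerance = 0.2)
})

test_that("widening the integration window never loses power", {
  rec <- generate_recording(noise_db = -25, duration = 6)
  spec <- compute_periodogram(rec)
  for (n in 1:12) {
    expect_gte(harmonic_power(spec, n * (2560 / 60), width = 2),
               harmonic_power(spec, n * (2560 / 60), width = 1))
  }
})

test_that("fundamental detection finds the pump line and flags noise", {
  rec <- generate_recording(ff = 2560 / 60, noise_db = -30, duration = 12)
  f <- detect_fundamental(compute_periodogram(rec))
  expect_equal(as.numeric(f), 42.67, tolerance = 0.05)
  expect_false(attr(f, "low_confidence"))

  pure <- sine_recording(freq = 50)
  spec <- compute_periodogram(pure)
  expect_equal(as.numeric(detect_fundamental(spec)), 50,
               tolerance = spec$bin_width)

  # noise-only: averaged (Welch) spectrum has no stable peak in the band
  flags <- vapply(1:5, function(s) {
    w <- compute_welch(noise_recording(seed = s, duration = 10))
    attr(detect_fundamental(w), "low_confidence")
  }, logical(1))
  expect_true(all(flags))

  expect_error(detect_fundamental(spec, c(1e5, 2e5)), "band")
})

test_that("profile normalization is a 0 dB-sum shift and idempotent", {
  prof <- cohort_profiles()
  for (i in c(1, 4, 11)) {
    row <- unlist(prof[i, harmonic_variables()])
    renorm <- normalize_profile(row)
    expect_true(all(abs(renorm - row) < 5e-4))
    expect_equal(linear_power_sum(renorm), 1, tolerance = 1e-12)
  }
  v <- c(0, rep(-Inf, 11))
  expect_equal(normalize_profile(v), v)
  w <- rnorm(12, -20, 5)
  expect_equal(normalize_profile(normalize_profile(w)), normalize_profile(w))
  expect_error(normalize_profile(rep(-Inf, 12)), "degenerate")
})

test_that("profile extraction resolves pure-tone structure exactly", {
  # single tone at FF: all normalized power in P_FF
  p <- extract_profile(sine_recording(freq = 50), ff = 50)
  expect_equal(unname(p["P_FF"]), 0, tolerance = 1e-3)
  expect_true(all(p[-1] < -80))

  # equal power at FF and 4H: both at -3.01 dB
  fs <- 6000; t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 200 * t + 1)
  p <- extract_profile(new_recording(x, fs), ff = 50)
  expect_equal(unname(p["P_FF"]), -3.01, tolerance = 0.02)
  expect_equal(unname(p["P_4H"]), -3.01, tolerance = 0.02)

  expect_error(extract_profile(sine_recording(freq = 50), ff = 400),
               "Nyquist")
})

test_that("normalized profiles are invariant to recording gain", {
  rec <- generate_recording(noise_db = -25, duration = 6)
  p1 <- extract_profile(rec, ff = 2560 / 60)
  for (c in c(0.01, 3, 1000)) {
    scaled <- new_recording(rec$samples * c, rec$sampling_rate)
    expect_equal(extract_profile(scaled, ff = 2560 / 60), p1, tolerance = 1e-6)
  }
})
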