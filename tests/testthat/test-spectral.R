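test_that("the amplitude spectrum is correctly normalized for a sinusoid", {
  rate <- 512
  tt <- (0:(rate - 1)) / rate
  x <- sin(2 * pi * 20 * tt)
  a <- sbf_amplitude_spectrum(x, rate, seq(1, 100, 0.1))
  expect_equal(peak_frequency(a, c(5, 50)), 20, tolerance = 0.05)
  expect_equal(max(a$amps), 1, tolerance = 0.02)
  z <- sbf_amplitude_spectrum(rep(0, 100), rate, seq(1, 50, 1))
  expect_true(all(z$amps == 0))
  expect_error(sbf_amplitude_spectrum(c(1, 2), rate), "3 samples")
})

test_that("the transform equals the zero-padded DFT times the sinc^2 kernel", {
  set.seed(31)
  rate <- 512
  x <- rnorm(300)
  M <- 4096
  bins <- 3:200
  freqs <- bins * rate / M
  a <- sbf_amplitude_spectrum(x, rate, freqs, demean = FALSE)
  X <- stats::fft(c(x, rep(0, M - length(x))))
  dt <- 1 / rate
  u <- freqs * dt
  oracle <- (2 / (length(x) * dt)) * dt * (sin(pi * u) / (pi * u))^2 *
    Mod(X[bins + 1])
  expect_equal(a$amps, oracle, tolerance = 1e-6)
})

test_that("the transform matches the analytic Gaussian Fourier modulus", {
  rate <- 512
  tt <- (0:(2 * rate - 1)) / rate
  ker <- data.frame(A = c(150, -400, 180), sigma = c(0.004, 0.0065, 0.005),
                    mu = c(0.9, 0.925, 0.955))
  x <- rowSums(sapply(1:3, function(i)
    ker$A[i] * exp(-(tt - ker$mu[i])^2 / (2 * ker$sigma[i]^2))))
  freqs <- seq(2, 50, 0.5)
  a <- sbf_amplitude_spectrum(x, rate, freqs, demean = FALSE)
  analytic <- Mod(colSums(t(sapply(1:3, function(i)
    ker$A[i] * ker$sigma[i] * sqrt(2 * pi) *
      exp(-2 * pi^2 * ker$sigma[i]^2 * freqs^2) *
      exp(-2i * pi * freqs * ker$mu[i])))))
  expect_equal(a$amps, (2 / a$segment_duration) * analytic, tolerance = 0.01)
})

test_that("fragment power approximately satisfies Parseval", {
  # band-limited input: sum of sinusoids well inside the grid
  rate <- 512
  tt <- (0:(5 * rate - 1)) / rate
  x <- 3 * sin(2 * pi * 7 * tt) + 1.5 * sin(2 * pi * 21 * tt + 1)
  freqs <- seq(0.2, 100, 0.2)
  a <- sbf_amplitude_spectrum(x, rate, freqs)
  # with the 2/T normalization each sinusoid's spectral peak equals its
  # amplitude, and the time-domain variance is the sum of A^2/2 terms
  expect_equal(stats::var(x), 3^2 / 2 + 1.5^2 / 2, tolerance = 0.01)
  pk1 <- max(a$amps[abs(freqs - 7) < 1]); pk2 <- max(a$amps[abs(freqs - 21) < 1])
  expect_equal(pk1, 3, tolerance = 0.05)
  expect_equal(pk2, 1.5, tolerance = 0.05)
})

test_that("peak_frequency refines, tie-breaks low, and validates", {
  f <- seq(1, 50, 1)
  mono <- amplitude_spectrum(f, 50 - f, 1)
  expect_equal(peak_frequency(mono, c(5, 50)), 5)          # band edge
  twin <- amplitude_spectrum(f, as.numeric(f %in% c(10, 20)), 1)
  expect_equal(peak_frequency(twin, c(5, 50)), 10)         # lower tie wins
  expect_error(peak_frequency(amplitude_spectrum(f, rep(0, 50), 1), c(5, 50)),
               "undefined")
  expect_error(peak_frequency(mono, c(200, 300)), "band")
})

test_that("5-s fragment power spectra peak at the discharge rate", {
  mk <- noisy_train("WAG/Rij", duration = 5, seed = 1)
  ps <- power_spectrum_fragment(mk$record, c(0, 5), freqs = seq(0.4, 100, 0.2))
  pk_orig <- ps$freqs[which.max(ps$power_original)]
  expect_equal(pk_orig, 8.8, tolerance = 0.21)
  pk_slow <- ps$freqs[which.max(ps$power_slow)]
  expect_equal(pk_slow, pk_orig, tolerance = 0.21)
  # preprocessing strongly reduces the low-frequency peak
  lo <- ps$freqs < 10
  expect_gt(max(ps$power_original[lo]) / max(ps$power_fast[lo]), 5)
  expect_error(power_spectrum_fragment(mk$record, c(2, 8)), "within")
})

test_that("white-noise fragments show no dominant spectral peak", {
  set.seed(13)
  rec <- eeg_record(rnorm(5 * 512, sd = 30), 512)
  ps <- power_spectrum_fragment(rec, c(0, 5), freqs = seq(1, 100, 0.2))
  # a consistent estimate (9-bin running mean) of a flat spectrum shows no
  # dominant peak; the raw periodogram's max/median reflects only the
  # chi-squared scatter of individual ordinates
  sm <- as.numeric(stats::filter(ps$power_original, rep(1 / 9, 9)))
  sm <- sm[!is.na(sm)]
  expect_lt(max(sm), 5 * median(sm))
})

test_that("mean discharge frequency is count over duration", {
  expect_equal(mean_discharge_frequency(44, 5), 8.8)
  expect_equal(mean_discharge_frequency(12, 5), 2.4)
  expect_equal(mean_discharge_frequency(list(), 5), 0)
  expect_error(mean_discharge_frequency(10, 0), "span_duration")
})

test_that("waveform averaging reproduces identical events and shrinks noise", {
  mk <- noisy_train("GAERS", duration = 3, seed = 5)
  an <- analyze_record(mk$record, archetype_template(archetype("GAERS")))
  ev <- an$events
  expect_gt(length(ev), 10)

  # identical copies: the average equals the single event
  one <- ev[[3]]
  avg1 <- average_waveforms(list(one, one, one))
  cover <- !is.na(avg1$mean_fast)
  i0 <- max(1L, floor(one$start * 512) + 1L)
  tt <- (i0 - 1 + seq_along(one$waveform) - 1) / 512 - one$t_sp2_peak
  ref <- stats::approx(tt, one$waveform, xout = avg1$time[cover])$y
  ok <- !is.na(ref)
  expect_equal(avg1$mean_fast[cover][ok], ref[ok], tolerance = 1e-9)

  # averaging N noisy copies of one waveform shrinks the noise ~ 1/sqrt(N)
  set.seed(99)
  n <- 100
  base <- ev[[3]]
  noisy <- lapply(1:n, function(i) {
    e <- base
    e$waveform <- e$waveform + rnorm(length(e$waveform), sd = 40)
    e
  })
  avgn <- average_waveforms(noisy)
  cover <- !is.na(avgn$mean_fast)
  refn <- stats::approx(tt, base$waveform, xout = avgn$time[cover])$y
  ok <- !is.na(refn)
  resid <- avgn$mean_fast[cover][ok] - refn[ok]
  expect_lt(sqrt(mean(resid^2)), 3 * 40 / sqrt(n))

  # spectrum of the averaged fast waveform peaks near the per-event median
  avg <- average_waveforms(ev)
  expect_equal(peak_frequency(avg$as_fast, c(5, 50)),
               median(an$sc_peaks), tolerance = 1)
  expect_error(average_waveforms(list()), "non-empty")
})
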