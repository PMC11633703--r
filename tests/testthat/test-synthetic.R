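test_that("make_swc is deterministic given a seed and validates jitter", {
  spec <- archetype("WAG/Rij")
  a <- make_swc(spec, amplitude_jitter = 0.2, seed = 5)
  b <- make_swc(spec, amplitude_jitter = 0.2, seed = 5)
  expect_identical(a$waveform, b$waveform)
  expect_error(make_swc(spec, amplitude_jitter = -0.1), "jitter")
  expect_equal(a$duration, 1 / spec$repetition_rate)
})

test_that("the archetype spike's analytic spectrum peaks at 18-20 Hz", {
  for (arch in c("WAG/Rij", "GAERS", "post-SE", "PTE")) {
    pk <- generator_spike_peak_hz(archetype(arch))
    expect_gt(pk, 18); expect_lt(pk, 20)
  }
})

test_that("the closed-form spike spectrum matches a brute-force Fourier integral", {
  spec <- archetype("GAERS")
  ker <- data.frame(A = spec$spike_triplet$rel_amplitude * spec$amplitude_scale,
                    sigma = spec$spike_triplet$sigma,
                    t0 = c(0, spec$spike_gaps[1], sum(spec$spike_gaps)))
  freqs <- c(5, 10, 19.5, 30, 45)
  # numerical quadrature of the continuous FT of untruncated Gaussians
  tt <- seq(-0.1, 0.25, by = 1e-5)
  g <- rowSums(sapply(1:3, function(i)
    ker$A[i] * exp(-(tt - ker$t0[i] - 3 * ker$sigma[i])^2 / (2 * ker$sigma[i]^2))))
  brute <- sapply(freqs, function(f)
    Mod(sum(g * exp(-2i * pi * f * tt)) * 1e-5))
  expect_equal(spike_spectrum_analytic(spec, freqs), brute, tolerance = 1e-4)
})

test_that("PTE's slow-wave second deflection is longer than WAG/Rij's", {
  d2 <- function(spec) {
    sw <- spec$slow_wave
    sw$fill_frac / spec$repetition_rate - sw$d1
  }
  expect_gt(d2(archetype("PTE")), d2(archetype("WAG/Rij")))
})

test_that("seizures place SWCs at the repetition rate", {
  wag <- make_seizure(archetype("WAG/Rij"), 5, seed = 1)
  expect_length(wag$sc_onsets, 44)                        # floor(8.8 * 5)
  pte <- make_seizure(archetype("PTE"), 5, seed = 1)
  expect_length(pte$sc_onsets, 12)                        # floor(2.4 * 5)
  expect_equal(diff(wag$sc_onsets),
               rep(1 / 8.8, 43), tolerance = 1e-12)       # zero jitter
  expect_error(make_seizure(archetype("PTE"), 0.5), ">= 1")
})

test_that("make_record honours trivial configurations and isolation rules", {
  spec <- archetype("GAERS")
  z <- make_record(spec, 4, 0, noise_rms = 0, drift = c(0, 0), seed = 1)
  expect_true(all(z$record$samples == 0))
  expect_length(z$truth$sc_onsets, 0)

  r <- make_record(spec, 30, 1, n_interictal = 3, seed = 2)
  ii <- r$truth$interictal_onsets
  expect_length(ii, 3)
  others <- c(r$truth$sc_onsets, r$truth$sc_ends)
  for (t0 in ii) {
    expect_true(all(abs(others - t0) >= 0.5))
    expect_true(all(abs(ii[ii != t0] - t0) >= 0.5))
  }
  expect_error(make_record(spec, 10, 3, seed = 1), "infeasible")
})

test_that("planted artifacts have spectral peaks outside the 10-30 Hz band", {
  spec <- archetype("WAG/Rij")
  r <- make_record(spec, 20, 0, noise_rms = 0, drift = c(0, 0),
                   n_artifacts = 3, seed = 3)
  for (i in seq_len(nrow(r$truth$artifact_spans))) {
    sp <- r$truth$artifact_spans[i, ]
    i0 <- floor(sp[1] * 512) + 1; i1 <- ceiling(sp[2] * 512) + 1
    a <- sbf_amplitude_spectrum(r$record$samples[i0:i1], 512, seq(0.5, 100, 0.1))
    pk <- peak_frequency(a, c(5, 50))
    expect_true(pk < 10 || pk > 30)
  }
})

test_that("ground-truth SC counts match the planted seizures", {
  spec <- archetype("post-SE")
  r <- make_record(spec, 45, 2, seed = 4)
  # onsets strictly increasing, ends after onsets
  expect_true(all(diff(r$truth$sc_onsets) > 0))
  expect_true(all(r$truth$sc_ends > r$truth$sc_onsets))
  # the count implied by the seizure durations: one SC per full period
  expect_gt(length(r$truth$sc_onsets),
            2 * floor(spec$seizure_duration_range[1] * spec$repetition_rate) - 2)
})

test_that("a DC shift through the high-pass filter makes a long transient", {
  rec <- eeg_record(rep(0, 20 * 512), rate = 512)
  out <- inject_dc_shift_and_filter(rec, shift = 500, shift_duration = 0.5,
                                    highpass_cutoff = 1)
  resp <- abs(out$samples)
  width <- sum(resp > 0.1 * max(resp)) / 512
  expect_gt(width, 0.06)    # much longer than a genuine ~70 ms spike complex

  # shift = 0 leaves only the filter response of the original record
  x <- with_seed(8, pink_noise(512 * 4, 20))
  rec2 <- eeg_record(x, 512)
  same <- inject_dc_shift_and_filter(rec2, 0, 0.5, 1)
  bf <- signal::butter(1, 1 / 256, type = "high")
  expect_equal(same$samples, as.numeric(signal::filter(bf, x)), tolerance = 1e-9)

  # high-pass rejects DC at steady state
  const <- inject_dc_shift_and_filter(eeg_record(rep(40, 512 * 10), 512),
                                      0, 0.5, 2)
  expect_lt(abs(const$samples[512 * 10]), 1e-3)
})

test_that("pink noise hits the requested RMS and is 1/f-shaped", {
  set.seed(9)
  x <- pink_noise(2^15, rms = 25)
  expect_equal(sqrt(mean(x^2)), 25, tolerance = 1e-9)
  p <- Mod(stats::fft(x))^2
  lo <- 10:40; hi <- 300:1200   # frequency bin ranges, factor ~30 apart
  expect_gt(mean(p[lo]) / mean(p[hi]), 5)
})
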