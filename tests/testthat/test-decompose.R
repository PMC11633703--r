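test_that("half-wave segmentation counts sign runs", {
  rate <- 512
  tt <- (0:(rate - 1)) / rate
  x <- sin(2 * pi * 8 * tt)          # 8 full cycles
  hw <- segment_half_waves(x, rate, 0.1)
  expect_equal(nrow(hw), 16)
  expect_true(all(diff(hw$start) > 0))
  expect_true(all(hw$end >= hw$start))
  expect_equal(nrow(segment_half_waves(rep(0, 100), rate)), 0)
})

test_that("a noiseless three-kernel complex yields three alternating half-waves", {
  spec <- archetype("WAG/Rij")
  tt <- (0:127) / 512
  x <- rowSums(sapply(1:3, function(i) {
    k <- spec$spike_triplet
    t0 <- c(0.02, 0.02 + spec$spike_gaps[1], 0.02 + sum(spec$spike_gaps))
    qgk_eval(qgk(k$rel_amplitude[i] * 400, k$sigma[i], t0[i]), tt)
  }))
  hw <- segment_half_waves(x, 512, 20)
  expect_equal(nrow(hw), 3)
  expect_equal(sign(hw$peak), c(1, -1, 1))
})

test_that("fit_qgk recovers a lone kernel almost exactly", {
  x <- lone_qgk_trace(A = -300, sigma = 0.004, t0 = 1)
  hw <- segment_half_waves(x, 512, 50)
  f <- fit_qgk(x, 512, c(hw$start[1], hw$end[1]))
  expect_true(f$converged)
  expect_lt(abs(f$A - (-300)) / 300, 0.01)
  expect_lt(abs(f$sigma - 0.004) / 0.004, 0.01)
  expect_lt(abs(f$t0 - 1), 5e-4)
})

test_that("fit_qgk amplitude recovery degrades gracefully under noise", {
  errs <- sapply(1:100, function(s) {
    x <- lone_qgk_trace(A = -300, sigma = 0.004, t0 = 1)
    x <- x + with_seed(s, rnorm(length(x), sd = 30))   # SNR 10
    hw <- segment_half_waves(x, 512, 100)
    hw <- hw[which.max(abs(hw$peak)), ]
    f <- fit_qgk(x, 512, c(hw$start, hw$end))
    abs(f$A - (-300)) / 300
  })
  expect_lte(median(errs), 0.10)
})

test_that("a Gaussian kernel fits a sine half-wave with small residual", {
  rate <- 512
  tt <- (0:(rate - 1)) / rate
  x <- sin(2 * pi * 10 * tt)
  hw <- segment_half_waves(x, rate, 0.5)
  f <- fit_qgk(x, rate, c(hw$start[2], hw$end[2]))
  expect_lte(f$nrmse, 0.15)
})

test_that("decompose recovers well-separated kernels and a tiny residual", {
  rate <- 512
  tt <- (0:(2 * rate - 1)) / rate
  truth <- data.frame(A = c(200, -350, 150), sigma = c(0.005, 0.007, 0.004),
                      t0 = c(0.3, 0.8, 1.4))
  x <- rowSums(sapply(1:3, function(i)
    qgk_eval(qgk(truth$A[i], truth$sigma[i], truth$t0[i]), tt)))
  m <- decompose(x, rate)
  expect_equal(nrow(m$kernels), 3)
  expect_lt(m$residual_rms / sqrt(mean(x^2)), 0.01)
  expect_equal(m$kernels$t0, truth$t0, tolerance = 0.01)

  z <- decompose(rep(0, 200), rate)
  expect_equal(nrow(z$kernels), 0)
  expect_equal(z$residual_rms, 0)
})

test_that("the reported residual matches the reconstruction residual", {
  mk <- noisy_train("GAERS", duration = 2, seed = 3)
  cp <- detrend(mk$record)
  m <- decompose(cp$fast, 512)
  tt <- record_times(mk$record)
  resid <- cp$fast - model_eval(m, tt)
  expect_equal(sqrt(mean(resid^2)), m$residual_rms, tolerance = 1e-9)
})

test_that("decomposing a reconstruction is nearly idempotent", {
  rate <- 512
  tt <- (0:(2 * rate - 1)) / rate
  x <- qgk_eval(qgk(250, 0.006, 0.5), tt) + qgk_eval(qgk(-180, 0.004, 1.1), tt)
  m1 <- decompose(x, rate)
  recon <- model_eval(m1, tt)
  m2 <- decompose(recon, rate)
  expect_lte(abs(nrow(m2$kernels) - nrow(m1$kernels)), 1)
  big1 <- m1$kernels[abs(m1$kernels$A) > 50, ]
  big2 <- m2$kernels[abs(m2$kernels$A) > 50, ]
  expect_equal(big2$t0, big1$t0, tolerance = 0.005)
  expect_equal(big2$A, big1$A, tolerance = 0.05 * max(abs(big1$A)))
})

test_that("a synthetic seizure yields at least three kernels per complex", {
  mk <- noisy_train("WAG/Rij", duration = 4, seed = 2)
  cp <- detrend(mk$record)
  m <- decompose(cp$fast, 512)
  per_swc <- sapply(mk$truth$sc_onsets, function(on)
    sum(m$kernels$t0 >= on - 0.005 & m$kernels$t0 <= on + 0.08))
  expect_gt(mean(per_swc >= 3), 0.95)
})
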