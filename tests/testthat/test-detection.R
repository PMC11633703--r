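toy_triplet <- function(scale = 1, tshift = 0) {
  data.frame(A = scale * c(120, -400, 170),
             sigma = c(0.004, 0.0065, 0.005),
             t0 = tshift + c(0, 0.018, 0.040))
}

test_that("templates are built from examples by normalized medians", {
  tpl1 <- template_from_examples(list(toy_triplet()))
  expect_equal(tpl1$ref_amplitudes, c(120, -400, 170) / 400)
  expect_equal(tpl1$ref_gaps, c(0.018, 0.022))
  # three identical examples give the same template as one
  tpl3 <- template_from_examples(list(toy_triplet(), toy_triplet(), toy_triplet()))
  expect_equal(tpl3$ref_amplitudes, tpl1$ref_amplitudes)
  expect_equal(tpl3$ref_sigmas, tpl1$ref_sigmas)
  # scatter: the median stays within the scatter of each parameter
  set.seed(21)
  exs <- lapply(1:7, function(i) {
    tr <- toy_triplet()
    tr$sigma <- tr$sigma * runif(3, 0.9, 1.1)
    tr$A <- tr$A * runif(3, 0.9, 1.1)
    tr
  })
  tpl <- template_from_examples(exs)
  expect_equal(tpl$ref_sigmas, c(0.004, 0.0065, 0.005), tolerance = 0.1)
  # non-alternating polarity is rejected
  bad <- toy_triplet(); bad$A <- abs(bad$A)
  expect_error(template_from_examples(list(bad)), "polarity")
})

test_that("the match score is scale-invariant and penalizes deviations", {
  tpl <- template_from_examples(list(toy_triplet()))
  expect_equal(match_score(toy_triplet(), tpl), 0)
  expect_equal(match_score(toy_triplet(scale = 7, tshift = 3), tpl), 0)
  flipped <- toy_triplet(); flipped$A <- -flipped$A
  expect_identical(match_score(flipped, tpl), Inf)
  wider <- toy_triplet(); wider$sigma <- wider$sigma * 1.2
  expect_equal(match_score(wider, tpl), sqrt(3 * log(1.2)^2 / 8),
               tolerance = 1e-12)
})

test_that("a single planted complex is detected with the stated bounds", {
  spec <- archetype("WAG/Rij")
  rate <- 512
  tt <- (0:(2 * rate - 1)) / rate
  trip <- toy_triplet(tshift = 0.9)
  x <- rowSums(sapply(1:3, function(i)
    qgk_eval(qgk(trip$A[i], trip$sigma[i], trip$t0[i]), tt)))
  m <- decompose(x, rate)
  tpl <- template_from_examples(list(toy_triplet()))
  ev <- detect_sc(m, tpl, fast = x)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$start, 0.9, tolerance = 0.004)
  trip <- ev[[1]]$triplet
  expect_equal(ev[[1]]$end, trip$t0[3] + 6 * trip$sigma[3], tolerance = 1e-9)
  expect_equal(ev[[1]]$start, trip$t0[1], tolerance = 1e-9)
  # empty model -> no events
  empty <- signal_model(data.frame(A = numeric(0), sigma = numeric(0),
                                   t0 = numeric(0)), rate = rate)
  expect_length(detect_sc(empty, tpl), 0)
})

test_that("detected events never overlap and starts increase", {
  mk <- noisy_train("GAERS", duration = 5, seed = 4, amplitude_jitter = 0.1)
  an <- analyze_record(mk$record, archetype_template(archetype("GAERS")))
  st <- sapply(an$events, `[[`, "start")
  en <- sapply(an$events, `[[`, "end")
  expect_true(all(diff(st) > 0))
  expect_true(all(st[-1] >= en[-length(en)]))
})

test_that("detection is deterministic for identical inputs", {
  mk <- noisy_train("WAG/Rij", duration = 3, seed = 6)
  tpl <- archetype_template(archetype("WAG/Rij"))
  a <- analyze_record(mk$record, tpl)
  b <- analyze_record(mk$record, tpl)
  expect_identical(a$table, b$table)
})

test_that("slow windows follow the extension and truncation rules", {
  slow <- rep(1, 3 * 512)
  ev <- function(s, e) structure(list(start = s, end = e, triplet = NULL,
                                      score = 0, rate = 512,
                                      t_sp2_peak = s + 0.02), class = "sc_event")
  # single event: plain extension
  out <- attach_slow_component(list(ev(1.000, 1.055)), slow, 512,
                               delta_minus = 0.010, delta_plus = 0.060)
  expect_equal(out[[1]]$slow_start, 0.990)
  expect_equal(out[[1]]$slow_end, 1.115)
  # zero extensions reproduce the SC span
  out0 <- attach_slow_component(list(ev(1.0, 1.055)), slow, 512, 0, 0)
  expect_equal(out0[[1]]$slow_start, 1.0)
  expect_equal(out0[[1]]$slow_end, 1.055)
  # overlapping windows are truncated at the inter-event gap midpoint
  two <- attach_slow_component(list(ev(1.00, 1.06), ev(1.12, 1.18)), slow, 512,
                               delta_minus = 0.010, delta_plus = 0.100)
  mid <- (1.06 + 1.12) / 2
  expect_equal(two[[1]]$slow_end, mid)
  expect_gte(two[[2]]$slow_start, mid)
  expect_lte(two[[1]]$slow_end, two[[2]]$slow_start)
})

test_that("isolated complexes are excluded as interictal spikes", {
  ev <- function(s) structure(list(start = s, end = s + 0.06), class = "sc_event")
  # both isolated by >= 0.5 s on each side
  r <- exclude_interictal(list(ev(10.0), ev(10.9)))
  expect_length(r$kept, 0); expect_length(r$excluded, 2)
  # 0.3 s apart: both kept
  r2 <- exclude_interictal(list(ev(10.0), ev(10.3)))
  expect_length(r2$kept, 2); expect_length(r2$excluded, 0)
  # a single event has no neighbors at all
  r3 <- exclude_interictal(list(ev(5)))
  expect_length(r3$excluded, 1)
})

test_that("artifact rejection uses a closed 10-30 Hz interval", {
  mkspec <- function(pk) {
    f <- seq(1, 50, 0.5)
    amplitude_spectrum(f, exp(-(f - pk)^2 / 4), 0.1)
  }
  ev <- function() structure(list(start = 0, end = 0.1), class = "sc_event")
  events <- list(ev(), ev(), ev())
  out <- reject_artifacts(events, list(mkspec(19.5), mkspec(45), mkspec(10)))
  expect_length(out$kept, 2)
  expect_length(out$rejected, 1)
  expect_equal(out$rejected[[1]]$as_peak_hz, 45, tolerance = 0.1)
  kept_pk <- sapply(out$kept, `[[`, "as_peak_hz")
  expect_equal(sort(kept_pk), c(10, 19.5), tolerance = 0.1)  # boundary kept
})

test_that("events flatten into the standard serialization columns", {
  mk <- noisy_train("WAG/Rij", duration = 2, seed = 10)
  an <- analyze_record(mk$record, archetype_template(archetype("WAG/Rij")))
  expect_named(an$table, c("record", "start_s", "end_s", "slow_start_s",
                           "slow_end_s", "as_peak_hz", "score", "accepted",
                           "reason"))
  expect_true(all(an$table$reason[!an$table$accepted] %in%
                    c("interictal", "artifact_band", "overlap_loser")))
})
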