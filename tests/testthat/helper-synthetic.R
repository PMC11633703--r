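# Shared fixtures, built in code at test time.

# a noisy SWC train as an eeg_record, with its planted ground truth
noisy_train <- function(arch = "WAG/Rij", duration = 5, seed = 1,
                        snr = 10, rate_jitter = 0, amplitude_jitter = 0) {
  spec <- archetype(arch)
  with_seed(seed, {
    sz <- make_seizure(spec, duration, rate_jitter = rate_jitter,
                       amplitude_jitter = amplitude_jitter)
    x <- sz$samples + pink_noise(length(sz$samples), spec$amplitude_scale / snr)
    list(record = eeg_record(x, 512, model_label = arch), truth = sz,
         spec = spec)
  })
}

# a lone truncated quasi-Gaussian kernel embedded in a zero trace
lone_qgk_trace <- function(A = -300, sigma = 0.004, t0 = 1, dur = 2, rate = 512) {
  tt <- (seq_len(round(dur * rate)) - 1) / rate
  qgk_eval(qgk(A, sigma, t0), tt)
}

# per-record SC and slow AS-peak means via ground-truth windows: the
# reduced extraction chain used for the cross-model statistics suites
# (detrend -> window -> spectrum -> peak, skipping detection, whose
# validity the detection tests establish separately)
gt_window_peaks <- function(spec, seed, duration = 3, morph_jitter = 0.12) {
  with_seed(seed, {
    sp <- spec
    tf <- 1 + morph_jitter * stats::runif(1, -1, 1)  # between-animal scale
    sp$spike_triplet$sigma <- sp$spike_triplet$sigma * tf
    sp$spike_gaps <- sp$spike_gaps * tf
    sz <- make_seizure(sp, duration, rate_jitter = 0.02, amplitude_jitter = 0.1)
    x <- sz$samples + pink_noise(length(sz$samples), sp$amplitude_scale / 10)
    cp <- detrend(x, rate = 512)
    scd <- spec_sc_duration(sp)
    P <- 1 / sp$repetition_rate
    dtp <- 0.6 * (P - scd)
    fgrid <- seq(1, 50, 0.1); sgrid <- seq(0.5, 20, 0.05)
    ons <- sz$sc_onsets[sz$sc_onsets > 0.05 & sz$sc_onsets + P < duration]
    pk <- t(sapply(ons, function(on) {
      i0 <- max(1, floor(on * 512) + 1)
      i1 <- floor((on + scd) * 512) + 1
      j0 <- max(1, floor((on - 0.01) * 512) + 1)
      j1 <- floor((on + scd + dtp) * 512) + 1
      c(peak_frequency(sbf_amplitude_spectrum(cp$fast[i0:i1], 512, fgrid), c(5, 50)),
        peak_frequency(sbf_amplitude_spectrum(cp$slow[j0:j1], 512, sgrid), c(1, 20)))
    }))
    c(sc = mean(pk[, 1]), slow = mean(pk[, 2]))
  })
}

# one cross-model suite: 4 models x 8 records at the models' slow-component
# rates; returns the two one-way ANOVA p values
mirror_suite <- function(suite_seed) {
  rates <- c("WAG/Rij" = 8.5, "GAERS" = 8, "post-SE" = 4.5, "PTE" = 4.5)
  sc <- list(); slow <- list()
  for (m in names(rates)) {
    spec <- archetype(m)
    spec$repetition_rate <- rates[[m]]
    res <- sapply(1:8, function(r)
      gt_window_peaks(spec, suite_seed * 1000 + match(m, names(rates)) * 100 + r))
    sc[[m]] <- res["sc", ]; slow[[m]] <- res["slow", ]
  }
  c(p_sc = anova_oneway(sc)$anova$p, p_slow = anova_oneway(slow)$anova$p)
}

# cache for expensive shared fixtures within one test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full-pipeline runs on 60-s records, one per archetype (shared by the
# spike-peak and sensitivity acceptance tests)
archetype_suite_60s <- function() {
  cached("suite60", {
    archs <- c("WAG/Rij", "GAERS", "post-SE", "PTE")
    lapply(seq_along(archs), function(i) {
      spec <- archetype(archs[i])
      mk <- make_record(spec, 60, 3, seed = i)
      an <- analyze_record(mk$record, archetype_template(spec))
      list(analysis = an, truth = mk$truth,
           metrics = detection_metrics(an$events, mk$truth))
    })
  })
}
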