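#' Epilepsy-model archetype specification
#'
#' Bundles the parameters of one synthetic spike-wave-complex (SWC)
#' archetype. Each SWC cycle is the sum of a fast three-phasic spike complex
#' (three alternating quasi-Gaussian kernels) and a biphasic slow wave that
#' occupies the inter-spike interval and shares the spike's polarity in its
#' first deflection.
#'
#' The spike triplet is identical across the four built-in archetypes — the
#' central empirical finding this generator emulates is that the fast spike
#' component is model-invariant while the slow wave differs. The triplet's
#' relative amplitudes are (+0.35, -1, +0.45) with the dominant negative
#' spike (Sp2) in the middle; its sigma values (4, 6.5, 5 ms) and inter-onset
#' gaps (18, 22 ms) were fixed once by a grid search on the closed-form
#' Gaussian Fourier transform so that the noiseless spike's amplitude
#' spectrum peaks at 19.5 Hz, inside the 18-20 Hz band characteristic of
#' rodent epileptic spikes. The spike complex lasts 70 ms.
#'
#' @param name Archetype name: `"WAG/Rij"`, `"GAERS"`, `"post-SE"` or `"PTE"`.
#' @param repetition_rate SWC repetition rate in Hz (> 0).
#' @param seizure_duration_range Length-2 numeric, seconds: range from which
#'   seizure durations are drawn.
#' @param spike_triplet Data frame with columns `rel_amplitude` (signed,
#'   Sp2 = -1) and `sigma` (seconds), 3 rows in temporal order, plus
#'   attribute-free `gap` handling via `spike_gaps`.
#' @param spike_gaps Length-2 numeric: inter-onset gaps between kernels 1-2
#'   and 2-3, seconds.
#' @param slow_wave List with `d1` (absolute duration of the first
#'   deflection, seconds — a spike-coupled trough whose length is roughly
#'   model-invariant), `fill_frac` (fraction of the SWC period occupied by
#'   the wave; the second deflection fills `fill_frac * period - d1`),
#'   `rel_amplitude` (first-deflection amplitude relative to the Sp2
#'   amplitude, positive; the deflection carries the spike's polarity). The
#'   second deflection's amplitude balances the first's area, so each cycle
#'   has zero net area.
#' @param amplitude_scale Absolute Sp2 amplitude in uV.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, repetition_rate, seizure_duration_range,
                           spike_triplet = default_spike_triplet(),
                           spike_gaps = c(0.018, 0.022),
                           slow_wave = list(d1 = 0.060, fill_frac = 0.9,
                                            rel_amplitude = 0.55),
                           amplitude_scale = 400) {
  if (repetition_rate <= 0) stop("'repetition_rate' must be > 0")
  stopifnot(nrow(spike_triplet) == 3, length(spike_gaps) == 2)
  s <- sign(spike_triplet$rel_amplitude)
  if (!(all(s == c(1, -1, 1)) || all(s == c(-1, 1, -1))))
    stop("spike triplet polarity must alternate")
  if (slow_wave$d1 <= 0 || slow_wave$fill_frac <= 0 || slow_wave$fill_frac > 1)
    stop("slow_wave d1 must be > 0 and fill_frac in (0, 1]")
  structure(list(name = name, repetition_rate = repetition_rate,
                 seizure_duration_range = seizure_duration_range,
                 spike_triplet = spike_triplet, spike_gaps = spike_gaps,
                 slow_wave = slow_wave, amplitude_scale = amplitude_scale),
            class = "archetype_spec")
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<archetype_spec> %s: %.1f Hz SWCs, seizures %.0f-%.0f s, Sp2 %g uV\n",
              x$name, x$repetition_rate, x$seizure_duration_range[1],
              x$seizure_duration_range[2], x$amplitude_scale))
  invisible(x)
}

#' The spike triplet shared by all built-in archetypes
#' @return Data frame with columns `rel_amplitude` and `sigma` (3 rows).
#' @export
default_spike_triplet <- function() {
  data.frame(rel_amplitude = c(0.35, -1, 0.45),
             sigma = c(0.004, 0.0065, 0.005))
}

#' Built-in epilepsy-model archetypes
#'
#' Returns the default specification for one of the four rat epilepsy-model
#' archetypes. Repetition rates follow the models' characteristic
#' mean discharge frequencies: 8.8 Hz (WAG/Rij), 7 Hz (GAERS), 6.4 Hz
#' (post-SE) and 2.4 Hz (PTE). The slow wave's second deflection is short in
#' the genetic absence models and longer in the acquired (post-SE, PTE)
#' models. Absolute amplitudes are order-of-magnitude choices (hundreds of
#' uV) since per-model amplitudes vary with electrode montage; they are
#' freely configurable. The slow-wave shape parameters (`d1`, `fill_frac`,
#' `rel_amplitude`) were calibrated once, per archetype, on noiseless trains
#' run through the extraction chain so that (i) the slow window's
#' amplitude-spectrum peak sits at the SWC repetition rate — the empirically
#' observed coupling between wave frequency and discharge rate — and (ii)
#' the extracted spike complex's spectral peak is the same across
#' archetypes, emulating the empirical model-invariance of the spike.
#'
#' @param name One of `"WAG/Rij"`, `"GAERS"`, `"post-SE"`, `"PTE"`.
#' @return An [archetype_spec()].
#' @export
archetype <- function(name = c("WAG/Rij", "GAERS", "post-SE", "PTE")) {
  name <- match.arg(name)
  switch(name,
    "WAG/Rij" = archetype_spec("WAG/Rij", 8.8, c(4, 8),
      slow_wave = list(d1 = 0.045, fill_frac = 0.90, rel_amplitude = 0.42),
      amplitude_scale = 400),
    "GAERS" = archetype_spec("GAERS", 7.0, c(4, 8),
      slow_wave = list(d1 = 0.045, fill_frac = 0.95, rel_amplitude = 0.50),
      amplitude_scale = 400),
    "post-SE" = archetype_spec("post-SE", 6.4, c(6, 12),
      slow_wave = list(d1 = 0.055, fill_frac = 0.85, rel_amplitude = 0.50),
      amplitude_scale = 350),
    "PTE" = archetype_spec("PTE", 2.4, c(6, 12),
      slow_wave = list(d1 = 0.055, fill_frac = 0.85, rel_amplitude = 0.50),
      amplitude_scale = 300)
  )
}

# internal: triplet kernel table (absolute amplitudes and onsets) for a spec,
# with the first kernel's onset at `t_start`
spec_triplet_kernels <- function(spec, t_start = 0, scale = 1) {
  t0 <- t_start + c(0, spec$spike_gaps[1], sum(spec$spike_gaps))
  data.frame(A = spec$spike_triplet$rel_amplitude * spec$amplitude_scale * scale,
             sigma = spec$spike_triplet$sigma,
             t0 = t0)
}

#' Duration of the archetype's spike complex
#'
#' Start = onset of the first kernel; end = onset of the third kernel plus
#' six times its sigma.
#'
#' @param spec An [archetype_spec()].
#' @return Duration in seconds.
#' @export
spec_sc_duration <- function(spec) {
  sum(spec$spike_gaps) + 6 * spec$spike_triplet$sigma[3]
}

#' Closed-form amplitude spectrum of the archetype spike complex
#'
#' The Fourier transform of a Gaussian pulse `A * exp(-(t - mu)^2 / (2 sigma^2))`
#' is `A * sigma * sqrt(2 pi) * exp(-2 pi^2 sigma^2 f^2) * exp(-2i pi f mu)`;
#' the triplet's amplitude spectrum is the modulus of the sum of the three
#' transforms (truncation of the kernels to their 6-sigma support is
#' neglected; its effect is below 1%). This is the generator's analytic
#' ground truth, independent of the numerical pipeline.
#'
#' @param spec An [archetype_spec()].
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of |FT| values (uV * s), same length as `freqs`.
#' @export
spike_spectrum_analytic <- function(spec, freqs) {
  ker <- spec_triplet_kernels(spec)
  mu <- ker$t0 + 3 * ker$sigma
  X <- rep(0 + 0i, length(freqs))
  for (i in 1:3) {
    X <- X + ker$A[i] * ker$sigma[i] * sqrt(2 * pi) *
      exp(-2 * pi^2 * ker$sigma[i]^2 * freqs^2) *
      exp(-2i * pi * freqs * mu[i])
  }
  Mod(X)
}

#' Analytic peak frequency of the archetype spike complex
#'
#' @param spec An [archetype_spec()].
#' @param band Search band in Hz.
#' @return Peak frequency (Hz) of [spike_spectrum_analytic()] in `band`.
#' @export
generator_spike_peak_hz <- function(spec, band = c(5, 50)) {
  opt <- stats::optimize(function(f) spike_spectrum_analytic(spec, f),
                         interval = band, maximum = TRUE, tol = 1e-6)
  opt$maximum
}

# internal: add one SWC cycle into `x` (sample vector) starting at time
# `t_cycle`, with the cycle lasting `period` seconds. Returns x.
add_swc_cycle <- function(x, rate, spec, t_cycle, period, scale = 1) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / rate
  ker <- spec_triplet_kernels(spec, t_start = t_cycle, scale = scale)
  for (i in 1:3) {
    idx <- which(tt >= ker$t0[i] & tt <= ker$t0[i] + 6 * ker$sigma[i])
    if (length(idx))
      x[idx] <- x[idx] + ker$A[i] *
        exp(-(tt[idx] - ker$t0[i] - 3 * ker$sigma[i])^2 / (2 * ker$sigma[i]^2))
  }
  # biphasic slow wave tiling most of the SWC period so the slow component
  # oscillates at the repetition rate. The first deflection (spike polarity,
  # coupled to the spike) has a fixed absolute duration d1 across models;
  # the opposite second deflection fills the rest of the wave, so it is
  # short at high repetition rates and long at low ones.
  sw <- spec$slow_wave
  w0 <- t_cycle
  wave_dur <- sw$fill_frac * period
  d1 <- min(sw$d1, 0.9 * wave_dur)
  d2 <- wave_dur - d1
  pol <- sign(spec$spike_triplet$rel_amplitude[2])
  a1 <- pol * sw$rel_amplitude * spec$amplitude_scale * scale
  a2 <- -a1 * d1 / d2           # zero net area per cycle
  i1 <- which(tt >= w0 & tt < w0 + d1)
  if (length(i1)) x[i1] <- x[i1] + a1 * sin(pi * (tt[i1] - w0) / d1)
  i2 <- which(tt >= w0 + d1 & tt < w0 + d1 + d2)
  if (length(i2)) x[i2] <- x[i2] + a2 * sin(pi * (tt[i2] - w0 - d1) / d2)
  x
}

#' Generate a single synthetic spike-wave complex
#'
#' One SWC cycle: the three-kernel spike complex plus the biphasic slow
#' wave, lasting `1 / repetition_rate` seconds.
#'
#' @param spec An [archetype_spec()].
#' @param amplitude_jitter Fractional amplitude jitter (>= 0): the whole
#'   cycle is scaled by `1 + amplitude_jitter * U(-1, 1)`.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param rate Sampling rate, Hz.
#' @return A list with `waveform` (numeric, uV), `duration` (s), `sc_end`
#'   (end of the spike complex, s) and `kernels` (the planted triplet).
#' @export
make_swc <- function(spec, amplitude_jitter = 0, seed = NULL, rate = 512) {
  if (amplitude_jitter < 0) stop("'amplitude_jitter' must be >= 0")
  with_seed(seed, {
    period <- 1 / spec$repetition_rate
    n <- round(period * rate)
    scale <- 1 + amplitude_jitter * stats::runif(1, -1, 1)
    x <- add_swc_cycle(numeric(n), rate, spec, 0, period, scale = scale)
    list(waveform = x, duration = period, sc_end = spec_sc_duration(spec),
         kernels = spec_triplet_kernels(spec, scale = scale))
  })
}

#' Generate a synthetic seizure (train of SWCs)
#'
#' Concatenates SWC cycles at the archetype's repetition rate with optional
#' per-cycle period jitter. A seizure is a train of recurring SWCs lasting
#' at least 1 s.
#'
#' @param spec An [archetype_spec()].
#' @param duration Seizure duration in seconds (>= 1).
#' @param rate_jitter Fractional per-cycle period jitter (>= 0); each cycle's
#'   period is `P * (1 + rate_jitter * U(-1, 1))`.
#' @param amplitude_jitter Per-cycle fractional amplitude jitter.
#' @param seed Optional integer seed.
#' @param rate Sampling rate, Hz.
#' @return A list with `samples` (numeric), `sc_onsets`, `sc_ends` (seconds,
#'   one per planted spike complex) and `duration`.
#' @export
make_seizure <- function(spec, duration, rate_jitter = 0, amplitude_jitter = 0,
                         seed = NULL, rate = 512) {
  if (duration < 1) stop("'duration' must be >= 1 s")
  P <- 1 / spec$repetition_rate
  if (duration < P) stop("'duration' must be at least one SWC period")
  with_seed(seed, {
    n <- round(duration * rate)
    x <- numeric(n)
    sc_dur <- spec_sc_duration(spec)
    onsets <- ends <- numeric(0)
    t <- 0
    repeat {
      period <- P * (1 + rate_jitter * stats::runif(1, -1, 1))
      if (t + period > duration + 1e-9) break
      scale <- 1 + amplitude_jitter * stats::runif(1, -1, 1)
      x <- add_swc_cycle(x, rate, spec, t, period, scale = scale)
      onsets <- c(onsets, t)
      ends <- c(ends, t + sc_dur)
      t <- t + period
    }
    list(samples = x, sc_onsets = onsets, sc_ends = ends, duration = duration)
  })
}

#' 1/f (pink) background noise
#'
#' Gaussian noise spectrally shaped to a 1/f power profile, scaled to the
#' requested RMS. Deterministic for a fixed RNG state.
#'
#' @param n Number of samples.
#' @param rms Target RMS in uV.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, rms = 1) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)           # symmetric frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * rms / rms(x)
}

#' Generate a full synthetic EEG record with ground truth
#'
#' Builds a record containing `n_seizures` SWC trains on a background of
#' pink noise plus sinusoidal baseline drift, with optional isolated
#' interictal spikes (single spike complexes at least 0.5 s away from any
#' other event) and broadband artifacts (bursts of very narrow transients
#' whose amplitude-spectrum peak falls outside the 10-30 Hz spike band).
#'
#' @param spec An [archetype_spec()].
#' @param total_duration Record duration, seconds.
#' @param n_seizures Number of seizures to plant.
#' @param noise_rms Pink-noise RMS in uV; the default gives a
#'   signal-to-noise ratio (Sp2 amplitude / noise RMS) of 10.
#' @param drift Length-2 numeric `c(amplitude_uV, freq_hz)` of the sinusoidal
#'   baseline drift; frequency should be below 1 Hz.
#' @param n_interictal Number of isolated interictal spike complexes.
#' @param n_artifacts Number of broadband artifact bursts.
#' @param rate_jitter,amplitude_jitter Per-cycle jitters, see [make_seizure()].
#' @param seed Optional integer seed (recorded in the ground truth).
#' @param rate Sampling rate, Hz.
#' @param bandpass If `TRUE`, apply a 1-100 Hz second-order Butterworth
#'   band-pass emulating the acquisition filter (default off).
#' @return A list with `record` (an [eeg_record()]) and `truth`, a ground
#'   truth list with `sc_onsets`, `sc_ends`, `interictal_onsets`,
#'   `artifact_spans` (two-column matrix), `generator_spike_peak_hz` (the
#'   closed-form spectral peak of the noiseless spike) and `seed`.
#' @export
make_record <- function(spec, total_duration, n_seizures,
                        noise_rms = spec$amplitude_scale / 10,
                        drift = c(50, 0.2),
                        n_interictal = 0, n_artifacts = 0,
                        rate_jitter = 0, amplitude_jitter = 0.1,
                        seed = NULL, rate = 512, bandpass = FALSE) {
  with_seed(seed, {
    n <- round(total_duration * rate)
    tt <- (seq_len(n) - 1) / rate
    gap_min <- 1.0  # minimum clear gap around seizures, seconds

    # seizure durations and placement
    dur <- if (n_seizures > 0)
      stats::runif(n_seizures, spec$seizure_duration_range[1],
                   spec$seizure_duration_range[2]) else numeric(0)
    free <- total_duration - sum(dur)
    if (n_seizures > 0 && free < (n_seizures + 1) * gap_min)
      stop("infeasible placement: seizures plus gaps exceed 'total_duration'")
    x <- numeric(n)
    sc_onsets <- sc_ends <- numeric(0)
    starts <- numeric(0)
    if (n_seizures > 0) {
      slack <- free - (n_seizures + 1) * gap_min
      u <- sort(stats::runif(n_seizures))
      extra <- diff(c(0, u)) * slack
      t <- gap_min
      for (s in seq_len(n_seizures)) {
        t <- t + extra[s]
        sz <- make_seizure(spec, dur[s], rate_jitter = rate_jitter,
                           amplitude_jitter = amplitude_jitter, rate = rate)
        i0 <- round(t * rate)
        idx <- i0 + seq_along(sz$samples)
        keep <- idx <= n
        x[idx[keep]] <- x[idx[keep]] + sz$samples[keep]
        sc_onsets <- c(sc_onsets, t + sz$sc_onsets)
        sc_ends <- c(sc_ends, t + sz$sc_ends)
        starts <- c(starts, t)
        t <- t + dur[s] + gap_min
      }
    }

    # free spans (outside seizures, with margin) for isolated events
    occupied <- cbind(starts - 0.5, starts + dur + 0.5)
    place_isolated <- function(n_ev, width, taken) {
      out <- numeric(0)
      tries <- 0
      while (length(out) < n_ev) {
        tries <- tries + 1
        if (tries > 2000) stop("infeasible placement of isolated events")
        cand <- stats::runif(1, 0.5, total_duration - width - 0.5)
        ok <- all(cand + width < taken[, 1] | cand > taken[, 2])
        if (ok) {
          out <- c(out, cand)
          taken <- rbind(taken, c(cand - 0.5, cand + width + 0.5))
        }
      }
      list(onsets = out, taken = taken)
    }

    interictal_onsets <- numeric(0)
    if (n_interictal > 0) {
      pl <- place_isolated(n_interictal, spec_sc_duration(spec), occupied)
      interictal_onsets <- sort(pl$onsets)
      occupied <- pl$taken
      for (t0 in interictal_onsets) {
        ker <- spec_triplet_kernels(spec, t_start = t0)
        for (i in 1:3) {
          idx <- which(tt >= ker$t0[i] & tt <= ker$t0[i] + 6 * ker$sigma[i])
          x[idx] <- x[idx] + ker$A[i] *
            exp(-(tt[idx] - ker$t0[i] - 3 * ker$sigma[i])^2 / (2 * ker$sigma[i]^2))
        }
      }
    }

    artifact_spans <- matrix(numeric(0), ncol = 2)
    if (n_artifacts > 0) {
      # burst of 4 alternating very narrow kernels: broadband, spectral peak
      # well above 30 Hz
      art_sig <- 0.0015; art_gap <- 0.008
      art_dur <- 3 * art_gap + 6 * art_sig
      pl <- place_isolated(n_artifacts, art_dur, occupied)
      art_on <- sort(pl$onsets)
      for (t0 in art_on) {
        for (i in 0:3) {
          a <- 1.2 * spec$amplitude_scale * (-1)^i
          k0 <- t0 + i * art_gap
          idx <- which(tt >= k0 & tt <= k0 + 6 * art_sig)
          x[idx] <- x[idx] + a *
            exp(-(tt[idx] - k0 - 3 * art_sig)^2 / (2 * art_sig^2))
        }
      }
      artifact_spans <- cbind(art_on, art_on + art_dur)
    }

    # background
    x <- x + pink_noise(n, noise_rms)
    if (drift[1] != 0)
      x <- x + drift[1] * sin(2 * pi * drift[2] * tt)
    if (bandpass) {
      bf <- signal::butter(2, c(1, 100) / (rate / 2), type = "pass")
      x <- as.numeric(signal::filter(bf, x))
    }

    rec <- eeg_record(x, rate = rate, channel_label = "synthetic",
                      model_label = spec$name)
    truth <- list(sc_onsets = sc_onsets, sc_ends = sc_ends,
                  interictal_onsets = interictal_onsets,
                  artifact_spans = artifact_spans,
                  generator_spike_peak_hz = generator_spike_peak_hz(spec),
                  seed = seed)
    list(record = rec, truth = truth)
  })
}

#' Inject a ramped DC shift and high-pass filter a record
#'
#' Adds a DC step (linearly ramped over `shift_duration`) at the middle of
#' the record and passes the result through a first-order Butterworth
#' high-pass filter. The filter converts the step into a slow decaying
#' transient — much longer than a genuine 70 ms spike complex — which is the
#' kind of spurious event that high-pass filtering of DC shifts produces.
#'
#' @param record An [eeg_record()].
#' @param shift DC shift amplitude in uV.
#' @param shift_duration Ramp duration in seconds.
#' @param highpass_cutoff High-pass cutoff frequency in Hz (> 0).
#' @param shift_time Start of the ramp in seconds; defaults to mid-record.
#' @return An [eeg_record()] with the filtered samples.
#' @export
inject_dc_shift_and_filter <- function(record, shift, shift_duration,
                                       highpass_cutoff, shift_time = NULL) {
  if (highpass_cutoff <= 0) stop("'highpass_cutoff' must be > 0")
  x <- record$samples
  n <- length(x)
  tt <- record_times(record)
  if (is.null(shift_time)) shift_time <- record_duration(record) / 2
  ramp <- pmin(pmax((tt - shift_time) / shift_duration, 0), 1) * shift
  bf <- signal::butter(1, highpass_cutoff / (record$rate / 2), type = "high")
  y <- as.numeric(signal::filter(bf, x + ramp))
  eeg_record(y, rate = record$rate, start_time = record$start_time,
             channel_label = record$channel_label,
             model_label = record$model_label)
}
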