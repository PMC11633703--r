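#' Amplitude spectrum of an arbitrary-length segment
#'
#' Computes the amplitude spectrum of a voltage segment of any length —
#' including sub-second spike-complex windows — on an arbitrary frequency
#' grid. The segment mean is subtracted, the samples define a continuous
#' piecewise-linear interpolant, and the spectrum is the exact continuous
#' Fourier integral of that interpolant:
#' `X(f) = dt * sinc(f*dt)^2 * sum_n x_n exp(-2i pi f n dt)`,
#' i.e. the discrete sum multiplied by the squared-sinc interpolation
#' kernel. The amplitude is normalized as `AS(f) = (2/T) |X(f)|` with `T`
#' the segment duration, so a unit-amplitude sinusoid has unit peak. Unlike
#' an FFT, the grid is independent of the segment length, so spectra of
#' 60 ms and 5 s segments live on the same axis.
#'
#' @param segment Numeric vector (uV), length >= 3.
#' @param rate Sampling rate, Hz.
#' @param freqs Strictly increasing frequency grid, Hz. Default 0.1-100 Hz
#'   in 0.1 Hz steps, fine enough to resolve sub-Hz peak differences.
#' @param demean Subtract the segment mean before transforming (default
#'   `TRUE`).
#' @return An [amplitude_spectrum()].
#' @export
sbf_amplitude_spectrum <- function(segment, rate, freqs = seq(0.1, 100, by = 0.1),
                                   demean = TRUE) {
  x <- as.numeric(segment)
  if (length(x) < 3) stop("'segment' must have at least 3 samples")
  if (any(diff(freqs) <= 0)) stop("'freqs' must be strictly increasing")
  if (demean) x <- x - mean(x)
  n <- length(x)
  dt <- 1 / rate
  T <- n * dt
  # chunk the frequency axis to bound the outer-product memory
  amps <- numeric(length(freqs))
  csize <- max(1L, floor(4e6 / n))
  nt <- (0:(n - 1)) * dt
  for (i0 in seq(1L, length(freqs), by = csize)) {
    ii <- i0:min(i0 + csize - 1L, length(freqs))
    ph <- 2 * pi * outer(freqs[ii], nt)
    re <- cos(ph) %*% x
    im <- sin(ph) %*% x
    amps[ii] <- sqrt(re^2 + im^2)
  }
  u <- freqs * dt
  sinc2 <- ifelse(u == 0, 1, (sin(pi * u) / (pi * u))^2)
  amplitude_spectrum(freqs, (2 / T) * dt * sinc2 * amps, segment_duration = T)
}

#' Peak frequency of an amplitude spectrum
#'
#' Finds the maximum of the spectrum within a band and refines it by
#' parabolic interpolation over the three surrounding grid points. Ties go
#' to the lower frequency; a maximum at a band edge is returned unrefined.
#'
#' @param as An [amplitude_spectrum()] (or any list with `freqs`, `amps`).
#' @param band Length-2 search band in Hz; must intersect the grid.
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(as, band = c(5, 50)) {
  sel <- which(as$freqs >= band[1] & as$freqs <= band[2])
  if (!length(sel)) stop("'band' does not intersect the frequency grid")
  a <- as$amps[sel]
  if (all(a == 0)) stop("undefined peak: spectrum is zero in the band")
  j <- which.max(a)           # first maximum -> lower-frequency tie-break
  i <- sel[j]
  if (i > 1 && i < length(as$freqs) &&
      i != sel[1] && i != sel[length(sel)]) {
    y1 <- as$amps[i - 1]; y2 <- as$amps[i]; y3 <- as$amps[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      return(as$freqs[i] + delta * (as$freqs[i + 1] - as$freqs[i]))
    }
  }
  as$freqs[i]
}

#' Power spectra of an EEG fragment and its components
#'
#' Squared amplitude spectra of a fragment (conventionally 5 s) of the
#' original EEG, of its slow component, and of its fast component. The
#' largest peak of the original-EEG power spectrum coincides with the slow
#' component's and lies close to the SWC repetition rate.
#'
#' @param record An [eeg_record()].
#' @param span Length-2 numeric: fragment `[start, end]` in seconds; must
#'   lie within the record.
#' @param freqs Frequency grid, Hz.
#' @param window,passes Detrending parameters, see [moving_average_trend()].
#' @return A list of class `power_spectrum_fragment` with `freqs`,
#'   `power_original`, `power_slow`, `power_fast` (uV^2) and `span`.
#' @export
power_spectrum_fragment <- function(record, span, freqs = seq(0.2, 100, by = 0.1),
                                    window = 0.040, passes = 2L) {
  dur <- record_duration(record)
  if (span[1] < 0 || span[2] > dur + 1e-9 || span[2] <= span[1])
    stop("'span' must lie within the record")
  i0 <- floor(span[1] * record$rate) + 1L
  i1 <- min(length(record$samples), floor(span[2] * record$rate))
  x <- record$samples[i0:i1]
  cp <- detrend(x, window = window, passes = passes, rate = record$rate)
  as_of <- function(v) sbf_amplitude_spectrum(v, record$rate, freqs)$amps^2
  structure(list(freqs = freqs,
                 power_original = as_of(x),
                 power_slow = as_of(cp$slow),
                 power_fast = as_of(cp$fast),
                 span = span),
            class = "power_spectrum_fragment")
}

#' Mean discharge frequency
#'
#' The number of spike-wave complexes in a fragment divided by the fragment
#' duration — the SWC repetition rate.
#'
#' @param events List of detected events, or an event count.
#' @param span_duration Fragment duration in seconds (> 0).
#' @return Frequency in Hz.
#' @export
mean_discharge_frequency <- function(events, span_duration) {
  if (span_duration <= 0) stop("'span_duration' must be > 0")
  n <- if (is.numeric(events) && length(events) == 1) events else length(events)
  n / span_duration
}

#' Average detected waveforms aligned at the Sp2 peak
#'
#' Events are aligned at the peak time of the middle (Sp2) kernel
#' (`t0 + 3 sigma`), resampled onto a common time axis spanning the longest
#' event, and averaged pointwise over the events covering each time point.
#' Fast and slow components are averaged separately, and the amplitude
#' spectra of both averaged waveforms are returned.
#'
#' @param events Non-empty list of `swc_event`s (or `sc_event`s; then only
#'   the fast average is computed).
#' @param freqs Frequency grid for the spectra of the averages.
#' @return A list of class `averaged_waveform` with `time` (seconds relative
#'   to the Sp2 peak), `mean_fast`, `mean_slow` (uV, `NA` where no event
#'   covers the time point), `n_events`, `as_fast`, `as_slow`.
#' @export
average_waveforms <- function(events, freqs = seq(0.5, 100, by = 0.1)) {
  if (!length(events)) stop("'events' must be non-empty")
  rate <- events[[1]]$rate
  dt <- 1 / rate
  rel_axis <- function(ev, start_f, wf_f) {
    i0 <- max(1L, floor(ev[[start_f]] * rate) + 1L)
    t <- (i0 - 1 + seq_along(ev[[wf_f]]) - 1) * dt - ev$t_sp2_peak
    list(t = t, y = ev[[wf_f]])
  }
  avg_of <- function(start_f, wf_f) {
    segs <- lapply(events, rel_axis, start_f = start_f, wf_f = wf_f)
    lo <- min(vapply(segs, function(s) s$t[1], 0))
    hi <- max(vapply(segs, function(s) s$t[length(s$t)], 0))
    grid <- seq(floor(lo / dt), ceiling(hi / dt)) * dt
    acc <- numeric(length(grid)); cnt <- integer(length(grid))
    for (s in segs) {
      y <- stats::approx(s$t, s$y, xout = grid, rule = 1)$y
      ok <- !is.na(y)
      acc[ok] <- acc[ok] + y[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    list(grid = grid, mean = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_))
  }
  fa <- avg_of("start", "waveform")
  has_slow <- !is.null(events[[1]]$slow_waveform)
  sa <- if (has_slow) avg_of("slow_start", "slow_waveform") else NULL
  grid <- fa$grid
  mean_slow <- if (has_slow) stats::approx(sa$grid, sa$mean, xout = grid, rule = 1)$y
               else rep(NA_real_, length(grid))
  as_of <- function(m) {
    v <- m[!is.na(m)]
    if (length(v) >= 3) sbf_amplitude_spectrum(v, rate, freqs) else NULL
  }
  structure(list(time = grid, mean_fast = fa$mean, mean_slow = mean_slow,
                 n_events = length(events),
                 as_fast = as_of(fa$mean), as_slow = as_of(mean_slow)),
            class = "averaged_waveform")
}

#' @export
print.averaged_waveform <- function(x, ...) {
  cat(sprintf("<averaged_waveform> %d events, axis [%.3f, %.3f] s\n",
              x$n_events, min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.averaged_waveform <- function(x, ...) {
  data.frame(time_s = x$time, fast_uv = x$mean_fast, slow_uv = x$mean_slow)
}
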