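#' EEG record
#'
#' Container for a uniformly sampled single-channel voltage trace. All
#' amplitudes are in microvolts and all times in seconds relative to the
#' record start; sample `i` covers time `(i - 1) / rate` (0-based,
#' left-aligned).
#'
#' @param samples Numeric vector of voltages (uV); must be finite, length >= 1.
#' @param rate Sampling frequency in Hz (> 0). Default 512, the rate used for
#'   rodent ECoG acquisition that this pipeline targets.
#' @param start_time Offset of the first sample in seconds.
#' @param channel_label Channel name.
#' @param model_label Optional epilepsy-model archetype tag, one of
#'   `"WAG/Rij"`, `"GAERS"`, `"post-SE"`, `"PTE"`, or `NULL`.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, rate = 512, start_time = 0,
                       channel_label = "EEG", model_label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  if (!is.null(model_label)) {
    model_label <- match.arg(model_label, c("WAG/Rij", "GAERS", "post-SE", "PTE"))
  }
  structure(
    list(samples = samples, rate = rate, start_time = start_time,
         channel_label = channel_label, model_label = model_label),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d samples @ %g Hz (%.2f s)%s\n",
              x$channel_label, length(x$samples), x$rate,
              length(x$samples) / x$rate,
              if (is.null(x$model_label)) "" else paste0(" [", x$model_label, "]")))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' Duration of an EEG record in seconds
#' @param record An `eeg_record`.
#' @return Duration in seconds (`n / rate`).
#' @export
record_duration <- function(record) length(record$samples) / record$rate

#' Sample times of an EEG record
#' @param record An `eeg_record`.
#' @return Numeric vector of times (seconds, relative to record start).
#' @export
record_times <- function(record) (seq_along(record$samples) - 1) / record$rate

#' Quasi-Gaussian kernel (QGK)
#'
#' The atomic element of the fragmentary-decomposition signal model: a
#' truncated Gaussian pulse fully defined by three parameters. The kernel
#' has support `[t0, t0 + 6 * sigma]` and attains its peak value `A` at
#' `t0 + 3 * sigma`; the value at the support endpoints is `A * exp(-4.5)`,
#' about 1.1% of the peak, so the truncation discontinuity is negligible.
#'
#' @param A Signed amplitude in uV; the sign encodes the kernel polarity.
#' @param sigma Shape parameter in seconds, > 0. The kernel duration is
#'   `6 * sigma`.
#' @param t0 Onset time in seconds.
#' @return An object of class `qgk`.
#' @export
qgk <- function(A, sigma, t0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("invalid QGK parameter: 'sigma' must be > 0")
  structure(list(A = A, sigma = sigma, t0 = t0), class = "qgk")
}

#' @export
print.qgk <- function(x, ...) {
  cat(sprintf("<qgk> A = %.3g uV, sigma = %.4g s, t0 = %.4g s (peak at %.4g s)\n",
              x$A, x$sigma, x$t0, x$t0 + 3 * x$sigma))
  invisible(x)
}

#' Evaluate a quasi-Gaussian kernel
#'
#' Returns `A * exp(-(t - t0 - 3*sigma)^2 / (2*sigma^2))` for
#' `t` in `[t0, t0 + 6*sigma]` and 0 elsewhere.
#'
#' @param k A `qgk` object, or a list/data.frame row with fields `A`,
#'   `sigma`, `t0`.
#' @param t Numeric vector of times (seconds).
#' @return Numeric vector of kernel values (uV), same length as `t`.
#' @export
qgk_eval <- function(k, t) {
  A <- k$A; sigma <- k$sigma; t0 <- k$t0
  if (!is.finite(sigma) || sigma <= 0)
    stop("invalid QGK parameter: 'sigma' must be > 0")
  v <- A * exp(-(t - t0 - 3 * sigma)^2 / (2 * sigma^2))
  v[t < t0 | t > t0 + 6 * sigma] <- 0
  v
}

#' Fragmentary-decomposition signal model
#'
#' An ordered sum of quasi-Gaussian kernels approximating a fast EEG
#' component, plus the RMS of the unexplained residual.
#'
#' @param kernels A data frame with columns `A`, `sigma`, `t0` (one row per
#'   kernel); rows are stored sorted by onset `t0`. Extra columns (e.g. fit
#'   diagnostics) are kept.
#' @param residual_rms RMS of `input - model` over the source span, in uV.
#' @param span Numeric length-2: `[start, end]` of the modelled span, seconds.
#' @param rate Sampling rate of the source signal (Hz), kept for convenience.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(kernels, residual_rms = NA_real_, span = c(NA_real_, NA_real_),
                         rate = NA_real_) {
  kernels <- as.data.frame(kernels)
  if (nrow(kernels) > 0) {
    stopifnot(all(c("A", "sigma", "t0") %in% names(kernels)))
    if (any(kernels$sigma <= 0)) stop("all kernel sigmas must be > 0")
    kernels <- kernels[order(kernels$t0), , drop = FALSE]
    rownames(kernels) <- NULL
  }
  structure(list(kernels = kernels, residual_rms = residual_rms,
                 span = span, rate = rate),
            class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf("<signal_model> %d kernels on [%.3g, %.3g] s, residual RMS %.3g uV\n",
              nrow(x$kernels), x$span[1], x$span[2], x$residual_rms))
  invisible(x)
}

#' Evaluate a signal model
#'
#' The model signal is the algebraic sum of all kernel evaluations.
#'
#' @param model A `signal_model`.
#' @param t Numeric vector of times (seconds).
#' @return Numeric vector (uV) of the reconstructed signal at `t`.
#' @export
model_eval <- function(model, t) {
  out <- numeric(length(t))
  ker <- model$kernels
  for (i in seq_len(nrow(ker))) {
    k <- ker[i, ]
    # only touch samples inside the kernel support
    idx <- which(t >= k$t0 & t <= k$t0 + 6 * k$sigma)
    if (length(idx))
      out[idx] <- out[idx] + k$A * exp(-(t[idx] - k$t0 - 3 * k$sigma)^2 / (2 * k$sigma^2))
  }
  out
}

#' Amplitude spectrum container
#'
#' @param freqs Strictly increasing frequency grid (Hz).
#' @param amps Nonnegative amplitudes (uV), same length as `freqs`.
#' @param segment_duration Duration of the analysed segment (seconds).
#' @return An object of class `amplitude_spectrum`.
#' @export
amplitude_spectrum <- function(freqs, amps, segment_duration) {
  if (length(freqs) != length(amps))
    stop("'freqs' and 'amps' must have the same length")
  if (any(diff(freqs) <= 0)) stop("'freqs' must be strictly increasing")
  if (any(amps < 0)) stop("'amps' must be nonnegative")
  structure(list(freqs = freqs, amps = amps,
                 segment_duration = segment_duration),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum> %d points, %.3g-%.3g Hz, segment %.4g s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$segment_duration))
  invisible(x)
}

#' @export
as.data.frame.amplitude_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs, amplitude_uv = x$amps)
}

#' @export
plot.amplitude_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$amps, type = "l", xlab = "Frequency (Hz)",
                 ylab = "Amplitude (uV)", ...)
  invisible(x)
}

# internal: root mean square
rms <- function(x) sqrt(mean(x^2))

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; with `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
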