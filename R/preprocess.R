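#' Two-pass moving-average trend of an EEG record
#'
#' Estimates the low-frequency component (baseline trend plus slow waves) by
#' applying a centered boxcar average of total width `window` to the signal,
#' `passes` times in succession (trend-on-trend). At 512 Hz the default
#' 40 ms window spans 21 samples: the central point plus 20 ms on each side.
#'
#' Edges are handled by shrinking the window symmetrically (at sample `i`
#' the half-width is `min(i - 1, n - i, h)`), so the output has the same
#' length as the input, affine signals are preserved exactly everywhere,
#' and no padding transients are introduced.
#'
#' @param record An [eeg_record()], or a plain numeric vector if `rate` is
#'   given.
#' @param window Total window width in seconds (default 0.040).
#' @param passes Number of smoothing passes (default 2).
#' @param rate Sampling rate in Hz; taken from `record` when it is an
#'   `eeg_record`.
#' @return Numeric vector: the trend, same length as the input.
#' @seealso [detrend()]
#' @export
moving_average_trend <- function(record, window = 0.040, passes = 2L, rate = NULL) {
  if (inherits(record, "eeg_record")) {
    x <- record$samples
    rate <- record$rate
  } else {
    x <- as.numeric(record)
    if (is.null(rate)) stop("'rate' is required when 'record' is a plain vector")
  }
  w <- round(window * rate)
  if (w < 2) stop("'window' must span at least 2 samples")
  if (w %% 2 == 0) w <- w + 1  # force odd so the window is symmetric
  h <- (w - 1L) / 2L
  n <- length(x)
  i <- seq_len(n)
  k <- pmin(i - 1L, n - i, h)
  for (p in seq_len(passes)) {
    S <- cumsum(c(0, x))
    x <- (S[i + k + 1L] - S[i - k]) / (2 * k + 1)
  }
  x
}

#' Detrend an EEG record into slow and fast components
#'
#' Splits the signal into a low-frequency component (the moving-average
#' trend, containing baseline drift and the slow waves of spike-wave
#' complexes) and a fast component (the original minus the trend, containing
#' the spikes). The decomposition is exactly additive:
#' `slow + fast == original` elementwise.
#'
#' @inheritParams moving_average_trend
#' @return A list of class `component_pair` with elements `slow`, `fast`
#'   (numeric vectors, uV) and `rate`.
#' @export
detrend <- function(record, window = 0.040, passes = 2L, rate = NULL) {
  if (inherits(record, "eeg_record")) {
    x <- record$samples
    rate <- record$rate
  } else {
    x <- as.numeric(record)
    if (is.null(rate)) stop("'rate' is required when 'record' is a plain vector")
  }
  slow <- moving_average_trend(x, window = window, passes = passes, rate = rate)
  structure(list(slow = slow, fast = x - slow, rate = rate),
            class = "component_pair")
}

#' @export
print.component_pair <- function(x, ...) {
  cat(sprintf("<component_pair> %d samples @ %g Hz; slow RMS %.3g, fast RMS %.3g uV\n",
              length(x$slow), x$rate, rms(x$slow), rms(x$fast)))
  invisible(x)
}
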