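#' Segment a fast component into half-waves
#'
#' A half-wave is a maximal run of samples of constant sign (intervals
#' between consecutive zero crossings). Samples that are exactly zero are
#' assigned to the preceding interval (ties at exact zeros go left); leading
#' zeros join the first signed run. Only half-waves whose extremum magnitude
#' reaches `min_amplitude` are returned.
#'
#' @param fast Numeric vector: the fast (detrended) component, uV.
#' @param rate Sampling rate, Hz.
#' @param min_amplitude Minimum |extremum| for a half-wave to be kept (uV).
#' @return Data frame with one row per half-wave: `start`, `end` (sample
#'   indices, inclusive), `peak_idx` (index of the extremum), `peak` (signed
#'   extremum value, uV). Ordered, disjoint. Zero rows if none qualify.
#' @export
segment_half_waves <- function(fast, rate, min_amplitude = 0) {
  if (min_amplitude < 0) stop("'min_amplitude' must be >= 0")
  n <- length(fast)
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_idx = integer(0), peak = numeric(0))
  if (n == 0) return(empty)
  s <- sign(fast)
  # zeros belong to the interval on their left; leading zeros to the first run
  if (any(s != 0)) {
    nz <- which(s != 0)
    filled <- s
    idx <- cummax(ifelse(s != 0, seq_len(n), 0L))
    filled[idx > 0] <- s[idx[idx > 0]]
    if (nz[1] > 1) filled[seq_len(nz[1] - 1)] <- s[nz[1]]
    s <- filled
  } else {
    return(empty)
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # vectorized per-run extremum: sort by (run, |x|), keep the last of each run
  runid <- rep.int(seq_along(r$lengths), r$lengths)
  o <- order(runid, abs(fast))
  peak_idx <- o[!duplicated(runid[o], fromLast = TRUE)]
  peak <- fast[peak_idx]
  keep <- abs(peak) >= min_amplitude & abs(peak) > 0
  data.frame(start = starts, end = ends, peak_idx = peak_idx,
             peak = peak)[keep, , drop = FALSE]
}

#' Fit a quasi-Gaussian kernel to one half-wave
#'
#' Least-squares fit of the Gaussian kernel over the half-wave interval
#' (Levenberg-Marquardt). `sigma` is bounded to `sigma_bounds` (default
#' 1-12 ms) so that kernels model the fast spike transients; single-sample
#' noise blips and broad slow humps are excluded. If the optimizer fails,
#' the initialization is returned with `converged = FALSE`.
#'
#' Initialization: `A` at the extremum value, `sigma` from the half-wave's
#' full width at half maximum around the extremum (`FWHM / 2.355`, falling
#' back to interval length / 6 when the flanks are clipped by the interval),
#' `t0` so the kernel peak sits on the extremum. The least-squares fit is
#' restricted to the extremum's neighborhood (3 initial sigmas on each side
#' of the peak) and includes a local constant baseline term that is *not*
#' part of the returned kernel: when a half-wave carries a sharp transient
#' riding on a broad low shoulder (typically residual slow-wave leakage), a
#' plain whole-interval fit drifts to a wide compromise kernel, whereas the
#' local baseline-corrected fit recovers the transient's true width and
#' leaves the shoulder in the residual, where later peeling iterations model
#' it separately. Accurate widths matter downstream: the spike-complex end
#' time is defined through the third kernel's sigma.
#'
#' @param fast Numeric vector, the fast component (uV).
#' @param rate Sampling rate, Hz.
#' @param interval Length-2 integer: first and last sample index of the
#'   half-wave.
#' @param sigma_bounds Length-2 numeric bounds on sigma, seconds.
#' @return A list with `A`, `sigma`, `t0`, `nrmse` (residual RMS divided by
#'   the data RMS over the interval) and `converged`.
#' @export
fit_qgk <- function(fast, rate, interval, sigma_bounds = c(0.001, 0.012)) {
  i0 <- interval[1]; i1 <- interval[2]
  if (i1 < i0) stop("'interval' must be nonempty")
  y <- fast[i0:i1]
  t <- (seq(i0, i1) - 1) / rate
  len <- (i1 - i0 + 1) / rate
  jmax <- which.max(abs(y))
  # sigma from the full width at half maximum around the extremum
  half <- abs(y[jmax]) / 2
  jl <- jmax; while (jl > 1 && abs(y[jl - 1]) > half) jl <- jl - 1
  jr <- jmax; while (jr < length(y) && abs(y[jr + 1]) > half) jr <- jr + 1
  sig0 <- if (jl > 1 && jr < length(y)) (jr - jl + 1) / rate / 2.355 else len / 6
  sig0 <- min(max(sig0, sigma_bounds[1]), sigma_bounds[2])
  init <- list(A = y[jmax], sigma = sig0,
               t0 = max(t[1] - 3 * sigma_bounds[2], t[jmax] - 3 * sig0))
  tpk <- t[jmax]
  cmax <- abs(y[jmax]) / 2
  # local fit window around the extremum
  hw <- max(3L, ceiling(3 * sig0 * rate))
  keep <- max(1L, jmax - hw):min(length(y), jmax + hw)
  y <- y[keep]; t <- t[keep]
  score <- function(p) rms(y - p$A * exp(-(t - p$t0 - 3 * p$sigma)^2 / (2 * p$sigma^2)))
  out <- c(init, nrmse = score(init) / max(rms(y), .Machine$double.eps),
           converged = FALSE)
  if (length(y) >= 5) {
    # parametrized on the peak time tp = t0 + 3 sigma, which is bounded to
    # the half-wave; the baseline c0 is bounded to half the extremum
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A * exp(-(t - tp)^2 / (2 * sigma^2)) + c0,
        start = list(A = init$A, sigma = init$sigma, tp = tpk, c0 = 0),
        lower = c(A = -Inf, sigma = sigma_bounds[1], tp = t[1], c0 = -cmax),
        upper = c(A = Inf, sigma = sigma_bounds[2], tp = t[length(t)], c0 = cmax),
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- as.list(stats::coef(fit))
      p <- list(A = cf$A, sigma = cf$sigma, t0 = cf$tp - 3 * cf$sigma)
      out <- c(p, nrmse = score(p) / max(rms(y), .Machine$double.eps),
               converged = TRUE)
    }
  }
  out$init <- init
  out
}

#' Fragmentary decomposition of a fast component
#'
#' Models the signal as an ordered sum of quasi-Gaussian kernels by
#' sequential greedy peeling: segment the residual into half-waves, fit a
#' kernel to the half-wave with the largest extremum, subtract it, and
#' repeat until no half-wave's extremum exceeds `min_amplitude`. Fitting the
#' dominant extrema first keeps the large Sp2 spike kernels robust at low
#' signal-to-noise ratios. A candidate whose subtraction would not reduce
#' the local residual RMS is skipped permanently, which guarantees that the
#' residual RMS is non-increasing over iterations.
#'
#' @param fast Numeric vector (uV) or a `component_pair` (its `$fast` is
#'   used).
#' @param rate Sampling rate, Hz (taken from a `component_pair` input).
#' @param min_amplitude Amplitude floor in uV. The default (`NULL`) is
#'   `3 * median(|diff(fast)|) / sqrt(2)`, a noise-floor estimate built on
#'   successive differences: differencing suppresses the smooth slow-wave
#'   leakage that survives detrending, and the median suppresses the sparse
#'   large spike transients, so the estimate tracks the background noise
#'   even when discharge trains fill most of the record (where a plain MAD
#'   of the samples reflects the spikes themselves). A floor of 1% of the
#'   maximum absolute amplitude is imposed so that noise-free signals
#'   decompose into finitely many kernels.
#' @param max_kernels Iteration cap; default allows 100 kernels per second.
#'   Hitting the cap returns the partial model with a warning.
#' @param sigma_bounds Bounds on fitted sigma, seconds.
#' @return A [signal_model()]; kernels carry `nrmse` and `converged`
#'   diagnostics from [fit_qgk()].
#' @export
decompose <- function(fast, rate = NULL, min_amplitude = NULL,
                      max_kernels = NULL, sigma_bounds = c(0.001, 0.012)) {
  if (inherits(fast, "component_pair")) {
    rate <- fast$rate
    fast <- fast$fast
  }
  if (is.null(rate)) stop("'rate' is required")
  n <- length(fast)
  if (is.null(min_amplitude)) {
    min_amplitude <- if (n >= 2)
      max(3 * stats::median(abs(diff(fast))) / sqrt(2),
          0.01 * max(abs(fast))) else 0
  }
  if (is.null(max_kernels))
    max_kernels <- max(20L, ceiling(100 * n / rate))

  residual <- fast
  kernels <- vector("list", 0)
  blocked <- integer(0)   # extremum sample indices of rejected half-waves
  repeat {
    hw <- segment_half_waves(residual, rate, min_amplitude)
    if (nrow(hw)) hw <- hw[!(hw$peak_idx %in% blocked), , drop = FALSE]
    if (!nrow(hw)) break
    top <- hw[which.max(abs(hw$peak)), ]
    f <- fit_qgk(residual, rate, c(top$start, top$end), sigma_bounds)
    # samples the kernel touches (support may extend past the half-wave)
    support <- function(p) {
      # samples strictly inside the truncated kernel's support
      j0 <- max(1L, as.integer(ceiling(p$t0 * rate - 1e-9)) + 1L)
      j1 <- min(n, as.integer(floor((p$t0 + 6 * p$sigma) * rate + 1e-9)) + 1L)
      jj <- j0:j1
      list(jj = jj,
           kv = p$A * exp(-((jj - 1) / rate - p$t0 - 3 * p$sigma)^2 /
                            (2 * p$sigma^2)))
    }
    improves <- function(s) rms(residual[s$jj] - s$kv) < rms(residual[s$jj])
    s <- support(f)
    if (!improves(s)) {
      # fall back to the initialization kernel (centered on the extremum);
      # if even that does not reduce the local residual, retire the half-wave
      f <- c(f$init, nrmse = f$nrmse, converged = FALSE)
      s <- support(f)
      if (!improves(s)) {
        blocked <- c(blocked, top$peak_idx)
        next
      }
    }
    residual[s$jj] <- residual[s$jj] - s$kv
    kernels[[length(kernels) + 1L]] <-
      data.frame(A = f$A, sigma = f$sigma, t0 = f$t0,
                 nrmse = f$nrmse, converged = f$converged)
    if (length(kernels) >= max_kernels) {
      warning("decompose: iteration cap reached; returning partial model")
      break
    }
  }
  ker <- if (length(kernels)) do.call(rbind, kernels)
         else data.frame(A = numeric(0), sigma = numeric(0), t0 = numeric(0),
                         nrmse = numeric(0), converged = logical(0))
  signal_model(ker, residual_rms = if (n) rms(residual) else 0,
               span = c(0, n / rate), rate = rate)
}
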