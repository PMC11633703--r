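#' Per-record peak-frequency summary
#'
#' Sample mean, sample standard deviation (n - 1 denominator), histogram
#' mode (1 Hz bins on \[0, 50\] Hz, lower bin on ties) and count of a
#' record's amplitude-spectrum peak frequencies.
#'
#' @param peaks Numeric vector of peak frequencies (Hz), length >= 2.
#' @return A list with `mean`, `sd`, `mode`, `n`.
#' @export
summarize_record <- function(peaks) {
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2) stop("at least 2 peak values are required")
  h <- peak_histogram(list(peaks))
  list(mean = mean(peaks), sd = stats::sd(peaks), mode = h$mode,
       n = length(peaks))
}

#' Histogram of peak frequencies
#'
#' Uniform-bin histogram of amplitude-spectrum peak frequencies with its
#' mode (center of the tallest bin; lower bin on ties).
#'
#' @param peak_lists List of numeric vectors (Hz); the histogram pools all
#'   of them.
#' @param bin_edges Uniform bin edges in Hz (default 1 Hz bins on 0-50 Hz).
#' @return An object of class `peak_histogram` with `bin_edges`, `counts`,
#'   `mode`, `n`.
#' @export
peak_histogram <- function(peak_lists, bin_edges = seq(0, 50, by = 1)) {
  values <- unlist(peak_lists, use.names = FALSE)
  if (any(values < min(bin_edges) | values > max(bin_edges)))
    stop("peak values fall outside the histogram range")
  counts <- hist(values, breaks = bin_edges, plot = FALSE,
                 right = FALSE, include.lowest = TRUE)$counts
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  structure(list(bin_edges = bin_edges, counts = counts,
                 mode = centers[which.max(counts)], n = length(values)),
            class = "peak_histogram")
}

#' @export
print.peak_histogram <- function(x, ...) {
  cat(sprintf("<peak_histogram> %d values, mode %.1f Hz\n", x$n, x$mode))
  invisible(x)
}

#' Pooled meta-histogram of per-animal peak frequencies
#'
#' Pools the amplitude-spectrum peak frequencies of all animals of one model
#' into a single histogram.
#'
#' @param per_animal_peaks List of numeric vectors, one per animal/record.
#' @param bin_edges Uniform bin edges in Hz.
#' @return A `peak_histogram`.
#' @export
meta_histogram <- function(per_animal_peaks, bin_edges = seq(0, 50, by = 1)) {
  if (!length(per_animal_peaks) || any(!lengths(per_animal_peaks)))
    stop("all per-animal peak lists must be non-empty")
  peak_histogram(per_animal_peaks, bin_edges)
}

#' Normality tests for peak-frequency samples
#'
#' Kolmogorov-Smirnov with mean and SD estimated from the sample (the
#' Lilliefors variant, computed with `nortest::lillie.test`) and the
#' Shapiro-Wilk test.
#'
#' @param values Numeric vector, n >= 4, non-degenerate.
#' @return A list with `ks` and `shapiro`, each `(statistic, p)`, plus
#'   `ks_variant = "Lilliefors"`.
#' @export
normality_tests <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("at least 4 values are required")
  if (stats::sd(values) == 0) stop("degenerate input: zero variance")
  ks <- nortest::lillie.test(values)
  sw <- stats::shapiro.test(values)
  list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       ks_variant = "Lilliefors")
}

#' One-way between-subjects ANOVA with Bonferroni post-hocs
#'
#' Parametric one-way ANOVA with the epilepsy model as between-subjects
#' factor, applied to per-record summary values (one value per animal).
#' Effect size is eta squared (`SS_between / SS_total`). Post-hoc pairwise
#' two-sample t tests (pooled variance, two-sided) are Bonferroni-corrected
#' over all pairs.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A list with `anova` (`F`, `df_between`, `df_within`, `p`,
#'   `eta_sq`) and `posthoc`, a data frame with one row per pair
#'   (`group1`, `group2`, `t`, `p`, `p_bonferroni`).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  ssb <- tab["group", "Sum Sq"]
  sse <- tab["Residuals", "Sum Sq"]
  res <- list(F = tab["group", "F value"],
              df_between = tab["group", "Df"],
              df_within = tab["Residuals", "Df"],
              p = tab["group", "Pr(>F)"],
              eta_sq = ssb / (ssb + sse))
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  ph <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, p = NA_real_, p_bonferroni = NA_real_)
  for (i in seq_len(m)) {
    tt <- stats::t.test(groups[[pairs[1, i]]], groups[[pairs[2, i]]],
                        var.equal = TRUE)
    ph$t[i] <- unname(tt$statistic)
    ph$p[i] <- tt$p.value
    ph$p_bonferroni[i] <- min(1, tt$p.value * m)
  }
  list(anova = res, posthoc = ph)
}
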