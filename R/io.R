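# EEG file I/O: CSV and 16-bit EDF. The EDF reader/writer is a minimal
# implementation of the European Data Format specification (ASCII header,
# little-endian 16-bit samples, physical dimension uV); continuous
# single-session files only, which is all this pipeline needs.

#' Read an EEG file
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#'   CSV files must have either a `time,uV` pair of columns (rate inferred
#'   from the time steps) or a single `uV` column plus a `# rate: <Hz>`
#'   comment line.
#' @return A list of [eeg_record()]s (one per channel; CSV files carry one).
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, csv = read_eeg_csv(path), edf = read_eeg_edf(path))
}

read_eeg_csv <- function(path) {
  first <- readLines(path, n = 5)
  rate <- NA_real_
  m <- regmatches(first, regexec("^#\\s*rate:\\s*([0-9.]+)", first))
  for (g in m) if (length(g) == 2) rate <- as.numeric(g[2])
  df <- utils::read.csv(path, comment.char = "#")
  if (all(c("time", "uV") %in% names(df))) {
    rate <- 1 / stats::median(diff(df$time))
    samples <- df$uV
  } else if ("uV" %in% names(df)) {
    if (is.na(rate)) stop("CSV parse error: no time column and no '# rate:' header")
    samples <- df$uV
  } else stop("CSV parse error: expected columns 'time,uV' or 'uV'")
  list(eeg_record(samples, rate = rate,
                  channel_label = sub("\\.[^.]*$", "", basename(path))))
}

#' Write an EEG record
#'
#' @param record An [eeg_record()], or a list of them (EDF only).
#' @param path Output path.
#' @param format `"csv"` or `"edf"` (guessed from the extension by default).
#'   EDF quantizes to 16 bits over the channel's physical range.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(record, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    stopifnot(inherits(record, "eeg_record"))
    con <- file(path, "w")
    writeLines(sprintf("# rate: %g", record$rate), con)
    utils::write.csv(data.frame(time = record_times(record),
                                uV = record$samples),
                     con, row.names = FALSE)
    close(con)
  } else {
    if (inherits(record, "eeg_record")) record <- list(record)
    write_eeg_edf(record, path)
  }
  invisible(path)
}

# --- minimal EDF ------------------------------------------------------------

pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

write_eeg_edf <- function(records, path) {
  rates <- vapply(records, `[[`, 0, "rate")
  ns <- length(records)
  nsamp <- vapply(records, function(r) length(r$samples), 0L)
  dur <- max(nsamp / rates)
  # one data record holding the whole signal keeps the writer simple
  spr <- as.integer(round(rates * dur))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("swdkit", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(1, 8)
  wr(format(dur, digits = 8), 8); wr(ns, 8)
  phys_min <- phys_max <- numeric(ns)
  for (r in records) wr(r$channel_label, 16)
  for (r in records) wr("AgAgCl electrode", 80)
  for (r in records) wr("uV", 8)
  for (i in seq_len(ns)) {
    rng <- range(records[[i]]$samples)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    phys_min[i] <- rng[1]; phys_max[i] <- rng[2]
  }
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr[i], 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    x <- records[[i]]$samples
    x <- c(x, rep(0, spr[i] - length(x)))
    dig <- round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (!length(out) || nchar(out) < n) stop("EDF parse error: truncated header")
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(8))
  if (is.na(ns) || ns < 1) stop("EDF parse error: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(c(pmin_, pmax_, dmin, dmax, spr))))
    stop("EDF parse error: malformed signal header")
  chans <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
      chans[[i]] <- c(chans[[i]], phys)
    }
  }
  lapply(seq_len(ns), function(i)
    eeg_record(chans[[i]], rate = spr[i] / rec_dur, channel_label = labels[i]))
}

#' Write an event table to CSV
#'
#' @param df Event data frame from [events_df()].
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header comments
#'   (provenance: seed, config hash, package version).
#' @return `path`, invisibly.
#' @export
write_events <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write ground truth as a JSON sidecar
#' @param truth Ground-truth list from [make_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  truth$artifact_spans <- apply(truth$artifact_spans, 1, identity, simplify = FALSE)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a signal model to JSON
#'
#' Serializes the kernel list (`A`, `sigma`, `t0` per kernel) together with
#' the residual RMS and modelled span.
#'
#' @param model A [signal_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_model <- function(model, path) {
  jsonlite::write_json(
    list(kernels = model$kernels[, c("A", "sigma", "t0")],
         residual_rms = model$residual_rms, span = model$span,
         rate = model$rate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
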