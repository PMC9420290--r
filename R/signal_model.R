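# Unit conventions shared by all modules: times are milliseconds throughout
# the API; sample indices appear only inside inner loops. The single
# ms->samples conversion rule is round-half-away-from-zero, so behaviour is
# identical at fs = 1000 and fs = 2000.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a duration in milliseconds to a whole number of samples
#'
#' The package-wide conversion rule: \code{n = round(t_ms * fs / 1000)} with
#' halves rounded away from zero.
#'
#' @param t_ms duration(s) in milliseconds.
#' @param fs sampling rate in Hz.
#' @return integer vector of sample counts.
#' @export
ms_to_samples <- function(t_ms, fs) as.integer(round_half_away(t_ms * fs / 1000))

# time of 1-based sample index i / index of time t for a record
sample_time <- function(rec, i) rec$t0 + (i - 1) * 1000 / rec$fs
time_sample <- function(rec, t_ms) ms_to_samples(t_ms - rec$t0, rec$fs) + 1L

#' Single-channel bipolar IEGM record
#'
#' Container for a raw electrogram: amplitude samples (mV), sampling rate and
#' the time of the first sample.
#'
#' @param samples numeric vector of amplitudes in mV; must be non-empty and
#'   finite.
#' @param fs sampling rate in Hz (clinical recordings are 1000 or 2000).
#' @param record_id identifier string.
#' @param t0 time of the first sample in ms (default 0).
#' @return an object of class \code{iegm_record} with fields
#'   \code{record_id}, \code{samples}, \code{fs}, \code{t0}.
#' @export
iegm_record <- function(samples, fs, record_id = "rec", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("amplitudes must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar")
  structure(list(record_id = as.character(record_id)[1L],
                 samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "iegm_record")
}

#' Duration of a record in milliseconds
#' @param rec an \code{iegm_record}.
#' @return \code{(length(samples) - 1) / fs * 1000}.
#' @export
duration_ms <- function(rec) (length(rec$samples) - 1) / rec$fs * 1000

#' @export
print.iegm_record <- function(x, ...) {
  cat(sprintf("<iegm_record '%s'> %d samples @ %g Hz (%.1f ms), t0 = %g ms\n",
              x$record_id, length(x$samples), x$fs, duration_ms(x), x$t0))
  invisible(x)
}

aa_sources <- c("raw_relen", "raw_amm", "corrected", "annotated_truth", "barycenter")

#' Ordered sequence of local activation times
#'
#' Strictly increasing activation times (ms) on one record, tagged with their
#' provenance. For every source except \code{annotated_truth} consecutive
#' activations must be at least \code{refractory} ms apart (the physiological
#' refractory contract of the pulmonary veins).
#'
#' @param lats numeric vector of activation times in ms, strictly increasing.
#' @param record_id identifier of the record the times belong to.
#' @param source one of \code{"raw_relen"}, \code{"raw_amm"},
#'   \code{"corrected"}, \code{"annotated_truth"}, \code{"barycenter"}.
#' @param refractory minimal allowed interval in ms for detector-derived
#'   sources (default 70).
#' @param record optional \code{iegm_record}; when given, all times must lie
#'   within the record span.
#' @return an object of class \code{activation_sequence}.
#' @export
activation_sequence <- function(lats, record_id = "rec", source = "annotated_truth",
                                refractory = 70, record = NULL) {
  source <- match.arg(source, aa_sources)
  lats <- as.numeric(lats)
  if (length(lats) && !all(is.finite(lats))) stop("activation times must be finite")
  if (length(lats) > 1L) {
    d <- diff(lats)
    if (any(d <= 0)) stop("activation times must be strictly increasing")
    if (source != "annotated_truth" && any(d < refractory - 1e-6))
      stop(sprintf("refractory violation: interval %.3f ms < %g ms", min(d), refractory))
  }
  if (!is.null(record)) {
    if (length(lats) &&
        (min(lats) < record$t0 - 1e-9 || max(lats) > record$t0 + duration_ms(record) + 1e-9))
      stop("activation times outside the record span")
  }
  structure(list(record_id = as.character(record_id)[1L], lats = lats, source = source),
            class = "activation_sequence")
}

#' @export
print.activation_sequence <- function(x, ...) {
  cat(sprintf("<activation_sequence '%s'> %d activations, source = %s\n",
              x$record_id, length(x$lats), x$source))
  if (length(x$lats) > 1L) {
    d <- diff(x$lats)
    cat(sprintf("  intervals: mean %.1f ms, min %.1f ms, max %.1f ms\n",
                mean(d), min(d), max(d)))
  }
  invisible(x)
}

#' @export
length.activation_sequence <- function(x) length(x$lats)

#' Mean and standard deviation of activation intervals
#'
#' The population mean and standard deviation of the successive differences
#' of an activation sequence; the basis of the sensing-correction weight
#' functions.
#'
#' @param seq an \code{activation_sequence} (or a numeric vector of times).
#' @return object of class \code{interval_stats} with fields \code{mean_aa},
#'   \code{sigma_aa} (population SD) and \code{n_intervals}.
#' @export
interval_stats <- function(seq) {
  lats <- if (inherits(seq, "activation_sequence")) seq$lats else as.numeric(seq)
  if (length(lats) < 2L) stop("insufficient activations for statistics")
  d <- diff(lats)
  structure(list(mean_aa = mean(d),
                 sigma_aa = sqrt(mean((d - mean(d))^2)),
                 n_intervals = length(d)),
            class = "interval_stats")
}

#' @export
print.interval_stats <- function(x, ...) {
  cat(sprintf("<interval_stats> meanAA %.1f ms, sigmaAA %.1f ms (n = %d)\n",
              x$mean_aa, x$sigma_aa, x$n_intervals))
  invisible(x)
}

#' Read an IEGM record from disk
#'
#' CSV files carry two columns (\code{time_ms}, \code{amplitude_mV}) with a
#' header row, or a single amplitude column together with an explicit
#' \code{fs}. The time grid must be uniform to within 1 ppm. WFDB records are
#' read from the \code{.hea} header plus a format-16 or format-212 signal
#' file.
#'
#' @param path file path (for WFDB, the path to the \code{.hea} file or the
#'   record name without extension).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @param fs sampling rate in Hz, required for single-column CSV.
#' @param channel channel to extract from a multi-signal WFDB record.
#' @return an \code{iegm_record}.
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL, channel = 1L) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path, fs = fs) else read_record_wfdb(path, channel)
}

read_record_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.csv(path)
  if (nrow(df) == 0L) stop("empty record file: ", path)
  rid <- sub("\\.[^.]*$", "", basename(path))
  if (ncol(df) >= 2L) {
    t <- as.numeric(df[[1L]]); x <- as.numeric(df[[2L]])
    if (length(t) < 2L) stop("record must contain at least two samples")
    dt <- diff(t)
    dt0 <- stats::median(dt)
    if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * dt0))
      stop("non-uniform time grid (spacing deviates by more than 1 ppm)")
    iegm_record(x, fs = 1000 / dt0, record_id = rid, t0 = t[1L])
  } else {
    if (is.null(fs)) stop("single-column CSV requires an explicit fs")
    iegm_record(as.numeric(df[[1L]]), fs = fs, record_id = rid)
  }
}

# Minimal WFDB reader: header + signal formats 16 (int16 LE) and 212
# (packed 12-bit). Amplitudes are converted to physical units via gain and
# baseline; a zero gain falls back to the WFDB default of 200 adu/mV.
read_record_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file does not exist: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rid <- sub("/.*$", "", hdr[1L])
  nsig <- as.integer(hdr[2L])
  fs <- if (length(hdr) >= 3L) as.numeric(sub("/.*$", "", hdr[3L])) else 250
  if (nsig < 1L || length(lines) < 1L + nsig) stop("malformed WFDB header: ", hea)
  if (channel < 1L || channel > nsig) stop("channel out of range")
  sig <- strsplit(trimws(lines[2L:(1L + nsig)]), "\\s+")
  fnames <- vapply(sig, `[`, "", 1L)
  fmts <- vapply(sig, function(s) sub("x.*$|:.*$|\\+.*$", "", s[2L]), "")
  gain <- vapply(sig, function(s) {
    g <- if (length(s) >= 3L) as.numeric(sub("\\(.*$|/.*$", "", s[3L])) else 200
    if (!is.finite(g) || g == 0) 200 else g
  }, 0)
  base <- vapply(sig, function(s) {
    b <- if (length(s) >= 3L && grepl("\\(", s[3L]))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", s[3L])) else 0
    if (is.finite(b)) b else 0
  }, 0)
  if (length(unique(fnames)) != 1L)
    stop("multi-file WFDB records are not supported")
  dat <- file.path(dirname(hea), fnames[1L])
  if (!file.exists(dat)) stop("signal file does not exist: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  fmt <- fmts[1L]
  if (fmt == "16") {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  } else if (fmt == "212") {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b1 <- b[seq(1L, n3, by = 3L)]; b2 <- b[seq(2L, n3, by = 3L)]; b3 <- b[seq(3L, n3, by = 3L)]
    s1 <- bitwOr(b1, bitwShiftL(bitwAnd(b2, 15L), 8L))
    s2 <- bitwOr(b3, bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 15L), 8L))
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
  } else stop("unsupported WFDB signal format: ", fmt)
  nsamp <- length(v) %/% nsig
  v <- v[seq_len(nsamp * nsig)]
  ch <- v[seq(channel, length(v), by = nsig)]
  iegm_record((ch - base[channel]) / gain[channel], fs = fs, record_id = rid)
}

#' Write an IEGM record to CSV
#'
#' Two columns (\code{time_ms}, \code{amplitude_mV}) with a header row,
#' readable back by \code{\link{read_record}}.
#'
#' @param rec an \code{iegm_record}.
#' @param path output file path.
#' @export
write_record <- function(rec, path) {
  df <- data.frame(time_ms = sample_time(rec, seq_along(rec$samples)),
                   amplitude_mV = rec$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an activation sequence to disk
#'
#' CSV output has columns \code{record_id}, \code{source}, \code{lat_ms}
#' (header only when the sequence is empty); JSON output follows the schema
#' \code{{record_id, source, lats_ms}}. Round-tripping through
#' \code{\link{read_annotations}} preserves times to better than 1e-6 ms.
#'
#' @param seq an \code{activation_sequence}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}; default inferred from the
#'   file extension.
#' @export
write_annotations <- function(seq, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- data.frame(record_id = rep(seq$record_id, length(seq$lats)),
                     source = rep(seq$source, length(seq$lats)),
                     lat_ms = seq$lats)
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(record_id = seq$record_id, source = seq$source,
                              lats_ms = seq$lats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an activation sequence written by \code{\link{write_annotations}}
#'
#' @param path file path (CSV or JSON).
#' @param format \code{"csv"} or \code{"json"}; default inferred from the
#'   file extension.
#' @return an \code{activation_sequence}.
#' @export
read_annotations <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- read.csv(path, colClasses = c("character", "character", "numeric"))
    if (nrow(df) == 0L)
      return(activation_sequence(numeric(0), record_id = "rec", source = "annotated_truth"))
    activation_sequence(df$lat_ms, record_id = df$record_id[1L], source = df$source[1L])
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    activation_sequence(as.numeric(j$lats_ms), record_id = j$record_id, source = j$source)
  }
}
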