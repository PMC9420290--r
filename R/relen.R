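# Relative-energy (Rel-En) raw detector. The electrogram is enhanced by the
# ratio of its short-term to Hamming-weighted long-term energy and activations
# are picked as thresholded local maxima under a 70 ms refractory.

#' Parameters of the relative-energy detector
#'
#' Defaults are the optima found by grid search on pulmonary-vein AF
#' electrograms: short half-window 100 ms, long half-window 400 ms, exponent
#' 4, percentile 11, refractory 70 ms.
#'
#' @param s_win half-length of the short sliding window, ms.
#' @param l_win half-length of the long sliding window, ms; must exceed
#'   \code{s_win}.
#' @param p_exp energy exponent (>= 1).
#' @param percentile P of the detection threshold TH_P (0 < P < 100).
#' @param refractory minimal interval between detections, ms.
#' @param threshold_side \code{"upper"} (default): TH_P is the value exceeded
#'   by P percent of the rectified enhanced samples, i.e. the
#'   \code{1 - P/100} quantile, so the suprathreshold fraction matches the
#'   fraction of time occupied by activations. \code{"lower"}: the literal
#'   P/100 quantile.
#' @param polarity rectification used for thresholding and peak picking:
#'   \code{"abs"} (default; bipolar electrogram polarity is arbitrary),
#'   \code{"pos"} or \code{"neg"}.
#' @param eps_scale relative floor of the energy-ratio denominator, applied
#'   as \code{eps_scale * max(|x|)^p_exp}.
#' @param eps_floor absolute denominator floor.
#' @return object of class \code{relen_params}.
#' @export
relen_params <- function(s_win = 100, l_win = 400, p_exp = 4, percentile = 11,
                         refractory = 70, threshold_side = c("upper", "lower"),
                         polarity = c("abs", "pos", "neg"),
                         eps_scale = 1e-12, eps_floor = 1e-300) {
  threshold_side <- match.arg(threshold_side)
  polarity <- match.arg(polarity)
  stopifnot(s_win > 0, l_win > s_win, p_exp >= 1,
            percentile > 0, percentile < 100, refractory >= 0,
            eps_scale > 0, eps_floor > 0)
  structure(list(s_win = s_win, l_win = l_win, p_exp = p_exp,
                 percentile = percentile, refractory = refractory,
                 threshold_side = threshold_side, polarity = polarity,
                 eps_scale = eps_scale, eps_floor = eps_floor),
            class = "relen_params")
}

# centered FFT convolution with zero padding; equivalent to truncating the
# window sums to valid sample indices
conv_same <- function(x, k) {
  h <- (length(k) - 1L) %/% 2L
  full <- stats::convolve(x, rev(k), type = "open")
  full[(h + 1L):(h + length(x))]
}

#' Relative-energy enhancement coefficient
#'
#' For every sample n the coefficient is the short-window energy sum of
#' \code{|x|^p} divided by the long-window sum of the Hamming-weighted
#' \code{|Hamming * x|^p}; window sums are truncated at the record edges and
#' the denominator is floored to keep silent segments finite.
#'
#' @param rec an \code{iegm_record} longer than \code{2 * l_win}.
#' @param params a \code{relen_params} object.
#' @return numeric vector of non-negative coefficients, one per sample.
#' @export
compute_coefficient <- function(rec, params = relen_params()) {
  x <- rec$samples
  p <- params$p_exp
  ns <- ms_to_samples(params$s_win, rec$fs)
  nl <- ms_to_samples(params$l_win, rec$fs)
  if (length(x) < 2L * nl + 1L)
    stop("record shorter than the long analysis window (need more than 2*l_win)")
  a <- abs(x)^p
  num <- conv_same(a, rep(1, 2L * ns + 1L))
  wl <- as.numeric(signal::hamming(2L * nl + 1L))^p
  den <- conv_same(a, wl)
  eps <- max(params$eps_floor, params$eps_scale * max(abs(x))^p)
  pmax(num, 0) / pmax(den, eps)
}

rectify <- function(v, polarity) {
  switch(polarity, abs = abs(v), pos = pmax(v, 0), neg = pmax(-v, 0))
}

#' Enhance a record by its relative-energy coefficient
#'
#' Computes \code{x_RE(n) = x(n) * c(n)} and the detection threshold TH_P as
#' the P-th percentile (linear interpolation between order statistics) of the
#' rectified enhanced amplitude distribution.
#'
#' @param rec an \code{iegm_record}.
#' @param coef coefficient vector from \code{\link{compute_coefficient}};
#'   must match the record length.
#' @param params a \code{relen_params} object.
#' @return object of class \code{enhanced_signal} with fields \code{values},
#'   \code{mag} (rectified values), \code{th_p}, \code{fs}, \code{t0},
#'   \code{record_id}.
#' @export
enhance <- function(rec, coef, params = relen_params()) {
  if (length(coef) != length(rec$samples)) stop("coefficient/record length mismatch")
  values <- rec$samples * coef
  mag <- rectify(values, params$polarity)
  q <- if (params$threshold_side == "upper") 1 - params$percentile / 100 else
    params$percentile / 100
  th_p <- as.numeric(stats::quantile(mag, q, type = 7, names = FALSE))
  structure(list(values = values, mag = mag, th_p = th_p,
                 fs = rec$fs, t0 = rec$t0, record_id = rec$record_id),
            class = "enhanced_signal")
}

#' @export
print.enhanced_signal <- function(x, ...) {
  cat(sprintf("<enhanced_signal '%s'> %d samples @ %g Hz, TH_P = %.4g\n",
              x$record_id, length(x$values), x$fs, x$th_p))
  invisible(x)
}

#' Pick activation peaks from an enhanced signal
#'
#' Candidates are local maxima of the rectified enhanced signal strictly
#' above TH_P. Candidates closer than the refractory interval are resolved in
#' favour of the larger amplitude (ties keep the earlier one).
#'
#' @param es an \code{enhanced_signal}.
#' @param refractory minimal interval between detections, ms.
#' @return \code{activation_sequence} with source \code{"raw_relen"} (an
#'   empty sequence is a valid result).
#' @export
detect_peaks <- function(es, refractory = 70) {
  m <- es$mag
  n <- length(m)
  acc <- integer(0)
  if (n >= 3L) {
    cand <- which(m[2:(n - 1L)] > m[1:(n - 2L)] & m[2:(n - 1L)] >= m[3:n]) + 1L
    cand <- cand[m[cand] > es$th_p]
    if (length(cand)) {
      ord <- cand[order(-m[cand], cand)]
      rs <- refractory * es$fs / 1000
      for (i in ord)
        if (!length(acc) || all(abs(acc - i) >= rs - 1e-9)) acc <- c(acc, i)
      acc <- sort(acc)
    }
  }
  activation_sequence(es$t0 + (acc - 1) * 1000 / es$fs,
                      record_id = es$record_id, source = "raw_relen",
                      refractory = refractory)
}

#' Run the full relative-energy detector
#'
#' Composition of \code{\link{compute_coefficient}}, \code{\link{enhance}}
#' and \code{\link{detect_peaks}}. The enhanced signal is returned for reuse
#' by the sensing-correction stage, whose removal and recovery criteria
#' compare against the same threshold TH_P.
#'
#' @param rec an \code{iegm_record}.
#' @param params a \code{relen_params} object.
#' @return list with elements \code{seq} (\code{activation_sequence}, source
#'   \code{"raw_relen"}) and \code{enhanced} (\code{enhanced_signal}).
#' @export
relen_detect <- function(rec, params = relen_params()) {
  coef <- compute_coefficient(rec, params)
  es <- enhance(rec, coef, params)
  list(seq = detect_peaks(es, params$refractory), enhanced = es)
}
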