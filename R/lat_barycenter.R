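# Barycenter annotation correction. Each activation's timestamp is replaced
# by the energy barycenter of its envelope-gated segment, which is far less
# sensitive than peak annotation to which sub-deflection of a fractionated
# complex happens to be largest.

#' Parameters of the barycenter annotation correction
#'
#' @param half_window half-length of the segment extracted around each LAT,
#'   ms (>= 10); segments are additionally clipped at the midpoints to the
#'   neighbouring activations so complexes never bleed into each other.
#' @param envelope_method \code{"analytic_magnitude"} (magnitude of the
#'   analytic signal, default) or \code{"sliding_max"} (running maximum of
#'   the absolute signal).
#' @param cutoff_frac fraction of the segment envelope maximum below which
#'   the activation tails are rejected (0 < cutoff_frac < 1).
#' @param sliding_win window of the sliding-max envelope, ms.
#' @return object of class \code{barycenter_params}.
#' @export
barycenter_params <- function(half_window = 70,
                              envelope_method = c("analytic_magnitude", "sliding_max"),
                              cutoff_frac = 0.05, sliding_win = 5) {
  envelope_method <- match.arg(envelope_method)
  stopifnot(half_window >= 10, cutoff_frac > 0, cutoff_frac < 1, sliding_win > 0)
  structure(list(half_window = half_window, envelope_method = envelope_method,
                 cutoff_frac = cutoff_frac, sliding_win = sliding_win),
            class = "barycenter_params")
}

#' Envelope of a signal segment
#'
#' Default method is the magnitude of the analytic signal (FFT half-spectrum
#' doubling on the zero-padded segment); the alternative is a running
#' maximum of the absolute signal over a short window.
#'
#' @param seg numeric segment (non-empty).
#' @param method \code{"analytic_magnitude"} or \code{"sliding_max"}.
#' @param fs sampling rate, Hz (used by the sliding-max window).
#' @param sliding_win sliding-max window, ms.
#' @return nonnegative envelope, same length as \code{seg}.
#' @export
envelope <- function(seg, method = c("analytic_magnitude", "sliding_max"),
                     fs = 1000, sliding_win = 5) {
  method <- match.arg(method)
  n <- length(seg)
  if (n == 0L) stop("empty segment")
  if (method == "analytic_magnitude") {
    if (all(seg == 0)) return(numeric(n))
    nfft <- 2L^as.integer(ceiling(log2(max(n, 2L))))
    X <- stats::fft(c(seg, rep(0, nfft - n)))
    h <- rep(0, nfft)
    h[1L] <- 1
    if (nfft %% 2L == 0L) { h[nfft / 2L + 1L] <- 1; h[2L:(nfft / 2L)] <- 2 }
    else h[2L:((nfft + 1L) / 2L)] <- 2
    Mod(stats::fft(X * h, inverse = TRUE) / nfft)[seq_len(n)]
  } else {
    hw <- max(1L, ms_to_samples(sliding_win / 2, fs))
    a <- abs(seg)
    vapply(seq_len(n), function(i) max(a[max(1L, i - hw):min(n, i + hw)]), 0)
  }
}

#' Retain the envelope lobe containing the maximum
#'
#' Returns the maximal contiguous index range containing the envelope
#' maximum on which the envelope stays at or above
#' \code{cutoff_frac * max(env)}; low-amplitude activation tails and
#' secondary lobes below the cutoff are rejected.
#'
#' @param seg signal segment (unused by the rule; kept for interface
#'   symmetry).
#' @param env envelope aligned with \code{seg}.
#' @param cutoff_frac cutoff fraction of the envelope maximum.
#' @return integer vector \code{c(start, end)} of the retained range.
#' @export
trim_tails <- function(seg, env, cutoff_frac) {
  imax <- which.max(env)
  thr <- cutoff_frac * env[imax]
  lo <- imax
  while (lo > 1L && env[lo - 1L] >= thr) lo <- lo - 1L
  hi <- imax
  while (hi < length(env) && env[hi + 1L] >= thr) hi <- hi + 1L
  c(lo, hi)
}

#' Power barycenter of a retained segment
#'
#' The corrected LAT is the first moment of the squared signal over the
#' retained range: \code{sum(t * x^2) / sum(x^2)}. Squaring emphasises the
#' high-amplitude portion of the complex.
#'
#' @param seg signal segment.
#' @param range integer \code{c(start, end)} from \code{\link{trim_tails}}.
#' @param t_axis times (ms) of the segment samples.
#' @return barycenter time in ms, or \code{NA} if the retained range has
#'   zero energy.
#' @export
barycenter_lat <- function(seg, range, t_axis) {
  idx <- range[1L]:range[2L]
  w <- seg[idx]^2
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) return(NA_real_)
  sum(t_axis[idx] * w) / sw
}

#' Beat-by-beat barycenter correction of activation annotations
#'
#' Each LAT is re-annotated independently: a segment of up to
#' \code{half_window} ms on each side (clipped at gap midpoints) is
#' extracted, its envelope computed, low-amplitude tails rejected, and the
#' timestamp replaced by the power barycenter of the retained samples.
#' Corrections that would break monotonicity or the 70 ms refractory revert
#' to the original times. The variance of the activation-interval sequence
#' before and after summarises the change.
#'
#' @param rec the \code{iegm_record}.
#' @param seq \code{activation_sequence} to re-annotate.
#' @param bp a \code{barycenter_params} object.
#' @return list with \code{seq} (\code{activation_sequence}, source
#'   \code{"barycenter"}) and \code{report} (a \code{variance_report}).
#' @export
correct_annotations <- function(rec, seq, bp = barycenter_params()) {
  lats <- seq$lats
  n <- length(lats)
  out <- lats
  if (n >= 1L) {
    t_end <- rec$t0 + duration_ms(rec)
    for (i in seq_len(n)) {
      a <- max(rec$t0, lats[i] - bp$half_window,
               if (i > 1L) (lats[i - 1L] + lats[i]) / 2 else -Inf)
      b <- min(t_end, lats[i] + bp$half_window,
               if (i < n) (lats[i] + lats[i + 1L]) / 2 else Inf)
      i1 <- time_sample(rec, a); i2 <- time_sample(rec, b)
      i1 <- max(1L, i1); i2 <- min(length(rec$samples), i2)
      if (i2 - i1 < 2L) next
      segx <- rec$samples[i1:i2]
      env <- envelope(segx, bp$envelope_method, rec$fs, bp$sliding_win)
      if (all(env == 0)) next
      rng <- trim_tails(segx, env, bp$cutoff_frac)
      tb <- barycenter_lat(segx, rng, sample_time(rec, i1:i2))
      if (is.finite(tb)) out[i] <- tb
    }
    # beat-by-beat independence cannot create crossings (segments are clipped
    # at gap midpoints) but can compress an interval below the refractory:
    # revert both members of any offending pair to their original times.
    # The guarantee cannot exceed what the input sequence itself satisfies.
    ref_eff <- min(70, if (n > 1L) min(diff(lats)) else Inf)
    for (iter in 1:5) {
      bad <- which(diff(out) < ref_eff - 1e-9)
      if (!length(bad)) break
      out[unique(c(bad, bad + 1L))] <- lats[unique(c(bad, bad + 1L))]
    }
  }
  cseq <- activation_sequence(out, record_id = seq$record_id,
                              source = "barycenter",
                              refractory = if (n > 1L) min(ref_eff, 70) else 70)
  list(seq = cseq, report = variance_change(seq, cseq))
}
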