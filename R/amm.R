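# Adaptive mathematical-morphology (AMM) raw detector. Grayscale opening and
# closing with a five-fiducial structuring element extract an activation
# feature signal per 200-ms window; the element is re-fitted to each detected
# activation with an exponential learning rule.

#' Five-fiducial structuring element
#'
#' The structuring element (SE) is defined by five fiducial points — onset,
#' the minimum between onset and peak, the peak, the minimum between peak and
#' offset, and the offset — and realised as an amplitude profile sampled at
#' the record rate by linear interpolation through the fiducials.
#'
#' @param fiducial_offsets five offsets in ms relative to the onset (first
#'   element 0, strictly increasing).
#' @param fiducial_amplitudes five amplitudes in mV.
#' @param fs sampling rate in Hz used to sample the profile.
#' @return object of class \code{structuring_element} with the fiducials and
#'   the interpolated \code{profile}.
#' @export
structuring_element <- function(fiducial_offsets, fiducial_amplitudes, fs) {
  stopifnot(length(fiducial_offsets) == 5L, length(fiducial_amplitudes) == 5L)
  if (abs(fiducial_offsets[1L]) > 1e-12) stop("onset offset must be 0")
  if (any(diff(fiducial_offsets) <= 0)) stop("fiducial offsets must be strictly increasing")
  if (!all(is.finite(fiducial_amplitudes))) stop("fiducial amplitudes must be finite")
  n <- ms_to_samples(fiducial_offsets[5L], fs) + 1L
  if (n < 3L) stop("structuring element too short for the sampling rate")
  t <- (seq_len(n) - 1L) * 1000 / fs
  profile <- approx(fiducial_offsets, fiducial_amplitudes, xout = pmin(t, fiducial_offsets[5L]),
                    rule = 2)$y
  structure(list(fiducial_offsets = as.numeric(fiducial_offsets),
                 fiducial_amplitudes = as.numeric(fiducial_amplitudes),
                 fs = fs, profile = profile),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %.1f ms (%d samples), peak %.3g mV\n",
              x$fiducial_offsets[5L], length(x$profile), x$fiducial_amplitudes[3L]))
  invisible(x)
}

#' Parameters of the adaptive-morphology detector
#'
#' Defaults follow the tuned configuration: 20 ms structuring element, 200 ms
#' non-overlapping analysis windows, learning coefficient 0.5, 70 ms
#' refractory, 500 ms initialisation span.
#'
#' @param se_duration duration of the synthesized SE, ms.
#' @param window analysis window length, ms.
#' @param alpha learning coefficient in (0, 1] blending the current SE with
#'   each newly extracted activation.
#' @param refractory minimal interval between detections, ms.
#' @param zero_tol relative tolerance defining "non-zero" feature-signal
#'   segments, as a fraction of the running maximum of |x_MM|.
#' @param init_span span of signal used to size the synthesized SE, ms.
#' @return object of class \code{amm_params}.
#' @export
amm_params <- function(se_duration = 20, window = 200, alpha = 0.5,
                       refractory = 70, zero_tol = 0.1, init_span = 500) {
  stopifnot(alpha > 0, alpha <= 1, se_duration > 0, se_duration < window,
            refractory >= 0, zero_tol > 0, init_span > 0)
  structure(list(se_duration = se_duration, window = window, alpha = alpha,
                 refractory = refractory, zero_tol = zero_tol,
                 init_span = init_span),
            class = "amm_params")
}

#' Synthesize the initial structuring element from a record
#'
#' The synthesized template is biphasic-with-troughs: zero amplitude at onset
#' and offset, a dominant positive peak at the midpoint equal to the
#' amplitude span (max minus min) of the first \code{init_span} ms of the
#' record, and two troughs at \code{-0.25 * span} at the quartile points.
#'
#' @param rec an \code{iegm_record} at least \code{init_span} ms long.
#' @param params an \code{amm_params} object.
#' @return a \code{structuring_element}.
#' @export
init_structuring_element <- function(rec, params = amm_params()) {
  if (duration_ms(rec) < params$init_span)
    stop(sprintf("record shorter than the %g ms initialisation span", params$init_span))
  n0 <- min(length(rec$samples), ms_to_samples(params$init_span, rec$fs) + 1L)
  seg <- rec$samples[seq_len(n0)]
  span <- max(seg) - min(seg)
  if (span <= 0) stop("flat initialization segment")
  d <- params$se_duration
  structuring_element(c(0, d / 4, d / 2, 3 * d / 4, d),
                      c(0, -0.25 * span, span, -0.25 * span, 0),
                      rec$fs)
}

# non-flat grayscale erosion/dilation of a 1-D signal by kernel k with origin
# at the kernel centre; supports truncated at the signal edges
grey_erode <- function(x, k, origin = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  acc <- rep(Inf, n)
  for (m in seq_along(k)) {
    s <- m - origin
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) next
    idx <- lo:hi
    acc[idx] <- pmin(acc[idx], x[idx + s] - k[m])
  }
  acc
}

grey_dilate <- function(x, k, origin = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  acc <- rep(-Inf, n)
  for (m in seq_along(k)) {
    s <- m - origin
    lo <- max(1L, 1L + s); hi <- min(n, n + s)
    if (lo > hi) next
    idx <- lo:hi
    acc[idx] <- pmax(acc[idx], x[idx - s] + k[m])
  }
  acc
}

grey_open <- function(x, k) grey_dilate(grey_erode(x, k), k)
grey_close <- function(x, k) grey_erode(grey_dilate(x, k), k)

#' Morphological feature signal of a window
#'
#' Computes \code{x_MM = x - (opening(x, SE) + closing(x, SE)) / 2}, the
#' average of the top-hat and bottom-hat residues with non-flat grayscale
#' operators; the SE origin is its centre sample so the output stays aligned
#' with the input.
#'
#' @param x_win numeric vector, at least as long as the SE profile.
#' @param se a \code{structuring_element}.
#' @return numeric feature signal of the same length as \code{x_win}.
#' @export
mm_filter <- function(x_win, se) {
  k <- se$profile
  if (length(x_win) < length(k)) stop("structuring element longer than the window")
  x_win - (grey_open(x_win, k) + grey_close(x_win, k)) / 2
}

# opening/closing at position n depend on x over n +/- (K-1); samples closer
# than that to the window edges carry truncated-support artifacts and are
# blanked before segment extraction
mm_feature_valid <- function(x_mm, k_len) {
  b <- k_len - 1L
  n <- length(x_mm)
  if (2L * b >= n) return(numeric(n))
  if (b > 0L) {
    x_mm[seq_len(b)] <- 0
    x_mm[(n - b + 1L):n] <- 0
  }
  x_mm
}

# fiducials of one activation from raw samples x over segment [a, b]
# (window-local indices), peak index ipk; offsets in ms relative to onset
extract_fiducials <- function(x, a, b, ipk, fs) {
  i_min1 <- a - 1L + which.min(x[a:ipk])
  i_min2 <- ipk - 1L + which.min(x[ipk:b])
  idx <- c(a, i_min1, ipk, i_min2, b)
  list(offsets = (idx - a) * 1000 / fs, amplitudes = x[idx])
}

#' Extract activations from a feature signal
#'
#' Non-zero segments are maximal runs where \code{|x_MM|} exceeds
#' \code{zero_tol} times the running maximum of \code{|x_MM|} observed so
#' far. Each segment contributes one activation at its most significant
#' feature peak, with onset/offset at the segment limits and the two local
#' minima of the raw signal around the peak; detections closer than the
#' refractory to the previously accepted activation are suppressed.
#'
#' @param x_mm feature signal of one window.
#' @param x_raw the raw samples the window was cut from (same indexing).
#' @param window_t0 time of the first sample of the window, ms.
#' @param params an \code{amm_params} object.
#' @param fs sampling rate, Hz.
#' @param run_max running maximum of \code{|x_MM|} including this window.
#' @param last_lat time of the last accepted activation (\code{-Inf} if none).
#' @param max_end segments whose end exceeds this (window-local) index are
#'   skipped: they straddle the analysis-window boundary and are handled,
#'   fully visible, by the next window.
#' @return list of activations, each with \code{lat}, \code{ipk} and
#'   \code{fiducials} (offsets + amplitudes).
#' @export
extract_activation <- function(x_mm, x_raw, window_t0, params, fs,
                               run_max = max(abs(x_mm)), last_lat = -Inf,
                               max_end = Inf) {
  th <- params$zero_tol * run_max
  above <- abs(x_mm) > th
  out <- list()
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    if (b > max_end) next
    ipk <- a - 1L + which.max(abs(x_mm[a:b]))
    lat <- window_t0 + (ipk - 1L) * 1000 / fs
    if (lat - last_lat < params$refractory - 1e-9) next
    fid <- extract_fiducials(x_raw, a, b, ipk, fs)
    out[[length(out) + 1L]] <- list(lat = lat, ipk = ipk, fiducials = fid)
    last_lat <- lat
  }
  out
}

#' Blend the structuring element with an extracted activation
#'
#' Each non-onset fiducial location (distance from onset) and every fiducial
#' amplitude is updated to
#' \code{(1 - alpha) * current + alpha * extracted}; the profile is
#' re-interpolated. If the blended locations are not strictly increasing the
#' update is skipped and the current SE kept.
#'
#' @param se current \code{structuring_element}.
#' @param extracted fiducial set (\code{offsets}, \code{amplitudes}) from
#'   \code{\link{extract_activation}}.
#' @param alpha learning coefficient.
#' @return updated (or unchanged) \code{structuring_element}; attribute
#'   \code{"skipped"} is \code{TRUE} when the update was rejected.
#' @export
update_se <- function(se, extracted, alpha) {
  new_loc <- (1 - alpha) * se$fiducial_offsets[2:5] + alpha * extracted$offsets[2:5]
  new_amp <- (1 - alpha) * se$fiducial_amplitudes + alpha * extracted$amplitudes
  offs <- c(0, new_loc)
  if (any(diff(offs) <= 0) || !all(is.finite(new_amp)) ||
      ms_to_samples(offs[5L], se$fs) + 1L < 3L) {
    attr(se, "skipped") <- TRUE
    return(se)
  }
  structuring_element(offs, new_amp, se$fs)
}

#' Run the full adaptive-morphology detector
#'
#' The record is processed in non-overlapping \code{window}-ms windows, each
#' extended by a look-back margin so activations straddling a boundary are
#' seen whole. The first window is filtered with the synthesized SE; each
#' accepted activation updates the SE used for subsequent windows. The
#' concatenated detections satisfy the refractory globally.
#'
#' @param rec an \code{iegm_record} at least \code{init_span} ms long.
#' @param params an \code{amm_params} object.
#' @return \code{activation_sequence} with source \code{"raw_amm"};
#'   attributes \code{"se"} (final SE), \code{"run_max"} and \code{"th"}
#'   (final segment threshold) support the sensing-correction stage.
#' @export
amm_detect <- function(rec, params = amm_params()) {
  se <- init_structuring_element(rec, params)
  x <- rec$samples
  fs <- rec$fs
  n <- length(x)
  wlen <- ms_to_samples(params$window, fs)
  margin <- ms_to_samples(max(params$se_duration, params$refractory), fs)
  run_max <- 0
  lats <- numeric(0)
  last_lat <- -Inf
  for (s0 in seq(1L, n, by = wlen)) {
    klen <- length(se$profile)
    i1 <- max(1L, s0 - margin)
    i2 <- min(n, s0 + wlen - 1L + klen)
    if (i2 - i1 + 1L < klen) next
    xw <- x[i1:i2]
    xmm <- mm_feature_valid(mm_filter(xw, se), klen)
    run_max <- max(run_max, max(abs(xmm)))
    cut <- if (s0 + wlen > n) Inf else s0 + wlen - i1
    acts <- extract_activation(xmm, xw, sample_time(rec, i1), params, fs,
                               run_max = run_max, last_lat = last_lat,
                               max_end = cut)
    for (ac in acts) {
      lats <- c(lats, ac$lat)
      last_lat <- ac$lat
      se <- update_se(se, ac$fiducials, params$alpha)
    }
  }
  seq <- activation_sequence(lats, record_id = rec$record_id, source = "raw_amm",
                             refractory = params$refractory)
  attr(seq, "se") <- se
  attr(seq, "run_max") <- run_max
  attr(seq, "th") <- params$zero_tol * run_max
  seq
}
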