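# Reduction of over- and undersensing. Weight functions built from the raw
# activation-interval statistics dampen implausibly early detections (false
# positives are removed first) and amplify the signal mid-gap where an
# activation was probably missed (recovered second).

#' Parameters of the sensing-correction weight functions
#'
#' @param shape \code{"linear"} (ramp) or \code{"nonlinear"} (truncated
#'   Gaussian).
#' @param p70 weight value at k = 70 ms (linear shape).
#' @param p_mean weight value at k = meanAA ms.
#' @param enlarge Gaussian enlargement factor E (nonlinear shape).
#' @param gaussian_mode \code{"widened_std"} (default): Gaussian with
#'   standard deviation \code{enlarge * sigma_AA} and peak \code{p_mean},
#'   continuous at k = meanAA. \code{"literal"}: amplitude
#'   \code{enlarge * p_mean / sigma_AA} with standard deviation
#'   \code{sigma_AA}, the formula as printed.
#' @return object of class \code{weight_params}.
#' @export
weight_params <- function(shape = c("nonlinear", "linear"), p70 = 0, p_mean = 3,
                          enlarge = 1.25,
                          gaussian_mode = c("widened_std", "literal")) {
  shape <- match.arg(shape)
  gaussian_mode <- match.arg(gaussian_mode)
  stopifnot(p70 >= 0, p_mean > 0, enlarge >= 1)
  structure(list(shape = shape, p70 = p70, p_mean = p_mean, enlarge = enlarge,
                 gaussian_mode = gaussian_mode),
            class = "weight_params")
}

#' Tuned weight defaults per detector
#'
#' The per-detector optima: nonlinear weights (E = 1.25, P_meanAA = 3) for
#' the relative-energy detector, linear weights (P_70 = 0.4,
#' P_meanAA = 2.2) for the adaptive-morphology detector.
#'
#' @param detector \code{"relen"} or \code{"amm"}.
#' @return a \code{weight_params} object.
#' @export
default_weights <- function(detector = c("relen", "amm")) {
  detector <- match.arg(detector)
  if (detector == "relen") weight_params("nonlinear", p70 = 0, p_mean = 3, enlarge = 1.25)
  else weight_params("linear", p70 = 0.4, p_mean = 2.2)
}

#' Evaluate a weight function
#'
#' Both shapes are zero below the 70 ms physiological refractory. The linear
#' shape ramps from \code{p70} at k = 70 ms to \code{p_mean} at k = meanAA ms
#' and continues with the same slope beyond. The nonlinear shape is a
#' truncated Gaussian centred at meanAA, flat at \code{p_mean} beyond the
#' mean.
#'
#' @param k interval position(s) in ms (vectorised).
#' @param wp a \code{weight_params} object.
#' @param stats an \code{interval_stats} object (meanAA, sigmaAA).
#' @return numeric vector of weights.
#' @export
weight_at <- function(k, wp, stats) {
  k <- as.numeric(k)
  m <- stats$mean_aa
  s <- stats$sigma_aa
  w <- numeric(length(k))
  if (wp$shape == "linear") {
    slope <- if (m > 70) (wp$p_mean - wp$p70) / (m - 70) else 0
    on <- k >= 70
    w[on] <- wp$p70 + slope * (k[on] - 70)
  } else {
    if (wp$gaussian_mode == "widened_std") {
      se <- max(wp$enlarge * s, .Machine$double.eps)
      mid <- k >= 70 & k <= m
      w[mid] <- wp$p_mean * exp(-(k[mid] - m)^2 / (2 * se^2))
    } else {
      se <- max(s, .Machine$double.eps)
      mid <- k >= 70 & k <= m
      w[mid] <- wp$enlarge * wp$p_mean / se * exp(-(k[mid] - m)^2 / (2 * se^2))
    }
    w[k > m] <- wp$p_mean
  }
  w
}

#' Interval statistics robust to undersensing
#'
#' Weight functions need the spread of the physiological activation
#' intervals, but a raw sequence with missed beats contains double-length
#' intervals that inflate the plain standard deviation — the very defect the
#' correction stage is meant to repair. Intervals longer than
#' \code{outlier_factor} times the median interval are therefore excluded
#' before computing the statistics used by the weights.
#'
#' @param seq an \code{activation_sequence} (>= 2 activations).
#' @param outlier_factor multiple of the median interval above which an
#'   interval is treated as containing a missed activation.
#' @return an \code{interval_stats} object.
#' @export
correction_stats <- function(seq, outlier_factor = 1.75) {
  lats <- if (inherits(seq, "activation_sequence")) seq$lats else as.numeric(seq)
  if (length(lats) < 2L) stop("insufficient activations for statistics")
  d <- diff(lats)
  keep <- d <= outlier_factor * stats::median(d)
  if (sum(keep) >= 2L) d <- d[keep]
  structure(list(mean_aa = mean(d),
                 sigma_aa = sqrt(mean((d - mean(d))^2)),
                 n_intervals = length(d)),
            class = "interval_stats")
}

# context describing how the correction stage talks to a detector
correction_ctx <- function(seq, detector, es = NULL, rec = NULL, params = NULL) {
  detector <- match.arg(detector, c("relen", "amm"))
  if (detector == "relen") {
    if (is.null(es) || !inherits(es, "enhanced_signal"))
      stop("relen-mode correction requires the enhanced_signal of the record")
    list(kind = "relen", es = es, th = es$th_p, fs = es$fs, t0 = es$t0,
         mag = es$mag, n = length(es$mag))
  } else {
    if (is.null(rec)) stop("amm-mode correction requires the iegm_record")
    se <- attr(seq, "se")
    th <- attr(seq, "th")
    if (is.null(params)) params <- amm_params()
    if (is.null(se)) se <- init_structuring_element(rec, params)
    if (is.null(th)) th <- params$zero_tol * max(abs(mm_filter(rec$samples, se)))
    list(kind = "amm", rec = rec, se = se, th = th, params = params,
         fs = rec$fs, t0 = rec$t0, mag = abs(rec$samples), n = length(rec$samples))
  }
}

ctx_index <- function(ctx, t_ms) {
  i <- ms_to_samples(t_ms - ctx$t0, ctx$fs) + 1L
  pmin(pmax(i, 1L), ctx$n)
}

# does an activation near t_target survive re-detection on the weighted raw
# signal? (amm mode). The segment spanning the weighting support is filtered
# with the final SE and searched for a suprathreshold feature peak.
amm_present <- function(ctx, x_weighted, i1, t_target, tol_ms) {
  if (length(x_weighted) < length(ctx$se$profile)) return(TRUE)
  xmm <- mm_feature_valid(mm_filter(x_weighted, ctx$se), length(ctx$se$profile))
  above <- which(abs(xmm) > ctx$th)
  if (!length(above)) return(FALSE)
  t_above <- ctx$t0 + (i1 - 1L + above - 1L) * 1000 / ctx$fs
  any(abs(t_above - t_target) <= tol_ms)
}

#' Remove false detections using interval-statistics weights
#'
#' For every activation LAT_0 the weight function is evaluated on the
#' preceding and succeeding intervals; each neighbour's amplitude is
#' multiplied by the weight at its interval length. In relen mode a neighbour
#' whose weighted enhanced amplitude falls below TH_P is removed; in amm mode
#' the weighted raw signal is re-run through the morphology detector and a
#' neighbour absent from the re-run is removed. An activation flagged from
#' either side is removed; the sequence is processed left to right on the
#' surviving detections.
#'
#' @param seq raw \code{activation_sequence} (>= 3 activations).
#' @param wp a \code{weight_params} object.
#' @param stats frozen \code{interval_stats} of the raw sequence.
#' @param detector \code{"relen"} or \code{"amm"}.
#' @param es \code{enhanced_signal} (relen mode).
#' @param rec \code{iegm_record} (amm mode).
#' @param params \code{amm_params} (amm mode).
#' @return list with \code{seq} (sequence after removals, source
#'   \code{"corrected"}) and \code{removed} (times of removed activations).
#' @export
remove_false <- function(seq, wp, stats, detector = c("relen", "amm"),
                         es = NULL, rec = NULL, params = NULL) {
  detector <- match.arg(detector)
  ctx <- correction_ctx(seq, detector, es, rec, params)
  lats <- seq$lats
  n <- length(lats)
  alive <- rep(TRUE, n)
  amp <- ctx$mag[ctx_index(ctx, lats)]
  flag_neighbor <- function(i0, j) {
    k <- abs(lats[j] - lats[i0])
    w <- weight_at(k, wp, stats)
    if (ctx$kind == "relen") return(amp[j] * w < ctx$th)
    # amm: weight the raw signal over the interval and re-detect around j
    t_lo <- min(lats[i0], lats[j]) - 1000 / ctx$fs
    t_hi <- max(lats[i0], lats[j]) + stats$mean_aa / 2
    i1 <- ctx_index(ctx, t_lo); i2 <- ctx_index(ctx, t_hi)
    idx <- i1:i2
    tt <- ctx$t0 + (idx - 1L) * 1000 / ctx$fs
    wv <- weight_at(abs(tt - lats[i0]), wp, stats)
    !amm_present(ctx, ctx$rec$samples[idx] * wv, i1, lats[j], 35)
  }
  for (i0 in seq_len(n)) {
    if (!alive[i0]) next
    prevs <- which(alive[seq_len(i0 - 1L)])
    if (length(prevs)) {
      p <- prevs[length(prevs)]
      if (flag_neighbor(i0, p)) alive[p] <- FALSE
    }
    nxts <- if (i0 < n) i0 + which(alive[(i0 + 1L):n]) else integer(0)
    if (length(nxts)) {
      q <- nxts[1L]
      if (flag_neighbor(i0, q)) alive[q] <- FALSE
    }
  }
  list(seq = activation_sequence(lats[alive], record_id = seq$record_id,
                                 source = "corrected"),
       removed = lats[!alive])
}

#' Recover missed activations using combined gap weights
#'
#' For every gap of length K between consecutive activations the signal is
#' multiplied by \code{W(k) = w(k) * w(K - k)}, the weight times its
#' time-reversed copy, which amplifies the centre of gaps that are long
#' relative to the mean interval. In relen mode a new activation is inserted
#' at the argmax of the weighted enhanced amplitude when it exceeds TH_P; in
#' amm mode the weighted raw gap is re-run through the morphology detector.
#' Insertions keep 70 ms to both gap endpoints; at most one activation is
#' inserted per gap per pass.
#'
#' @inheritParams remove_false
#' @param forbidden times (ms) near which insertions are suppressed (used to
#'   avoid re-inserting an activation removed in the same pass).
#' @return list with \code{seq} (sequence after insertions, source
#'   \code{"corrected"}) and \code{inserted} (times of inserted activations).
#' @export
recover_missed <- function(seq, wp, stats, detector = c("relen", "amm"),
                           es = NULL, rec = NULL, params = NULL,
                           forbidden = numeric(0)) {
  detector <- match.arg(detector)
  ctx <- correction_ctx(seq, detector, es, rec, params)
  lats <- seq$lats
  refr <- 70
  inserted <- numeric(0)
  if (length(lats) >= 2L) {
    for (g in seq_len(length(lats) - 1L)) {
      K <- lats[g + 1L] - lats[g]
      if (K < 2 * refr) next
      i1 <- ctx_index(ctx, lats[g])
      i2 <- ctx_index(ctx, lats[g + 1L])
      idx <- i1:i2
      kk <- (idx - i1) * 1000 / ctx$fs
      W <- weight_at(kk, wp, stats) * weight_at(K - kk, wp, stats)
      ok <- kk >= refr & kk <= K - refr
      if (length(forbidden))
        ok <- ok & vapply(lats[g] + kk, function(t) all(abs(t - forbidden) > refr / 2), TRUE)
      if (!any(ok)) next
      if (ctx$kind == "relen") {
        xw <- W * ctx$mag[idx]
        xw[!ok] <- 0
        if (max(xw) > ctx$th)
          inserted <- c(inserted, lats[g] + kk[which.max(xw)])
      } else {
        xw <- W * ctx$rec$samples[idx]
        if (length(xw) < length(ctx$se$profile)) next
        xmm <- mm_feature_valid(mm_filter(xw, ctx$se), length(ctx$se$profile))
        cand <- abs(xmm)
        cand[!ok] <- 0
        if (max(cand) > ctx$th)
          inserted <- c(inserted, lats[g] + kk[which.max(cand)])
      }
    }
  }
  out <- sort(c(lats, inserted))
  list(seq = activation_sequence(out, record_id = seq$record_id, source = "corrected"),
       inserted = inserted)
}

#' Two-pass sensing correction of a raw detection sequence
#'
#' One pass removes false detections first, then screens the gaps for missed
#' activations, both using interval statistics frozen from the raw sequence.
#' Sequences with fewer than 3 activations are returned unchanged with a
#' warning.
#'
#' @inheritParams remove_false
#' @param max_passes number of remove/recover passes (default 1).
#' @return \code{activation_sequence} with source \code{"corrected"};
#'   attributes \code{"removed"} and \code{"inserted"} list the changes.
#' @export
correct_sequence <- function(seq, wp = NULL, detector = c("relen", "amm"),
                             es = NULL, rec = NULL, params = NULL,
                             max_passes = 1L) {
  detector <- match.arg(detector)
  if (is.null(wp)) wp <- default_weights(detector)
  if (length(seq$lats) < 3L) {
    warning("fewer than 3 raw detections: sequence returned uncorrected")
    out <- activation_sequence(seq$lats, record_id = seq$record_id, source = "corrected")
    attr(out, "removed") <- numeric(0)
    attr(out, "inserted") <- numeric(0)
    return(out)
  }
  stats <- correction_stats(seq)   # frozen from the raw detections
  cur <- seq
  removed_all <- numeric(0)
  inserted_all <- numeric(0)
  for (pass in seq_len(max_passes)) {
    rf <- remove_false(cur, wp, stats, detector, es, rec, params)
    rm_ <- recover_missed(rf$seq, wp, stats, detector, es, rec, params,
                          forbidden = rf$removed)
    removed_all <- c(removed_all, rf$removed)
    inserted_all <- c(inserted_all, rm_$inserted)
    if (!length(rf$removed) && !length(rm_$inserted)) { cur <- rm_$seq; break }
    cur <- rm_$seq
  }
  out <- activation_sequence(cur$lats, record_id = seq$record_id, source = "corrected")
  attr(out, "removed") <- removed_all
  attr(out, "inserted") <- inserted_all
  out
}
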