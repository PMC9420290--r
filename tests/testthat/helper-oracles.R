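# Independent brute-force oracles and small fixture builders shared by the
# test files. All fixtures are generated in code at test time.

# literal double-loop evaluation of the relative-energy coefficient
brute_coefficient <- function(x, fs, s_win, l_win, p, eps_scale = 1e-12) {
  ns <- ms_to_samples(s_win, fs)
  nl <- ms_to_samples(l_win, fs)
  ham <- as.numeric(signal::hamming(2 * nl + 1))
  n <- length(x)
  eps <- max(1e-300, eps_scale * max(abs(x))^p)
  vapply(seq_len(n), function(i) {
    si <- max(1, i - ns):min(n, i + ns)
    li <- max(1, i - nl):min(n, i + nl)
    num <- sum(abs(x[si])^p)
    den <- sum(abs(ham[li - i + nl + 1] * x[li])^p)
    num / max(den, eps)
  }, 0)
}

# literal sliding min/max grayscale morphology
brute_erode <- function(x, k, o = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    m <- seq_along(k)
    idx <- i + m - o
    v <- idx >= 1 & idx <= n
    min(x[idx[v]] - k[m[v]])
  }, 0)
}
brute_dilate <- function(x, k, o = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    m <- seq_along(k)
    idx <- i - m + o
    v <- idx >= 1 & idx <= n
    max(x[idx[v]] + k[m[v]])
  }, 0)
}
brute_mm <- function(x, k) {
  open <- brute_dilate(brute_erode(x, k), k)
  close <- brute_erode(brute_dilate(x, k), k)
  x - (open + close) / 2
}

# exhaustive maximum matching (max pairs, then min total |dt|) for small
# sequences; the reference for the greedy matcher
brute_match <- function(tt, td, tol) {
  best <- list(tp = -1L, cost = Inf)
  recurse <- function(i, used, tp, cost) {
    if (i > length(tt)) {
      if (tp > best$tp || (tp == best$tp && cost < best$cost))
        best <<- list(tp = tp, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, tp, cost)        # leave tt[i] unmatched
    for (j in seq_along(td)) {
      if (!used[j] && abs(tt[i] - td[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L, cost + abs(tt[i] - td[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(td)), 0L, 0)
  best
}

# classical peak annotation of known activations: each truth time replaced by
# the time of the largest |deflection| nearby (clipped to half the gaps)
peak_annotate <- function(rec, truth, hw = 35) {
  lats <- mapply(function(tl, lo, hi) {
    h <- min(hw, (tl - lo) / 2, (hi - tl) / 2)
    i <- ms_to_samples(tl - rec$t0, rec$fs) + 1L
    k <- max(1, round(h))
    i1 <- max(1, i - k)
    i2 <- min(length(rec$samples), i + k)
    rec$t0 + (i1 - 1 + which.max(abs(rec$samples[i1:i2])) - 1) * 1000 / rec$fs
  }, truth$lats, c(-Inf, utils::head(truth$lats, -1)), c(utils::tail(truth$lats, -1), Inf))
  activation_sequence(lats, rec$record_id, "annotated_truth")
}

# corpus configurations used by the study-condition tests
cfg_clean <- function(seed) {
  synth_config(duration = 10, mean_cl = 200, cl_sd = 40, min_cl = 90,
               morphology_mix = c(biphasic = 1, fractionated = 0, double_peak = 0),
               amp_cv = 0.05, noise_sd = 0, artifact_rate = 0, farfield_amp = 0,
               farfield_rate = 0, dropout_prob = 0, mod_depth = 0, seed = seed)
}
cfg_amm <- function(seed) {
  synth_config(duration = 10, mean_cl = 250, cl_sd = 40, min_cl = 120,
               morphology_mix = c(biphasic = 1, fractionated = 0, double_peak = 0),
               amp_cv = 0.05, noise_sd = 0, artifact_rate = 0, farfield_amp = 0,
               farfield_rate = 0, dropout_prob = 0, mod_depth = 0,
               carrier_freq = 180, seed = seed)
}
cfg_landscape <- function() {
  synth_config(noise_sd = 0.012, amp_cv = 0.25, dropout_prob = 0,
               pause_prob = 0.15, farfield_rate = 0.4)
}
cfg_lat <- function(class, seed) {
  mix <- if (class == "fractionated")
    c(biphasic = 0, fractionated = 1, double_peak = 0)
  else c(biphasic = 0, fractionated = 0, double_peak = 1)
  synth_config(duration = 10, mean_cl = 220, cl_sd = 30, min_cl = 90,
               morphology_mix = mix, amp_cv = 0.1, noise_sd = 0.01,
               artifact_rate = 0, farfield_amp = 0, farfield_rate = 0,
               dropout_prob = 0, mod_depth = 0,
               site_morphology = TRUE, subpeak_jitter = 0.5, seed = seed)
}
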