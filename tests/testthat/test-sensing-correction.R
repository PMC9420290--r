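mk_stats <- function(mean_aa, sigma_aa) {
  structure(list(mean_aa = mean_aa, sigma_aa = sigma_aa, n_intervals = 10L),
            class = "interval_stats")
}

# a hand-built enhanced signal: unit impulses at given times over silence
mk_es <- function(lats, amps, n = 3000, th = 0.5, fs = 1000) {
  v <- rep(0, n)
  v[round(lats) + 1L] <- amps
  structure(list(values = v, mag = abs(v), th_p = th, fs = fs, t0 = 0,
                 record_id = "syn"), class = "enhanced_signal")
}

test_that("weight functions match their closed forms", {
  st <- mk_stats(220, 40)
  lin <- weight_params("linear", p70 = 0.4, p_mean = 2.2)
  nl <- weight_params("nonlinear", p70 = 0, p_mean = 3, enlarge = 1.25)
  # dead below the 70 ms refractory, both shapes
  expect_equal(weight_at(c(0, 50, 69.9), lin, st), c(0, 0, 0))
  expect_equal(weight_at(c(0, 50, 69.9), nl, st), c(0, 0, 0))
  # linear ramp: value at 70, at the mean, and the printed slope beyond
  expect_equal(weight_at(70, lin, st), 0.4)
  expect_equal(weight_at(220, lin, st), 2.2)
  slope <- (2.2 - 0.4) / (220 - 70)
  expect_equal(weight_at(300, lin, st), 2.2 + slope * 80)
  # Gaussian: peak at the mean, e^-1/2 one (widened) sd below, flat beyond
  expect_equal(weight_at(220, nl, st), 3)
  expect_equal(weight_at(220 - 1.25 * 40, nl, st), 3 * exp(-0.5))
  expect_equal(weight_at(400, nl, st), 3)
  # literal mode reproduces the printed amplitude
  nll <- weight_params("nonlinear", p70 = 0, p_mean = 3, enlarge = 1.25,
                       gaussian_mode = "literal")
  expect_equal(weight_at(220, nll, st), 1.25 * 3 / 40)
  expect_equal(weight_at(180, nll, st), 1.25 * 3 / 40 * exp(-(40)^2 / (2 * 40^2)))
})

test_that("robust correction statistics exclude missed-beat double gaps", {
  lats <- c(0, 200, 400, 600, 1040, 1240, 1440)   # one 440 ms double gap
  plain <- interval_stats(lats)
  rob <- correction_stats(lats)
  expect_gt(plain$sigma_aa, 80)
  expect_lt(rob$sigma_aa, 10)
  expect_equal(rob$mean_aa, 200)
})

test_that("false detections at implausibly short intervals are removed", {
  st <- mk_stats(219, 40)
  wp <- default_weights("relen")
  # regular train plus an artifact 103 ms after a true beat (271 ms before,
  # 103 ms after the processed activation, mean interval 219 ms)
  lats <- c(100, 371, 474, 700, 920)
  amps <- c(2, 2, 0.8, 2, 2)        # the artifact is smaller but above TH
  es <- mk_es(lats, amps, th = 0.5)
  seq0 <- activation_sequence(lats, "syn", "raw_relen")
  out <- remove_false(seq0, wp, st, "relen", es = es)
  expect_true(474 %in% out$removed)
  expect_false(371 %in% out$removed)
  # all intervals at the mean, ample amplitude: nothing removed
  lats2 <- seq(100, 1300, by = 219)
  es2 <- mk_es(lats2, rep(3, length(lats2)), th = 0.5)
  seq2 <- activation_sequence(lats2, "syn", "raw_relen")
  expect_length(remove_false(seq2, wp, mk_stats(219, 40), "relen", es = es2)$removed, 0)
})

test_that("missed activations are recovered only in amplified long gaps", {
  st <- mk_stats(231, 40)
  wp <- default_weights("relen")
  # a 432 ms gap (mean interval 231 ms) with a subthreshold deflection mid-gap
  lats <- c(100, 532, 717)
  es <- mk_es(c(lats, 316), c(2, 2, 2, 0.4), th = 0.5)
  seq0 <- activation_sequence(lats, "syn", "raw_relen")
  out <- recover_missed(seq0, wp, st, "relen", es = es)
  expect_length(out$inserted, 1)
  expect_equal(out$inserted, 316, tolerance = 1)
  # the 185 ms gap gets no insertion: too short to clear the refractory guard
  st2 <- mk_stats(231, 40)
  lats2 <- c(100, 285)
  es3 <- mk_es(c(lats2, 190), c(2, 2, 0.4), th = 0.5)
  out2 <- recover_missed(activation_sequence(lats2, "syn", "raw_relen"),
                         wp, st2, "relen", es = es3)
  expect_length(out2$inserted, 0)
})

test_that("gap weights are symmetric under time reversal", {
  st <- mk_stats(220, 45)
  for (shape in c("linear", "nonlinear")) {
    wp <- weight_params(shape, p70 = 0.2, p_mean = 2.5, enlarge = 1.25)
    for (K in c(150, 240, 433)) {
      k <- seq(0, K, by = 0.5)
      W <- weight_at(k, wp, st) * weight_at(K - k, wp, st)
      expect_equal(W, rev(W), tolerance = 1e-12)
    }
  }
})

test_that("a perfect sequence is a fixed point and tiny sequences pass through", {
  sr <- generate_iegm(cfg_clean(55))
  det <- relen_detect(sr$record)
  co <- correct_sequence(det$seq, detector = "relen", es = det$enhanced)
  expect_equal(co$lats, det$seq$lats)
  small <- activation_sequence(c(100, 300), "syn", "raw_relen")
  expect_warning(out <- correct_sequence(small, detector = "relen",
                                         es = mk_es(c(100, 300), c(2, 2))),
                 "uncorrected")
  expect_equal(out$lats, small$lats)
})

test_that("correction output always honours the refractory and never
           re-inserts what it removed", {
  for (s in 1:8) {
    corp <- make_corpus(synth_config(noise_sd = 0.01), 1, seed = 4400 + s)
    el <- corp[[1]]
    det <- relen_detect(el$record)
    if (length(det$seq$lats) < 3) next
    co <- correct_sequence(det$seq, detector = "relen", es = det$enhanced)
    if (length(co$lats) > 1) expect_gte(min(diff(co$lats)), 70 - 1e-6)
    rem <- attr(co, "removed"); ins <- attr(co, "inserted")
    if (length(rem) && length(ins))
      expect_gt(min(abs(outer(rem, ins, "-"))), 1)
  }
})

test_that("amm-mode correction runs end to end and respects the refractory", {
  sr <- generate_iegm(cfg_amm(61))
  s <- amm_detect(sr$record)
  co <- correct_sequence(s, detector = "amm", rec = sr$record, params = amm_params())
  expect_s3_class(co, "activation_sequence")
  expect_identical(co$source, "corrected")
  if (length(co$lats) > 1) expect_gte(min(diff(co$lats)), 70 - 1e-6)
})
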