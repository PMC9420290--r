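test_that("analytic envelope tracks amplitude and handles degenerate input", {
  t <- seq(0, 0.5, by = 1e-3)
  seg <- 2 * sin(2 * pi * 40 * t)
  env <- envelope(seg, "analytic_magnitude")
  core <- env[50:450]                       # away from the edges
  expect_true(all(abs(core - 2) / 2 < 0.05))
  expect_equal(envelope(rep(0, 100)), rep(0, 100))
  imp <- rep(0, 128); imp[60] <- 1
  expect_equal(which.max(envelope(imp)), 60L)
  # sliding-max alternative is bounded below by |x|
  es <- envelope(seg, "sliding_max", fs = 1000)
  expect_true(all(es >= abs(seg) - 1e-12))
})

test_that("tail trimming keeps the lobe containing the envelope maximum", {
  env <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  rng <- trim_tails(env, env, 0.2)
  expect_true(rng[1] > 1 && rng[2] < 100)
  expect_true(which.max(env) >= rng[1] && which.max(env) <= rng[2])
  # vanishing cutoff retains everything (positive envelope)
  expect_equal(trim_tails(env + 0.01, env + 0.01, 1e-9), c(1, 100))
  # a second lobe below the cutoff is rejected
  env2 <- c(rep(1, 20), rep(0.05, 20), rep(0.15, 20))
  expect_equal(trim_tails(env2, env2, 0.2), c(1, 20))
})

test_that("power barycenter matches closed forms", {
  t <- 0:100
  seg <- rep(0, 101); seg[41] <- 1; seg[61] <- 1
  expect_equal(barycenter_lat(seg, c(1, 101), t), 50)   # symmetric pair
  seg2 <- rep(0, 101); seg2[1] <- 1; seg2[11] <- 2
  expect_equal(barycenter_lat(seg2, c(1, 101), t), 10 * 4 / 5)  # a and 2a
  seg3 <- rep(0, 101); seg3[31] <- 3
  expect_equal(barycenter_lat(seg3, c(1, 101), t), 30)
  expect_true(is.na(barycenter_lat(rep(0, 10), c(1, 10), 0:9)))
})

test_that("barycenter is range-bound, shift-equivariant and scale-invariant", {
  set.seed(31)
  for (rep_i in 1:25) {
    n <- sample(50:200, 1)
    seg <- rnorm(n)
    t <- seq(0, by = 1, length.out = n)
    rng <- sort(sample(n, 2))
    if (rng[1] == rng[2]) next
    b <- barycenter_lat(seg, rng, t)
    expect_gte(b, t[rng[1]]); expect_lte(b, t[rng[2]])
    dd <- runif(1, -50, 50)
    expect_equal(barycenter_lat(seg, rng, t + dd), b + dd)
    a <- runif(1, 0.1, 9) * sample(c(-1, 1), 1)
    expect_equal(barycenter_lat(a * seg, rng, t), b)
  }
})

test_that("symmetric clean activations anchor the correction at their centroid", {
  sr <- generate_iegm(cfg_clean(321))
  det <- relen_detect(sr$record)
  ann <- correct_annotations(sr$record, det$seq)
  expect_equal(length(ann$seq$lats), length(det$seq$lats))
  m <- match_detections(ann$seq, sr$truth, 35)
  expect_equal(m$tp, m$n_truth)
  # every corrected LAT sits on the symmetric complex centre to one sample,
  # including beats whose peak annotation was several ms off
  expect_lte(max(abs(m$pairs$detected_lat - m$pairs$truth_lat)), 1.001)
  # beats already annotated at the centre are left in place
  expect_gte(mean(abs(ann$seq$lats - det$seq$lats) < 0.5), 0.7)
})

test_that("peak-hopping between two lobes is pulled back to a stable barycenter", {
  # identical two-lobe complexes every 200 ms, annotated alternately on the
  # first and second lobe: the raw intervals alternate long-short-long, the
  # corrected ones are nearly constant
  fs <- 1000
  x <- rep(0, 3000)
  tpl_t <- seq(-30, 30)
  lobe <- function(c0) exp(-(tpl_t - c0)^4 / (2 * 6^4)) * cos(2 * pi * 125 * (tpl_t - c0) / 1000)
  w <- lobe(-8) + lobe(8)                     # two equal lobes 16 ms apart
  centers <- seq(300, 2700, by = 200)
  for (c0 in centers) x[c0 + tpl_t + 1] <- x[c0 + tpl_t + 1] + w
  rec <- iegm_record(x, fs, "hop")
  hop <- rep(c(-8, 8), length.out = length(centers))
  annotated <- activation_sequence(centers + hop, "hop", "annotated_truth")
  out <- correct_annotations(rec, annotated)
  v_raw <- stats::var(diff(annotated$lats))
  v_cor <- stats::var(diff(out$seq$lats))
  expect_lt(v_cor, v_raw / 4)
  expect_lt(out$report$relative_change, 0)
})

test_that("correction reduces annotation error variance on jittered morphologies", {
  nerr <- 0
  for (s in 1:6) {
    cls <- if (s %% 2) "fractionated" else "double_peak"
    sr <- generate_iegm(cfg_lat(cls, 8800 + s))
    pa <- peak_annotate(sr$record, sr$truth)
    ann <- correct_annotations(sr$record, pa)
    e1 <- pa$lats - sr$truth$lats
    e2 <- ann$seq$lats - sr$truth$lats
    nerr <- nerr + (stats::var(e2) < stats::var(e1))
  }
  expect_gte(nerr, 5)
})
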