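test_that("structuring element interpolates its profile through the fiducials", {
  se <- structuring_element(c(0, 5, 10, 15, 20), c(0, -0.25, 1, -0.25, 0), 1000)
  expect_length(se$profile, 21L)
  expect_equal(se$profile[c(1, 6, 11, 16, 21)], c(0, -0.25, 1, -0.25, 0))
  expect_error(structuring_element(c(0, 10, 5, 15, 20), rep(0, 5), 1000),
               "increasing")
  expect_error(structuring_element(c(1, 5, 10, 15, 20), rep(0, 5), 1000),
               "onset")
})

test_that("SE initialisation uses the span of the first 500 ms", {
  x <- rep(0, 2000)
  x[100:110] <- seq(-1, 1, length.out = 11)   # span 2 mV in the first 500 ms
  rec <- iegm_record(x, 1000)
  se <- init_structuring_element(rec)
  expect_equal(se$fiducial_amplitudes[3], 2)
  expect_equal(se$fiducial_amplitudes[c(2, 4)], c(-0.5, -0.5))
  expect_equal(se$fiducial_offsets[5], 20)
  expect_error(init_structuring_element(iegm_record(rep(1, 2000), 1000)),
               "flat initialization")
  expect_error(init_structuring_element(iegm_record(rnorm(300), 1000)),
               "initialisation span")
})

test_that("morphology filter matches brute-force sliding operators", {
  set.seed(21)
  se <- structuring_element(c(0, 5, 10, 15, 20), c(0, -0.2, 0.8, -0.2, 0), 1000)
  for (rep_i in 1:5) {
    x <- rnorm(200)
    expect_equal(afdetect:::grey_erode(x, se$profile),
                 brute_erode(x, se$profile), tolerance = 1e-12)
    expect_equal(afdetect:::grey_dilate(x, se$profile),
                 brute_dilate(x, se$profile), tolerance = 1e-12)
    expect_equal(mm_filter(x, se), brute_mm(x, se$profile), tolerance = 1e-12)
  }
})

test_that("opening/closing bracket the signal and flat input gives a null feature", {
  set.seed(22)
  se <- structuring_element(c(0, 5, 10, 15, 20), c(0, -0.25, 1, -0.25, 0), 1000)
  for (rep_i in 1:10) {
    x <- rnorm(200)
    op <- afdetect:::grey_open(x, se$profile)
    cl <- afdetect:::grey_close(x, se$profile)
    expect_true(all(op <= x + 1e-12))
    expect_true(all(cl >= x - 1e-12))
  }
  xf <- rep(0.3, 200)
  expect_lt(max(abs(mm_filter(xf, se))), 1e-10)
  # a single spike on a flat baseline leaves a dominant lobe at the spike
  xs <- rep(0, 200); xs[100] <- 2
  xmm <- mm_filter(xs, se)
  expect_equal(which.max(abs(xmm)), 100L)
  expect_gt(max(abs(xmm)), 0.5)
})

test_that("SE update follows the learning rule and guards degeneracy", {
  se <- structuring_element(c(0, 5, 10, 15, 20), c(0, -0.25, 1, -0.25, 0), 1000)
  ext <- list(offsets = c(0, 7, 14, 17, 24), amplitudes = c(0, -0.5, 2, -0.5, 0))
  expect_equal(update_se(se, ext, 0)$fiducial_offsets, se$fiducial_offsets)
  expect_equal(update_se(se, ext, 1)$fiducial_offsets, ext$offsets)
  up <- update_se(se, ext, 0.5)
  expect_equal(up$fiducial_offsets, c(0, 6, 12, 16, 22))
  expect_equal(up$fiducial_amplitudes, c(0, -0.375, 1.5, -0.375, 0))
  # blended locations collapse -> update skipped
  bad <- list(offsets = c(0, 25, 2, 3, 4), amplitudes = rep(0, 5))
  expect_true(isTRUE(attr(update_se(se, bad, 1), "skipped")))
})

test_that("adaptive detector recovers a clean activation train accurately", {
  tp <- fp <- fn <- nt <- 0
  for (s in 1:2) {
    sr <- generate_iegm(cfg_amm(30 + s))
    m <- match_detections(amm_detect(sr$record), sr$truth, 15)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn; nt <- nt + m$n_truth
  }
  expect_gte(tp / nt, 0.95)
  expect_lte(fp / nt, 0.05)
})

test_that("detector keeps working across an abrupt amplitude step", {
  sr <- generate_iegm(cfg_amm(99))
  rec <- sr$record
  half <- length(rec$samples) %/% 2
  rec$samples[(half + 1):length(rec$samples)] <-
    5 * rec$samples[(half + 1):length(rec$samples)]
  s <- amm_detect(rec)
  late_truth <- sr$truth$lats[sr$truth$lats > duration_ms(rec) / 2 + 200]
  late_det <- s$lats[s$lats > duration_ms(rec) / 2 + 200]
  m <- match_detections(
    activation_sequence(late_det, rec$record_id, "raw_amm"),
    activation_sequence(late_truth, rec$record_id, "annotated_truth"), 15)
  expect_gte(m$tp / m$n_truth, 0.9)
})

test_that("SE stays valid over many updates", {
  sr <- generate_iegm(cfg_amm(7))
  s <- amm_detect(sr$record)
  se <- attr(s, "se")
  expect_true(all(diff(se$fiducial_offsets) > 0))
  expect_true(all(is.finite(se$fiducial_amplitudes)))
  expect_true(all(is.finite(se$profile)))
})
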