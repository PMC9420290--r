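test_that("record and sequence containers enforce their invariants", {
  expect_error(iegm_record(numeric(0), 1000), "non-empty")
  expect_error(iegm_record(c(1, NA), 1000), "finite")
  expect_error(iegm_record(rnorm(10), -1), "positive")
  rec <- iegm_record(rnorm(1000), 1000, "r1")
  expect_equal(duration_ms(rec), 999)

  expect_error(activation_sequence(c(100, 100), source = "raw_relen"),
               "strictly increasing")
  expect_error(activation_sequence(c(100, 150), source = "raw_relen"),
               "refractory")
  # ground truth is exempt from the refractory contract
  expect_silent(activation_sequence(c(100, 150), source = "annotated_truth"))
  expect_error(activation_sequence(c(100, 2000), source = "raw_relen", record = rec),
               "outside the record")
})

test_that("ms->samples conversion rounds halves away from zero at both rates", {
  expect_identical(ms_to_samples(0.5, 1000), 1L)
  expect_identical(ms_to_samples(-0.5, 1000), -1L)
  expect_identical(ms_to_samples(2.5, 1000), 3L)
  expect_identical(ms_to_samples(70, 2000), 140L)
  expect_identical(ms_to_samples(0.25, 2000), 1L)
})

test_that("interval statistics match hand arithmetic and reject tiny inputs", {
  s <- interval_stats(activation_sequence(c(0, 200, 400, 600)))
  expect_equal(s$mean_aa, 200)
  expect_equal(s$sigma_aa, 0)
  expect_equal(s$n_intervals, 3L)
  s2 <- interval_stats(c(0, 100, 300))
  expect_equal(s2$mean_aa, 150)
  expect_equal(s2$sigma_aa, 50)     # population SD
  expect_error(interval_stats(c(42)), "insufficient")
})

test_that("CSV record round-trip preserves samples and infers the rate", {
  rec <- iegm_record(rnorm(1000), 1000, "rt")
  f <- file.path(tempdir(), "rt.csv")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$fs, 1000, tolerance = 1e-9)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)

  # a 2 kHz grid is recognised too
  rec2 <- iegm_record(rnorm(500), 2000, "rt2")
  f2 <- file.path(tempdir(), "rt2.csv")
  write_record(rec2, f2)
  expect_equal(read_record(f2)$fs, 2000, tolerance = 1e-6)
})

test_that("CSV reader rejects jittered or empty time grids", {
  t <- seq(0, 999) + runif(1000, -0.5, 0.5)
  f <- file.path(tempdir(), "jit.csv")
  write.csv(data.frame(time_ms = t, amplitude_mV = rnorm(1000)), f, row.names = FALSE)
  expect_error(read_record(f), "non-uniform")
  f0 <- file.path(tempdir(), "empty.csv")
  writeLines("time_ms,amplitude_mV", f0)
  expect_error(read_record(f0), "empty")
  f1 <- file.path(tempdir(), "onecol.csv")
  write.csv(data.frame(amplitude_mV = rnorm(100)), f1, row.names = FALSE)
  expect_error(read_record(f1), "fs")
  expect_equal(read_record(f1, fs = 1000)$fs, 1000)
})

test_that("a WFDB format-16 record written in code reads back correctly", {
  dir <- tempdir()
  fs <- 2000
  adu <- as.integer(round(sin(2 * pi * 5 * seq(0, 1, length.out = 2000)) * 400))
  writeLines(c("wf01 1 2000 2000", "wf01.dat 16 200 0(0) 0 0"),
             file.path(dir, "wf01.hea"))
  writeBin(adu, file.path(dir, "wf01.dat"), size = 2L, endian = "little")
  rec <- read_record(file.path(dir, "wf01.hea"), format = "wfdb")
  expect_equal(rec$fs, 2000)
  expect_equal(length(rec$samples), 2000)
  expect_equal(rec$samples, adu / 200, tolerance = 1e-9)
})

test_that("annotation files round-trip in CSV and JSON to sub-microsecond", {
  set.seed(7)
  lats <- sort(runif(1000, 0, 1e5))
  lats <- lats[c(TRUE, diff(lats) > 1e-3)]
  seq0 <- activation_sequence(lats, "rr", "annotated_truth")
  for (ext in c("csv", "json")) {
    f <- file.path(tempdir(), paste0("ann.", ext))
    write_annotations(seq0, f)
    back <- read_annotations(f)
    expect_equal(back$lats, seq0$lats, tolerance = 1e-9)
    expect_identical(back$record_id, "rr")
    expect_identical(back$source, "annotated_truth")
  }
  # empty sequence -> header-only CSV that reads back empty
  f <- file.path(tempdir(), "ann0.csv")
  write_annotations(activation_sequence(numeric(0), "rr"), f)
  expect_length(read_annotations(f)$lats, 0)
})
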