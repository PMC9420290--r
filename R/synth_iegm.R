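# Seeded generator of AF-like pulmonary-vein electrograms with exact
# ground-truth activation times: irregular activation trains, heterogeneous
# morphologies, beat-to-beat amplitude variability, band-limited noise,
# impulsive artifacts and far-field bumps.

#' Configuration of the synthetic IEGM generator
#'
#' Defaults emulate persistent-AF pulmonary-vein electrograms: a ~220 ms mean
#' cycle length with substantial irregularity, a mix of biphasic,
#' fractionated and double-peak activation morphologies, ~0.5 mV activations
#' with 20\% beat-to-beat amplitude variation plus a slow contact/respiratory
#' amplitude modulation, 30--300 Hz band-limited baseline noise, sparse
#' impulsive artifacts and low-amplitude far-field bumps.
#'
#' @param duration record duration, s.
#' @param fs sampling rate, Hz.
#' @param mean_cl mean activation cycle length, ms.
#' @param cl_sd standard deviation of the cycle length, ms.
#' @param min_cl minimal cycle length, ms (>= 70, the refractory of the
#'   pulmonary veins).
#' @param morphology_mix named fractions over \code{biphasic},
#'   \code{fractionated}, \code{double_peak}; must sum to 1.
#' @param amp_mean mean activation amplitude, mV.
#' @param amp_cv coefficient of variation of the (lognormal) amplitudes.
#' @param noise_sd standard deviation of the band-limited baseline noise, mV.
#' @param artifact_rate impulsive artifacts per second.
#' @param farfield_amp amplitude scale of far-field bumps, mV.
#' @param farfield_rate far-field bumps per second.
#' @param dropout_prob fraction of activations generated at near-zero
#'   amplitude (undersensing substrate).
#' @param mod_depth depth of the slow sinusoidal amplitude modulation of the
#'   near-field activations (catheter-contact / respiratory variation).
#' @param mod_freq frequency of the amplitude modulation, Hz.
#' @param pause_prob probability that an interval is a firing pause of
#'   2.5--3.5 times the mean cycle length (intermittent pulmonary-vein
#'   activity); 0 gives a steady activation train.
#' @param carrier_freq carrier frequency of the activation deflection lobes,
#'   Hz (within the 30--300 Hz acquisition band; higher values give sharper
#'   deflections).
#' @param site_morphology if \code{TRUE}, one base morphology per class is
#'   drawn for the whole record (a stable recording site) and beats vary only
#'   by sub-deflection jitter; if \code{FALSE} every beat draws a fresh
#'   morphology.
#' @param subpeak_jitter relative standard deviation of the per-beat
#'   sub-deflection amplitude jitter under site morphology.
#' @param seed integer seed; the generator is deterministic given
#'   \code{(config, seed)}.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(duration = 10, fs = 1000, mean_cl = 220, cl_sd = 40,
                         min_cl = 90,
                         morphology_mix = c(biphasic = 0.5, fractionated = 0.3,
                                            double_peak = 0.2),
                         amp_mean = 0.5, amp_cv = 0.2, noise_sd = 0.03,
                         artifact_rate = 0.05, farfield_amp = 0.06,
                         farfield_rate = 0.2, dropout_prob = 0.01,
                         mod_depth = 0.35, mod_freq = 0.25,
                         pause_prob = 0, carrier_freq = 125,
                         site_morphology = FALSE, subpeak_jitter = 0.25,
                         seed = 1L) {
  stopifnot(duration > 0, fs > 0, min_cl >= 70, mean_cl >= min_cl, cl_sd >= 0,
            amp_mean > 0, amp_cv >= 0, noise_sd >= 0, artifact_rate >= 0,
            farfield_amp >= 0, farfield_rate >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            mod_depth >= 0, mod_depth < 1, mod_freq >= 0,
            pause_prob >= 0, pause_prob < 1, carrier_freq > 0,
            is.logical(site_morphology), subpeak_jitter >= 0)
  mm <- morphology_mix[c("biphasic", "fractionated", "double_peak")]
  if (any(is.na(mm)) || abs(sum(mm) - 1) > 1e-9)
    stop("morphology_mix must give fractions for biphasic/fractionated/double_peak summing to 1")
  structure(list(duration = duration, fs = fs, mean_cl = mean_cl, cl_sd = cl_sd,
                 min_cl = min_cl, morphology_mix = mm, amp_mean = amp_mean,
                 amp_cv = amp_cv, noise_sd = noise_sd,
                 artifact_rate = artifact_rate, farfield_amp = farfield_amp,
                 farfield_rate = farfield_rate, dropout_prob = dropout_prob,
                 mod_depth = mod_depth, mod_freq = mod_freq,
                 pause_prob = pause_prob, carrier_freq = carrier_freq,
                 site_morphology = site_morphology, subpeak_jitter = subpeak_jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Mexican-hat wavelet on a ms axis: dominant positive peak flanked by two
# shallow troughs, the canonical compact biphasic-spike surrogate
ricker_ms <- function(t_ms, s_ms) (1 - (t_ms / s_ms)^2) * exp(-t_ms^2 / (2 * s_ms^2))

# the morphology of an activation complex, separated into the random draw of
# its shape parameters and the rendering into samples so that one site-specific
# shape can be re-rendered with per-beat jitter
draw_morph <- function(class, f_hz) {
  if (class == "biphasic") {
    list(class = class, f_hz = f_hz)
  } else if (class == "fractionated") {
    nsub <- sample(6:11, 1L)
    span <- runif(1L, 45, 85)
    list(class = class, f_hz = f_hz, span = span,
         centers = sort(runif(nsub, -span / 2, span / 2)),
         rel = runif(nsub, 0.4, 1),
         sgn = sample(c(-1, 1), nsub, replace = TRUE))
  } else {
    list(class = class, f_hz = f_hz,
         sep = runif(1L, 12, 28), ratio = runif(1L, 0.6, 0.95),
         lead = runif(1L) < 0.5)
  }
}

render_template <- function(m, fs, amp, jitter = 0) {
  grid <- function(half_ms) {
    k <- ms_to_samples(half_ms, fs)
    (seq(-k, k)) * 1000 / fs
  }
  # activation complexes are oscillatory packets: deflection lobes of a
  # ~125 Hz carrier (~3 ms half-waves, the 30-300 Hz band-pass content of
  # clinical bipolar electrograms) under a flat-topped envelope, so a complex
  # sustains near-full amplitude over 15-60 ms of each cycle as in real
  # pulmonary-vein recordings; cosine phase gives a dominant central
  # deflection whose polarity is stable across beats, as catheter orientation
  # fixes it in real recordings
  packet <- function(t, env_sd = 10) {
    exp(-t^4 / (2 * env_sd^4)) * cos(2 * pi * m$f_hz * t / 1000)
  }
  jit <- function(v) {
    if (jitter <= 0) v else pmax(v * (1 + jitter * rnorm(length(v))), 0.05)
  }
  if (m$class == "biphasic") {
    t <- grid(16)
    w <- amp * packet(t)
  } else if (m$class == "fractionated") {
    rel <- jit(m$rel)
    t <- grid(m$span / 2 + 8)
    w <- numeric(length(t))
    for (j in seq_along(rel))
      w <- w + rel[j] * m$sgn[j] * amp * ricker_ms(t - m$centers[j], 2)
  } else {
    a <- jit(c(1, m$ratio))
    t <- grid(m$sep / 2 + 14)
    if (m$lead)
      w <- a[1L] * amp * packet(t + m$sep / 2, 8) + a[2L] * amp * packet(t - m$sep / 2, 8)
    else
      w <- a[2L] * amp * packet(t + m$sep / 2, 8) + a[1L] * amp * packet(t - m$sep / 2, 8)
  }
  list(t = t, w = w, centroid = sum(t * w^2) / sum(w^2))
}

make_template <- function(class, fs, amp, f_hz = 125) {
  render_template(draw_morph(class, f_hz), fs, amp)
}

# intervals from a truncated-normal renewal process, optionally interrupted
# by firing pauses; the 1 ms slack over min_cl absorbs template placement
# rounding
draw_intervals <- function(n, mean_cl, cl_sd, min_cl, pause_prob = 0) {
  out <- numeric(0)
  lo <- min_cl + 1
  while (length(out) < n) {
    d <- rnorm(n, mean_cl, cl_sd)
    out <- c(out, d[d >= lo])
  }
  out <- out[seq_len(n)]
  if (pause_prob > 0) {
    p <- runif(n) < pause_prob
    out[p] <- runif(sum(p), 2.5, 3.5) * mean_cl
  }
  out
}

#' Generate a synthetic AF electrogram with ground truth
#'
#' Activation times are drawn from a truncated-normal renewal process;
#' morphology templates are placed so that the energy barycenter of each
#' clean template coincides with its ground-truth LAT (giving the barycenter
#' annotation a well-defined target); band-limited Gaussian noise, Poisson
#' impulsive artifacts and far-field bumps are added on top. Deterministic
#' given the config seed.
#'
#' @param cfg a \code{synth_config}.
#' @return object of class \code{synth_record}: a list with \code{record}
#'   (\code{iegm_record}), \code{truth} (\code{activation_sequence}, source
#'   \code{"annotated_truth"}) and \code{meta} (data frame with per-activation
#'   morphology class, amplitude and dropout flag).
#' @export
generate_iegm <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  fs <- cfg$fs
  dur_ms <- cfg$duration * 1000
  n <- round(dur_ms * fs / 1000) + 1L
  x <- numeric(n)
  rec0 <- iegm_record(x, fs, record_id = sprintf("synth%06d", cfg$seed))

  edge <- 120
  nmax <- ceiling((dur_ms - 2 * edge) / cfg$min_cl) + 2L
  iv <- draw_intervals(nmax, cfg$mean_cl, cfg$cl_sd, cfg$min_cl, cfg$pause_prob)
  lat_nom <- edge + runif(1L, 0, cfg$mean_cl) + c(0, cumsum(iv))
  lat_nom <- lat_nom[lat_nom <= dur_ms - edge]

  k <- length(lat_nom)
  classes <- sample(names(cfg$morphology_mix), k, replace = TRUE,
                    prob = cfg$morphology_mix)
  sdlog <- sqrt(log(1 + cfg$amp_cv^2))
  amps <- stats::rlnorm(k, log(cfg$amp_mean) - sdlog^2 / 2, sdlog)
  dropout <- runif(k) < cfg$dropout_prob
  amps[dropout] <- amps[dropout] * runif(sum(dropout), 0.05, 0.2)
  if (cfg$mod_depth > 0 && cfg$mod_freq > 0) {
    phase <- runif(1L, 0, 2 * pi)
    amps <- amps * (1 + cfg$mod_depth * sin(2 * pi * cfg$mod_freq * lat_nom / 1000 + phase))
  }

  site <- NULL
  if (cfg$site_morphology)
    site <- lapply(stats::setNames(nm = names(cfg$morphology_mix)),
                   draw_morph, f_hz = cfg$carrier_freq)

  lats_true <- numeric(k)
  for (i in seq_len(k)) {
    tpl <- if (cfg$site_morphology)
      render_template(site[[classes[i]]], fs, amps[i], cfg$subpeak_jitter)
    else
      make_template(classes[i], fs, amps[i], cfg$carrier_freq)
    # place so the clean-template energy barycenter lands on the nominal LAT
    # (up to sample-grid rounding), and record the realised barycenter as truth
    i0 <- time_sample(rec0, lat_nom[i] - tpl$centroid + tpl$t[1L])
    idx <- i0 + seq_along(tpl$w) - 1L
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl$w[ok]
    t_axis <- sample_time(rec0, idx)
    lats_true[i] <- sum(t_axis[ok] * tpl$w[ok]^2) / sum(tpl$w[ok]^2)
  }

  if (cfg$noise_sd > 0) {
    nz <- rnorm(n)
    bf <- signal::butter(2, c(30, min(300, 0.45 * fs)) / (fs / 2), type = "pass")
    nz <- signal::filtfilt(bf, nz)
    x <- x + nz / stats::sd(nz) * cfg$noise_sd
  }
  n_art <- rpois(1L, cfg$artifact_rate * cfg$duration)
  if (n_art > 0) {
    ta <- runif(n_art, edge, dur_ms - edge)
    aa <- runif(n_art, 1, 3) * cfg$amp_mean * sample(c(-1, 1), n_art, replace = TRUE)
    for (j in seq_len(n_art)) {
      i0 <- time_sample(rec0, ta[j])
      if (i0 >= 2L && i0 <= n - 1L) {
        x[i0] <- x[i0] + aa[j]
        x[i0 + c(-1L, 1L)] <- x[i0 + c(-1L, 1L)] + 0.4 * aa[j]
      }
    }
  }
  n_ff <- rpois(1L, cfg$farfield_rate * cfg$duration)
  if (n_ff > 0 && cfg$farfield_amp > 0) {
    tf <- runif(n_ff, edge, dur_ms - edge)
    af <- runif(n_ff, 0.5, 1) * cfg$farfield_amp * sample(c(-1, 1), n_ff, replace = TRUE)
    tg <- seq(-24, 24) * 1000 / fs
    for (j in seq_len(n_ff)) {
      bump <- af[j] * exp(-tg^2 / (2 * 8^2))
      i0 <- time_sample(rec0, tf[j]) - 24L
      idx <- i0 + seq_along(bump) - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + bump[ok]
    }
  }

  rec <- iegm_record(x, fs, record_id = rec0$record_id)
  truth <- activation_sequence(lats_true, record_id = rec$record_id,
                               source = "annotated_truth", record = rec)
  if (length(lats_true) > 1L && any(diff(lats_true) < cfg$min_cl - 1.5))
    stop("internal error: generated truth violates the minimal cycle length")
  structure(list(record = rec, truth = truth,
                 meta = data.frame(lat = lats_true, class = classes,
                                   amplitude = amps, dropout = dropout)),
            class = "synth_record")
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("<synth_record '%s'> %.1f s, %d true activations\n",
              x$record$record_id, duration_ms(x$record) / 1000,
              length(x$truth$lats)))
  invisible(x)
}

#' Generate a labelled corpus of synthetic records
#'
#' Per-record seeds are derived deterministically from the corpus seed. When
#' \code{dir} is given, each record is written as CSV, each truth sequence as
#' JSON, and a \code{manifest.json} listing the files is written alongside.
#'
#' @param cfg template \code{synth_config} (its \code{seed} is ignored).
#' @param n_records number of records.
#' @param seed corpus seed.
#' @param dir optional output directory.
#' @return (invisibly when writing) list of \code{synth_record}s with
#'   attribute \code{"manifest"} (data frame of record ids, seeds and file
#'   names).
#' @export
make_corpus <- function(cfg, n_records, seed = 1L, dir = NULL) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  seeds <- if (n_records > 0) sample.int(.Machine$integer.max - 1L, n_records) else integer(0)
  corpus <- vector("list", n_records)
  manifest <- data.frame(record_id = character(n_records),
                         seed = seeds,
                         record_file = character(n_records),
                         truth_file = character(n_records),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_records)) {
    ci <- cfg
    ci$seed <- seeds[i]
    sr <- generate_iegm(ci)
    corpus[[i]] <- sr
    manifest$record_id[i] <- sr$record$record_id
    if (!is.null(dir)) {
      rf <- file.path(dir, paste0(sr$record$record_id, ".csv"))
      tf <- file.path(dir, paste0(sr$record$record_id, "_truth.json"))
      write_record(sr$record, rf)
      write_annotations(sr$truth, tf)
      manifest$record_file[i] <- basename(rf)
      manifest$truth_file[i] <- basename(tf)
    }
  }
  attr(corpus, "manifest") <- manifest
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    return(invisible(corpus))
  }
  corpus
}
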