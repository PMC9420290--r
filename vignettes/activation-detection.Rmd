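---
title: "Detecting and annotating atrial activations in pulmonary-vein electrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating atrial activations in pulmonary-vein electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdetect)
```

## The problem

Bipolar intracardiac electrograms (IEGMs) recorded inside the pulmonary
veins (PVs) during atrial fibrillation (AF) consist of irregular trains of
atrial activation complexes (AAs): packets of sharp deflections lasting
tens of milliseconds, separated by cycle lengths of roughly 150–300 ms,
with strong beat-to-beat variation in amplitude and morphology. Two
analysis tasks recur in the electrophysiology lab: *detecting* every
activation (so cycle-length statistics can be computed), and *annotating*
each one with a single local activation time (LAT) that is stable across
beats even when the complex is fractionated into many sub-deflections.

`afdetect` implements a three-stage pipeline for both tasks:

1. **Raw detection** by one of two detectors: a relative-energy
   enhancement detector (`relen_detect()`) or an adaptive
   mathematical-morphology detector (`amm_detect()`).
2. **Over/undersensing correction** (`correct_sequence()`): false
   detections are removed and missed activations recovered using weight
   functions built from the statistics of the detected intervals.
3. **Barycenter annotation correction** (`correct_annotations()`): each
   LAT is replaced by the energy barycenter of its envelope-gated
   activation segment.

A seeded synthetic IEGM generator (`generate_iegm()`) with exact ground
truth, evaluation metrics and a grid-search tuner complete the toolkit.

## Stage 1a: relative-energy detection

The electrogram $x(n)$ is multiplied by an enhancement coefficient, the
ratio of its short-term to its Hamming-weighted long-term energy:

$$c(n) = \frac{\sum_{i=n-s_{win}}^{n+s_{win}} |x(i)|^p}
              {\sum_{j=n-l_{win}}^{n+l_{win}} |\mathrm{Hamming}(j)\,x(j)|^p},
\qquad x_{RE}(n) = x(n)\,c(n).$$

Defaults are the tuned optima: $s_{win} = 100$ ms and $l_{win} = 400$ ms
(half-lengths), exponent $p = 4$. The short window matches the duration of
an activation complex; the long window tracks the local baseline.
Activations are local maxima of $|x_{RE}|$ above a threshold
$\mathrm{TH}_P$, with a 70 ms refractory (the shortest physiological PV
interval); among candidates closer than the refractory the larger one is
kept.

**Threshold orientation.** $\mathrm{TH}_P$ is defined as the $P$-th
percentile of the amplitude distribution of the rectified enhanced signal,
with $P = 11$ by default. We take the percentile *from the top*: the
threshold is the value exceeded by $P\%$ of samples
(`threshold_side = "upper"`, the `quantile(…, 1 - P/100)` point). The
reasoning is structural: activation complexes occupy roughly 10–30 % of
each cycle in PV recordings, so a threshold exceeded by ~11 % of samples
sits just above the baseline and just below the complex amplitudes — which
is also why the useful tuning range of $P$ is a narrow band (6–13). Read
from the bottom instead, the threshold would lie *below* ~89 % of samples,
i.e. inside the noise floor, and any record with baseline noise would
produce a false detection in essentially every gap longer than two
refractory periods. The bottom-oriented reading remains available as
`threshold_side = "lower"` for audit.

Other pinned conventions: window sums are truncated at the record edges
(no padding); the Hamming window appears in the denominator only, exactly
as in the defining ratio; rectification is `abs()` by default because
bipolar electrogram polarity is arbitrary (`polarity` exposes `pos`/`neg`);
the percentile uses linear interpolation between order statistics
(`quantile` type 7); the denominator is floored at
$10^{-12}\max|x|^p$ so silent records yield $c \equiv 0$ rather than NaN.
The threshold is computed once per recording.

## Stage 1b: adaptive mathematical morphology

The AMM detector filters each 200 ms window with grayscale opening
($\circ$) and closing ($\bullet$) by a structuring element (SE) and keeps
the average of the top-hat and bottom-hat residues,

$$x_{MM} = x - \tfrac{1}{2}\big(x \circ SE + x \bullet SE\big),$$

which is non-zero where the signal contains features sharper than the SE —
the activation deflections — and zero on baseline. The SE is defined by
five fiducial points (onset, first trough, peak, second trough, offset)
and realised by linear interpolation at the sampling rate. It is
synthesized from the record itself (amplitude span of the first 500 ms,
duration 20 ms by default) and then *adapted*: after each detected
activation, every fiducial location and amplitude is blended with the
extracted activation's fiducials with learning coefficient
$\alpha = 0.5$.

Implementation choices that the formulas leave open:

* **Non-zero tolerance.** "Non-zero segments" of $x_{MM}$ are runs
  exceeding `zero_tol` times the running maximum of $|x_{MM}|$. The
  default is 0.1. Much smaller values make the segments include the
  faintest morphological ringing, so the extracted onset/offset geometry —
  and through the learning rule the SE itself — inflates and drifts;
  detection timing then degrades by tens of milliseconds. At 0.1 the
  segments hug the complex core and the SE stays stable over arbitrarily
  many updates.
* **Window edges.** Grayscale opening/closing are contaminated within one
  SE length of a window edge (truncated kernel support). Each 200 ms
  window is therefore extended by a look-back margin of
  `max(se_duration, 70 ms)` and one SE length of look-ahead, the invalid
  edge samples of the feature signal are blanked, and segments that reach
  the analysis-window cut are deferred to the next window, which sees them
  whole. Duplicates are resolved by the refractory rule.
* **Degenerate updates.** If blending would make the fiducial locations
  non-increasing (or the SE shorter than 3 samples), the update is skipped
  and the current SE kept.
* A record whose first 500 ms are flat cannot synthesize an SE and is
  rejected.

## Stage 2: over/undersensing correction

From the raw sequence, interval statistics
($\mathrm{meanAA}$, $\sigma_{AA}$) parameterise two weight functions of
the time $k$ since (or until) a detected activation, both zero below the
70 ms refractory:

* linear: a ramp from $P_{70}$ at $k = 70$ ms to $P_{meanAA}$ at
  $k = \mathrm{meanAA}$, continuing with the same slope;
* nonlinear: a truncated Gaussian centred at $\mathrm{meanAA}$, flat at
  $P_{meanAA}$ beyond it.

Defaults are the per-detector optima: nonlinear with $E = 1.25$,
$P_{meanAA} = 3$ for the relative-energy detector; linear with
$P_{70} = 0.4$, $P_{meanAA} = 2.2$ for AMM.

**Gaussian width.** The printed closed form of the nonlinear weight has
amplitude $E\,P_{meanAA}/\sigma_{AA}$ on the Gaussian branch but
$P_{meanAA}$ on the flat branch, which is discontinuous at the mean unless
$\sigma_{AA} = E$. The accompanying description — a Gaussian *enlarged by
a factor E* that *reaches* $P_{meanAA}$ — is self-consistent, so the
default (`gaussian_mode = "widened_std"`) uses standard deviation
$E\,\sigma_{AA}$ and peak $P_{meanAA}$, continuous at the mean; the
literal form is retained as `gaussian_mode = "literal"` for audit.

One pass removes false detections first, then screens gaps for missed
activations. For removal, each activation's neighbours are weighted at
their interval position; in relen mode a neighbour whose weighted enhanced
amplitude falls below $\mathrm{TH}_P$ is removed (an activation flagged
from either side is removed, processing left to right on the survivors);
in amm mode the weighted signal is re-run through the morphology detector.
For recovery, the signal inside each gap of length $K$ is multiplied by
$W(k) = w(k)\,w(K-k)$ — the weight times its time reversal, symmetric on
the gap — which amplifies the centre of gaps long relative to the mean;
one activation per gap per pass may be inserted where the weighted
amplitude crosses the threshold, at least 70 ms from both endpoints and
never within half a refractory of a detection removed in the same pass.

**Robust statistics.** The weights need the spread of the *physiological*
intervals, but a raw sequence with missed beats contains double-length
intervals — exactly the defect this stage repairs — which inflate the
plain standard deviation two- to three-fold and flatten the Gaussian until
it amplifies mid-gap noise everywhere. `correct_sequence()` therefore
computes the statistics after discarding intervals longer than 1.75 times
the median interval (`correction_stats()`). For healthy sequences nothing
is discarded. `interval_stats()` keeps the plain textbook definition.

The statistics are frozen from the raw sequence and not recomputed
mid-pass; `max_passes` (default 1) allows iteration.

## Stage 3: barycenter annotation

For each activation, independently of all others: a segment of up to
±70 ms (clipped at the midpoints to the neighbouring activations) is
extracted; its envelope is computed (magnitude of the analytic signal by
default, computed by FFT half-spectrum doubling; a sliding-max alternative
is available); tails where the envelope falls below `cutoff_frac` of the
segment maximum are rejected; and the LAT is replaced by the barycenter of
the *squared* signal over the retained range,
$\mathrm{LAT}^* = \sum t\,x(t)^2 / \sum x(t)^2$. Squaring emphasises the
high-amplitude portion, which is also why only mild tail-trimming is
needed: the default `cutoff_frac` is 0.05, enough to reject
noise-dominated tails while keeping all sub-deflection clusters of a
fractionated complex inside the barycenter. (Aggressive trimming — say a
0.2 cutoff — keeps only the single dominant cluster, and the corrected
annotation then hops between clusters exactly like the peak annotation it
is meant to replace.)

Corrections cannot cross (segments are clipped at gap midpoints) but can
compress an interval below the refractory; offending pairs revert to their
original times. If the *input* annotations already violate 70 ms the
output can only guarantee the input's own minimal spacing.

Because true LATs are unknown on clinical data, the method is evaluated
through the variance of the interval sequence: a beat-by-beat
re-annotation leaves the true interval variability untouched, so —
assuming annotation errors independent of the rhythm — any reduction in
interval variance is attributable to reduced annotation error.
`variance_change()` reports population variances of the interval
sequences before and after, and their relative change.

## The synthetic generator

`generate_iegm()` emulates the properties of PV recordings in persistent
AF that drive all four algorithms, with exact ground truth:

* **Rhythm**: a truncated-normal renewal process (mean 220 ms, SD 40 ms,
  minimum 90 ms by default). `pause_prob` optionally interleaves firing
  pauses of 2.5–3.5 cycle lengths, emulating intermittent PV activity.
* **Morphology**: activation complexes are oscillatory packets — a 125 Hz
  carrier (3–4 ms deflection lobes, the sharp content that the 30–300 Hz
  acquisition band admits and that morphological filtering exploits) under
  a flat-topped envelope, so each complex sustains amplitude over tens of
  milliseconds and complexes occupy ~15–25 % of each cycle, the occupancy
  that makes the 11-percent threshold meaningful. Three classes: biphasic
  packets (~30 ms), fractionated complexes (6–11 sharp sub-deflections
  over 45–85 ms), and double-peak complexes (two lobes 12–28 ms apart).
  The dominant deflection polarity is stable across beats, as catheter
  orientation fixes it in reality. With `site_morphology = TRUE` one base
  shape per class is drawn for the whole record and beats vary only by
  sub-deflection jitter — a stable recording site, the regime in which
  peak annotation hops while the complex shape persists.
* **Ground truth**: each clean template is placed so that its energy
  barycenter coincides with the truth LAT, giving the annotation
  correction a well-defined target.
* **Corruption**: 30–300 Hz band-limited Gaussian noise; Poisson impulsive
  artifacts (0.05/s); low-amplitude far-field bumps (0.06 mV, 0.2/s);
  near-zero-amplitude dropout beats (1 %); beat-to-beat lognormal
  amplitude variation (CV 0.2) and a slow sinusoidal amplitude modulation
  (depth 0.35, 0.25 Hz) emulating catheter-contact/respiratory variation.

Everything is deterministic given `(config, seed)`, and the generator
restores the caller's RNG state.

What the generator does **not** emulate: wavefront propagation and
multi-channel structure, catheter motion, ventricular far-field timed to a
ventricular rhythm, continuous fibrillatory baseline without an isoline,
and non-stationary cycle-length drifts. Tests passing on this substrate
therefore show that the implementation realises the intended mechanisms
under controlled conditions — not that clinical error rates would be
reproduced.

## The validation experiments

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` run five experiments; corpus sizes were chosen to
keep sampling noise well below the measured effects:

1. **Equation oracles** — the energy coefficient against a literal
   double-loop, grayscale erosion/dilation against brute-force sliding
   min/max, weights against closed forms (100 two-second records; exact to
   1e-9 relative).
2. **Invariants** — refractory on 1 000 fuzzed inputs, opening ≤ x ≤
   closing, gap-weight symmetry, barycenter containment/shift/scale,
   matching count identities.
3. **Clean recovery** — 40 × 10 s noise-free biphasic records (all
   corruption off, amplitude CV 0.05): the relative-energy detector at
   defaults attains 0 % total error at ±35 ms.
4. **Degraded recovery** — generator defaults with the noise level
   calibrated into the 2–5 % raw-error band; over 20 seeds × 24 records,
   the sensing correction strictly reduces the pooled error in ≥ 95 % of
   seeds.
5. **Tuning landscape** — a 12-record corpus with intermittent firing
   (`pause_prob = 0.15`), stronger far-field (0.4/s) and amplitude
   heterogeneity (CV 0.25): the grid search over
   $s_{win} \in \{50,100,150\}$, $l_{win} \in \{200,400,800\}$ finds its
   optimum at an interior long-window value. Intermittency is what makes
   the long window matter: with $l_{win}$ shorter than a pause the
   enhancement degenerates into a per-event gain control that amplifies
   far-field bumps inside pauses, while an over-long window averages over
   the amplitude modulation and misses weak beats.
6. **Annotation correction** — site-stable fractionated and double-peak
   corpora (20 seeds × 12 records, sub-peak jitter 0.5) annotated at their
   largest deflection: the barycenter correction reduces the variance of
   (annotation − truth) *and* the interval-sequence variance in ≥ 90 % of
   seeds. The experiment uses peak-annotated known activations rather than
   detector output because detector misses create double-length intervals
   whose variance contribution (~40 000 ms² each) drowns the
   annotation-jitter signal this stage targets.

## A worked run

```{r, eval = FALSE}
cfg <- synth_config(duration = 20, noise_sd = 0.01, seed = 42)
sr <- generate_iegm(cfg)
res <- run_pipeline(sr$record, algo = "relen", truth = sr$truth)
print(res)
```

On this record the raw detector misses two dropout beats (2.25 % FN, 0 %
FP); with no removable or recoverable errors present the corrected stage
is a fixed point, and the barycenter stage re-annotates without changing
the detection counts.

## Known limitations

* The percentile threshold is self-referential: it adapts to the fraction
  of time occupied by activations, so recordings whose active fraction
  differs grossly from the configured percentile (very slow rhythms, long
  asystolic stretches) shift the operating point; `percentile` should then
  be re-tuned.
* With exponent $p = 4$ the enhanced amplitude of a beat scales like the
  fifth power of its relative amplitude, so very weak beats are
  suppressed far below threshold — the dominant false-negative mechanism.
  The recovery stage only retrieves beats missed by a modest margin.
* The AMM detector requires deflections sharper than its structuring
  element; on smooth, low-frequency complexes the morphological residue
  vanishes and sensitivity drops.
* The sensing correction assumes the interval distribution is unimodal
  around its mean; genuinely bimodal rhythms (bigeminy-like PV firing)
  would mislead the weights.
* WFDB support covers signal formats 16 and 212; annotation files are
  exchanged as CSV/JSON.
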