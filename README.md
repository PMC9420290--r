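# afdetect

Automatic detection and temporal annotation of atrial activations (AAs) in
single-channel bipolar intracardiac electrograms (IEGMs) recorded in the
pulmonary veins during atrial fibrillation — for electrophysiology
researchers who need reliable activation sequences and cycle-length
statistics from complex, fractionated AF recordings.

## Method

The pipeline has three stages:

1. **Raw detection.** Two detectors are provided.
   *Relative energy (Rel-En)*: the signal is enhanced by the ratio of its
   short- to its Hamming-weighted long-term energy,

   ```
   c(n) = Σ_{i=n-s}^{n+s} |x(i)|^p  /  Σ_{j=n-l}^{n+l} |Hamming(j)·x(j)|^p ,
   x_RE(n) = x(n)·c(n),
   ```

   with defaults s = 100 ms, l = 400 ms (half-windows), p = 4. Activations
   are local maxima of |x_RE| above TH_P — the amplitude exceeded by P = 11 %
   of samples — under a 70 ms physiological refractory.
   *Adaptive mathematical morphology (AMM)*: each 200 ms window is filtered
   by `x_MM = x − (opening + closing)/2` with a five-fiducial structuring
   element (20 ms) that is re-fitted to every detected activation with
   learning coefficient α = 0.5.

2. **Over/undersensing correction.** Weight functions built from the
   detected interval statistics (meanAA, σ_AA) — a linear ramp or a
   truncated Gaussian, both zero below 70 ms — dampen implausibly early
   detections (removed if the weighted amplitude falls below TH_P) and
   amplify gap centres via `W(k) = w(k)·w(K−k)` to recover missed beats.

3. **Barycenter annotation.** Each local activation time is re-annotated
   beat-by-beat as `LAT* = Σ t·x(t)² / Σ x(t)²` over the envelope-gated
   activation segment, which stabilises annotations of fractionated and
   double-peaked complexes; success is measurable as a drop in the
   interval-sequence variance.

A seeded synthetic AF-electrogram generator with exact ground truth,
matching/error-rate metrics and a grid-search tuner support validation
without clinical data. The methods vignette
(`vignettes/activation-detection.Rmd`) documents the model, every default
and the open design choices.

## Worked example

```r
library(afdetect)

cfg <- synth_config(duration = 20, noise_sd = 0.01, seed = 42)
sr  <- generate_iegm(cfg)            # record + ground-truth activation times
res <- run_pipeline(sr$record, algo = "relen", truth = sr$truth)
print(res)
#> <afdetect_result> algo = relen
#>   raw: 87, corrected: 87, barycenter-annotated: 87 activations
#>   interval variance change: +7.8%
#>   raw        FN 2.25%  FP 0.00%  total 2.25%
#>   corrected  FN 2.25%  FP 0.00%  total 2.25%
#>   barycenter FN 2.25%  FP 0.00%  total 2.25%
```

The 20 s record contains 89 true activations; the detector finds 87 — the
two misses are "dropout" beats generated at near-zero amplitude, invisible
at any threshold — with no false positives. There being nothing removable
or recoverable, the correction stage is a fixed point here, and the
barycenter stage re-annotates every beat without changing the counts (the
interval variance rises slightly on this clean record because the peak and
barycenter annotations agree to within a sample for symmetric complexes).

Stage functions can be called individually: `relen_detect()`,
`amm_detect()`, `correct_sequence()`, `correct_annotations()`,
`match_detections()`, `error_rates()`, `grid_search()`. Records are read
with `read_record()` (CSV or WFDB format 16/212); annotations round-trip
through `write_annotations()`/`read_annotations()` (CSV/JSON). A thin
command-line wrapper lives at `inst/cli/afdetect.R`:

```sh
Rscript inst/cli/afdetect.R simulate --n 5 --seed 7 --out corpus/
Rscript inst/cli/afdetect.R detect --algo relen -i corpus/synth*.csv -o ann.json
Rscript inst/cli/afdetect.R evaluate -a ann.json -t corpus/synth*_truth.json
```

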