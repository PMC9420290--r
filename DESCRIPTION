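Package: afdetect
Title: Detection and Temporal Annotation of Atrial Activations in
    Intracardiac Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic detection and temporal annotation of atrial
    activations in single-channel bipolar intracardiac electrograms
    recorded during atrial fibrillation. Provides two raw detectors (a
    relative short/long-term energy enhancement detector and an adaptive
    grayscale mathematical-morphology detector with a five-fiducial
    structuring element), a post-processing stage that removes false
    detections and recovers missed activations using interval-statistics
    weight functions, and a beat-by-beat local-activation-time correction
    based on the energy barycenter of the activation complex. Includes a
    seeded synthetic electrogram generator with exact ground truth,
    detection-evaluation metrics, a grid-search parameter tuner, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
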