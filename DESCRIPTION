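Package: stocta
Title: Spatial-Temporal Speckle-Variance En-Face OCT Angiography
Version: 0.1.0
Authors@R:
    person("OCTA", "Maintainers", email = "octa@example.org", role = c("aut", "cre"))
Description: Converts high-density optical coherence tomography (OCT)
    intensity volumes into depth-resolved, vessel-enhanced angiograms using
    the spatial-temporal speckle-variance (ST-OCTA) approach: rigid bulk
    motion registration, frame compositing by mean or standard deviation,
    digital reslicing to the en-face view, and a six-step 2.5D enhancement
    pipeline (background RMS offset subtraction, Fourier bandpass with
    stripe suppression, Gaussian or 3D-median smoothing, oriented
    third-derivative-Gaussian ridge enhancement, median suppression, and
    rolling-ball background subtraction). Includes slab and color-coded
    depth projections, speckle-variance / phase-variance / complex
    differential variance baselines, SNR and CNR evaluation with
    ground-truth mask construction, a synthetic OCT phantom generator with
    known vessel and fiber ground truth, minimal multi-page TIFF
    interchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
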