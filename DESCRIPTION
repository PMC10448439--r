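Package: cnldeconv
Title: Cumulative Neutral Loss Model for MS2 Fragment Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Mass-domain deconvolution of electrospray-ionization
    high-resolution MS2 spectra of small molecules (<1000 Da). Builds a
    probabilistic cumulative neutral loss (CNL) occurrence model from a
    fragmentation spectral library (MSP/MGF): merged per-compound spectra
    are converted to CNLs on a fixed 0-1000 Da grid with 0.001 Da steps,
    true-positive and true-negative occurrence distributions are
    accumulated with Laplace (+1) smoothing, and candidate fragments are
    scored by the contrast of windowed TP and TN probability mass
    (score_CNL). Includes decoy-based evaluation (TPr/FPr/FDr/reduction
    rates, ROC grids over mass tolerance and score threshold), the two
    conventional time-domain baselines (extracted-ion-chromatogram peak
    shape correlation and apex retention-time difference) with
    signal-to-noise quality control, AND-combination of methods, and a
    synthetic spectral-library and chromatogram generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
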