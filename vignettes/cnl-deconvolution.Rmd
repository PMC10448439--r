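---
title: "Cumulative neutral loss deconvolution: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative neutral loss deconvolution: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cnldeconv)
```

## The model and its assumptions

A fragment of a precursor ion is characterized here by its cumulative
neutral loss (CNL), the precursor mass minus the fragment mass. Two
assumptions drive everything else:

1. **CNLs recur across compounds.** Fragmentation chemistry detaches a
   limited repertoire of neutral moieties (H2O, NH3, CO, CH4O, C2H4O2,
   ...), so the distribution of CNL masses over a compound library is
   heavy-tailed: a modest set of losses accounts for most observations.
   A candidate fragment whose CNL sits on a frequently observed loss is
   far more likely to be real than one whose CNL matches nothing.
2. **Absence is informative only below the precursor.** A CNL larger than
   the precursor mass is physically impossible, so only bins up to the
   precursor bin count as true-negative evidence for that compound.

The model is deliberately frequency-based and intensity-blind: every
recorded fragment counts once, regardless of abundance, and replicate
spectra are merged per compound (single-linkage at 0.001 Da, cluster mean
as representative) so a compound measured 50 times contributes no more than
one measured once.

Per compound, TP and TN binary vectors over the 1,000,001-bin grid are
summed, every bin gets one pseudo-count (Laplace smoothing — no CNL has
probability zero), and each vector is normalized by its own total, giving
the conditionals P(CNL|TP) and P(CNL|TN). Under a flat prior the class
posteriors are proportional to these conditionals, so classification can
work directly on them. A candidate CNL is scored by the normalized contrast
of the probability masses within ± one mass tolerance:

score = (ΣP(TP) − ΣP(TN)) / (ΣP(TP) + ΣP(TN)).

The form is chosen for three properties: it is bounded in [−1, 1], its
neutral point 0 marks "TP and TN evidence in balance", and it is monotone
in the evidence ratio. Acceptance is strict (`score > threshold`), so a
threshold of +1 accepts nothing and ties reject.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid | 0–1000, step 0.001 | Da | small-molecule range; bins match the merge width |
| bin_width (merge) | 0.001 | Da | replicate collapse window; not an uncertainty claim |
| tolerance | 0.005 | Da | window half-width; the best-separating cell in our ROC sweeps, and comfortably above the synthetic replicate jitter (sd 0.001) |
| threshold | 0.00 | — | the score's natural neutral point |
| mass_window (XIC) | 0.020 | Da | grouping window, i.e. ±0.010 tolerance |
| min_snr | 2 | — | XIC QC |
| min_consecutive | 3 | scans | XIC QC: run of scans above both cumulative means |
| corr_threshold | 0.57 | — | peak-shape correlation acceptance |
| tr_diff_threshold | 0.025 | min | apex retention-time acceptance |
| n_decoys | 200 | per spectrum | decoy evaluation density |

All of these live in `run_config()` (precedence: defaults < YAML file <
explicit arguments).

## Evaluation design

TP cases are taken from the **raw** spectra, one per (spectrum, fragment) —
not from the merged spectra the model is built on — so evaluation weight
follows measurement evidence while the model stays compound-balanced. TN
cases are uniform decoy masses on [50 Da, precursor], redrawn (up to 10,000
attempts) whenever they land within the active tolerance of any true
fragment of that compound across all its spectra; the exclusion tolerance
equals the scoring tolerance, so a "decoy" is never something the scorer
should accept by construction. Rates follow the usual definitions, in
percent: TPr = TP/(TP+FN), FPr = FP/(FP+TN), FDr = FP/(FP+TP) (reported as
missing when nothing is accepted), and the reduction rate is the rejected
share of all candidates. The ROC grid crosses seven tolerances (0.001,
0.005, 0.010, 0.020, 0.050, 0.100, 0.200 Da) with thresholds −1 to 1 in
0.01 steps; `select_optimum()` picks the Youden-maximal cell (TPr − FPr) as
a convenience — a documented choice, with the full grid remaining the
primary output.

## What the synthetic generator emulates — and what it does not

The generator exists so that every operation is testable with known ground
truth and no database download. Its design mirrors the statistical
structure of real libraries:

* **Precursors**: lognormal, median ≈ 300 Da, sdlog 0.35, truncated to
  [100, 1000] Da — small-molecule libraries cluster near 300 Da.
* **Vocabulary losses**: water/ammonia/methanol/C2H4O2 at per-compound
  frequencies 0.6/0.3/0.2/0.15.
* **Secondary losses**: five per compound. Crucially, these are drawn
  mostly (90%) from a *shared catalog* of 64 recurring loss masses
  (uniform on 12–250 Da, Zipf-like weights with exponent 0.5), with a 10%
  compound-unique uniform component. The shared catalog is what makes the
  generator faithful: in real chemistry even "compound-specific" losses
  recur across compounds, and an occurrence model can only ever recognize
  recurrence. A generator whose non-vocabulary losses were all unique
  would be adversarial by construction — unique losses are
  distributionally identical to uniform decoys, so no mass-domain score
  could separate them, which misrepresents what the method is for. With
  the catalog, every recurring loss is seen tens of times at the
  2,000-compound scale, and held-out libraries built from the *same*
  catalog (new compounds, same chemistry) separate cleanly: TPr ≈ 90%,
  FPr ≈ 4% at 0.005 Da / 0.00 in the acceptance runs.
* **Replicates**: 3 per compound with fragment m/z jitter sd 0.001 Da, so
  the 0.005 Da tolerance window is exercised realistically. Three is a
  desk-scale choice; real libraries average more replicates, which only
  sharpens the merge.
* **Chromatograms**: Gaussian elution profiles at a 6 Hz scan rate,
  half-normal baseline noise, and a centroiding-style intensity cutoff
  (3× the noise sd) under which points record as zero — this is why a
  noise-only m/z channel appears as a sparse, spiky trace and fails the
  consecutive-scan QC rule, as in real centroided data.

Not emulated: matrix effects, adducts, isotope envelopes, concentration
series, intensity structure of fragments, and any precursor-dependence of
loss propensities. Passing tests on this generator therefore show that the
implementation recovers recurrence structure it was given; they do not
certify performance numbers on any real library.

## Numerical choices

* **Bin assignment** is nearest-bin rounding; bin centres sit at exact
  multiples of 0.001 Da. Window membership is closed-interval on bin
  centres with a 10⁻⁶-bin guard against float rounding, so 18 ± 0.010 Da
  is exactly the 21 bins 17.990–18.010.
* **Window sums** are direct sums over the bin slice (no cumulative-sum
  shortcut), so they agree bit-for-bit with an all-bin scan.
* **Counts** accumulate streamingly: per-spectrum bin indices are pooled
  and tabulated once, and TN counts come from precursor-bin coverage
  (a reversed cumulative sum) minus the TP counts — peak memory is a few
  grid-length vectors regardless of library size.
* **S/N estimate** (the literature rarely defines one): noise = median
  intensity of the lowest-50% points of the trace; infinite S/N when that
  median is zero but signal exists.
* **Degenerate inputs**: zero-variance traces get correlation 0 (reject);
  apex ties break to the earliest scan; fragments above the precursor are
  rejected outright with score −1; an empty candidate list yields an empty
  table, not an error.
* **Model files** are versioned RDS containers; loading verifies the
  format version and round trips are bit-exact.

## Problem sizes

The test suite and the acceptance script run the full workflow at a
2,000-compound training scale (6,000 spectra) with 400 held-out compounds,
8 decoys per held-out spectrum for the operating-point rates, and 150
simulated chromatograms for the time-domain comparison. These sizes give
stable rates (binomial noise on TPr at ~7,000 TP cases is ±1%) while
keeping a full run in well under a minute on one core.

## Known limitations

* The model is precursor-agnostic: P(CNL|TP) is pooled over all compounds,
  so a loss that is plausible overall is accepted for any precursor. A
  precursor-conditional model needs far more data per precursor mass.
* High-CNL bins are reachable by few compounds, so their TN evidence is
  thin and the score drifts positive: false discoveries concentrate at
  high CNL mass (the stratified rates show FDr rising with CNL range).
* Only the positive-ionization defaults ship; the machinery is
  mode-agnostic but negative-mode defaults are untested here.
* AND is the only method combination: it reproduces the monotone
  TPr-drop/reduction-rise behaviour of stacking filters, and OR-style
  rescue logic is out of scope.
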