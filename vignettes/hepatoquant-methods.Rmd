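---
title: "Methods: phasor-based steatosis quantification and cIEF isoform profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor-based steatosis quantification and cIEF isoform profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatoquant)
```

# Overview

hepatoquant quantifies hepatic steatosis and protein PTM isoform profiles
from two label-free measurement modalities:

1. **Hyperspectral SRS imaging.** A stimulated Raman scattering microscope
   scans the C–H stretch region and records, at every pixel, a Raman
   spectrum across wavenumber channels. In liver tissue three chemical
   classes dominate this window: lipid (CH~2~ stretch, ~2850 cm^-1^),
   protein (CH~3~ stretch, ~2930 cm^-1^) and DNA (~2960 cm^-1^). The
   package segments each stack into these classes by spectral phasor
   analysis and computes percentage steatosis and lipid droplet
   morphometry.
2. **cIEF immunoassays.** Capillary isoelectric focusing separates the
   charge isoforms of one protein along a pH gradient; chemiluminescence
   detection yields an electropherogram whose peaks are the unmodified,
   phospho-, acetyl- and glycosyl-isoforms. The package fits the peaks,
   assigns PTM identity from the pI shift and reports relative
   concentrations as AUC ratios.

Because human biopsies cannot ship with a package, a synthetic-data module
generates ground-truthed phantoms for both modalities; every downstream
stage is tested against that ground truth.

# Spectral phasor segmentation

## The transform

For a pixel spectrum $I_k$, $k = 0, \dots, N-1$, the first-harmonic
spectral phasor is

$$ g = \frac{\sum_k I_k \cos(2\pi k / N)}{\sum_k I_k}, \qquad
   s = \frac{\sum_k I_k \sin(2\pi k / N)}{\sum_k I_k}. $$

This is the standard normalized-DFT form of the spectral phasor; any
nonnegative spectrum maps into the closed unit disc, and the map is
invariant to global intensity scaling, so chemically identical pixels of
different brightness coincide. Pixels with non-positive total intensity
are flagged and parked at the origin rather than dividing by zero.

## Gating

Pure-class spectra map to fixed phasor points, so classes form clusters
in the (g, s) plane. The package automates the conventional manual gating
deterministically: `default_gates()` places a regular hexagon (circumradius
0.12 phasor units by default) around each reference spectrum's phasor
point, and refuses to build gates whose centers are closer than twice the
radius — in that case hand-drawn polygon gates (JSON, `read_gates()`)
should be used, mirroring manual practice. Point-in-polygon membership
uses the even-odd rule with boundary points counted inside; gate order is
irrelevant because gates must be pairwise disjoint (checked by vertex
containment plus edge intersection). With the default references the
three cluster centers are separated by 0.58–1.34 phasor units, so the
0.12 hexagons are comfortably disjoint and, at the default 5% noise,
segmentation agreement with ground truth exceeds 99%.

## Steatosis statistic and morphometry

Percentage steatosis is the lipid SRS signal as a fraction of the
combined lipid + protein + DNA signal, times 100. It is
intensity-weighted (sums of per-pixel total intensity over class members)
because SRS intensity is proportional to bond concentration; a
pixel-count variant exists behind `weighting = "pixel"` for comparison.
Unassigned signal is excluded from the denominator.

Droplets are 8-connected components of the lipid mask. The equivalent
circular diameter is $d = p \cdot 2\sqrt{A/\pi}$ for area $A$ px and pixel
size $p$; components below 1 µm equivalent diameter are classed
microvesicular, the rest macrovesicular. Border-touching components are
kept. Connected component labeling is done on the pixel adjacency graph
(igraph), which gives true 8-connectivity.

# The tissue phantom generator

Each phantom frame emulates one hyperspectral SRS field of liver tissue:

- **Geometry.** Protein-class cytoplasm everywhere; lipid droplets are
  discs with diameters drawn from a truncated log-normal law; DNA-class
  nuclei (8 ± 1 µm discs, ~2 per 100×100 px tile) are placed only where
  no lipid lies, so crowded macrovesicular frames carry fewer in-plane
  nuclei — the same displacement effect seen in real macrovesicular
  steatosis.
- **Spectra.** Every pixel's noiseless spectrum is its class amplitude
  times the class reference spectrum (Gaussian mixtures peak-normalized
  to 1: lipid 2850 cm^-1^ with a 2930 shoulder, protein 2930, DNA
  2960 with a 2930 shoulder; the shoulders create realistic phasor
  overlap while keeping each class argmax at its cluster center).
  Additive Gaussian noise with SD equal to 5% of the mean signal models
  lock-in detection noise; shot noise is omitted.
- **Ground-truth lipid fraction.** Droplets are placed until the lipid
  share of total signal reaches the target at the default amplitudes;
  the lipid amplitude is then solved analytically so the realized
  noiseless fraction equals the target exactly. Solving the amplitude
  rather than iterating placement further makes the ground truth exact
  (machine precision) instead of approximate, which sharpens every
  recovery test; the amplitude adjustment is small because placement
  already stops near the target.
- **Modes.** `normal` mode uses a log-normal diameter law with median
  0.6 µm, log-SD 0.4, truncated at 2 µm (microvesicular: sub-micrometer
  droplets) and a default lipid signal fraction of 0.09. `nash` mode
  uses median 0.9 µm, log-SD 0.8, truncated at 50 µm and fraction 0.28.
  The NASH law was calibrated so that the *detected* mean droplet
  diameter — after rasterization and the merging of overlapping discs at
  28% fill — is about two-fold the normal-mode value, the group contrast
  the morphometry is meant to exhibit, while its heavy tail still spans
  sub-micrometer to tens of micrometers. The raw diameter laws differ by
  less than their detected means because sub-pixel droplets rasterize to
  a 1-pixel floor and dense fills merge.
- **Determinism.** A spec's seed fixes everything; identical specs give
  bit-identical stacks.

Default frame geometry is 400×400 px at 0.5 µm/px in the cohort design
(a 200 µm field, plausible for a 40× objective; the true field of view of
the instrument is not part of the data model), with a 40-channel axis
from 2800 cm^-1^ in 5 cm^-1^ steps. The instrument's stated scan range
(2800–3050 cm^-1^) and its stated frame count (40 at 5 cm^-1^) are
mutually inconsistent by 11 channels; the axis is configurable and the
package defaults to 40 channels (2800–2995 cm^-1^), which covers all
three cluster centers.

What the phantom does *not* emulate: partial-volume (mixed-class) pixels,
spatially correlated noise, cross-phase-modulation backgrounds,
out-of-focus light and tissue autofluorescence. Passing recovery tests on
phantoms therefore demonstrates the correctness of the pipeline's
arithmetic and geometry, not robustness to every real-tissue artifact;
on real stacks the gating step is the place where judgment (manual gates)
enters.

# cIEF electropherogram analysis

## Model

A trace is modeled as a sum of Gaussian isoform peaks on a flat baseline:
peak area is proportional to isoform concentration (equal antibody
affinity across isoforms), peak width defaults to 0.05 pH units on a
pH 5–8 axis sampled at 601 points. pI-shift conventions: phospho and
acetyl isoforms shift to lower pI (defaults −0.15 and −0.50), acetyl much
farther than phospho; glycosyl isoforms shift to higher pI (+0.30).

## Pipeline and numerical choices

1. **Normalize** to unit peak intensity (`normalize_trace()`).
2. **Baseline** removal by a centered rolling minimum (window ≈ 1/12 of
   the trace, wide relative to peak support) smoothed by a rolling mean;
   a linear lower-envelope fit is available for tilted baselines. A flat
   trace maps to ~0, and a Gaussian on a constant offset $c$ is recovered
   within 5% of $c$.
3. **Peak detection** on a lightly smoothed copy (moving average,
   half-width ≈ n/300 points). Smoothing matters: at 3σ separation the
   valley between two peaks has small prominence, and unsmoothed
   detection intermittently loses the smaller shoulder to noise. The
   smoothed trace is used only to seed the fit.
4. **Mixture refinement** by Levenberg–Marquardt nonlinear least squares
   (minpack.lm), one Gaussian per candidate, with nonnegative heights and
   widths bounded to the axis; components whose fitted height falls below
   the prominence threshold (5% of the maximum) are dropped. AUC is taken
   from the fitted components ($h\sigma\sqrt{2\pi}$), not raw
   integration, so overlapping peaks are decomposed; raw trapezoid
   integration remains available for parity checks.
5. **Assignment** by shift from the unmodified pI: |shift| < 0.05 →
   unmodified; shift ≤ −0.35 → acetyl; in between (negative) → phospho;
   shift ≥ +0.05 → glycosyl. Thresholds are configurable per protein.
   When the unmodified pI is not supplied it is inferred as the
   highest-pI major peak (≥25% of the tallest height) — supply the
   nominal pI when strong glycosyl peaks are expected.
6. **Relative concentrations** are per-class AUC sums over total AUC and
   sum to 1 by construction.

On noiseless traces with ≥3σ peak separation the full pipeline recovers
ground-truth concentrations within 1% absolute; at the default 1% noise,
four replicates reproduce the phospho concentration with CV ≈ 0.01–0.03,
well inside the 0.1 fidelity bound used for replicate QC.

The λ-phosphatase operator (`apply_phosphatase()`) moves phospho
concentration to the unmodified isoform (complete dephosphorylation by
default; `efficiency` scales it), conserving the total exactly. The
phosphatase-sensitivity score is the phospho concentration lost between
untreated and treated profiles, with a 0.1 call threshold.

# Cohort level

`generate_cohort()` writes a full synthetic study: per sample, three
frames and four cIEF replicates of each of six panel proteins whose
normal/NASH compositions carry the qualitative effect directions of the
disease (phospho-AKT up in NASH; phospho-4EBP1, -BID, -HMGCS2, -FABP1
down; FABP5 shifted to acetyl). The panel's nominal pI values and
composition numbers are synthetic choices, not measured values.
Between-sample variability: lipid-fraction jitter SD 0.02 and log-scale
isoform jitter SD 0.15, both chosen to resemble biological scatter
without overwhelming the group effects.

`differential_analysis()` applies a two-tailed paired Student's t-test
per protein×isoform with pairing by sample index and significance at
p ≤ 0.05. Pairing unrelated donors by index is statistically debatable —
the cross-donor "pairs" share nothing — so an unpaired Welch alternative
sits behind `paired = FALSE`; the paired test remains the default because
it is the study design being reproduced. No multiple-testing correction
is applied by default (matching the original analysis); `adjust = "BH"`
enables Benjamini–Hochberg. The ratio heat map plots log₂(NASH/normal)
for symmetry; raw ratios are preserved in the CSV twins, which carry the
exact numbers for every figure.

# Problem sizes and verification scale

The test suite and the acceptance script run the full pipeline at
200×200 px × 40 channels with 3 frames per sample and 9 samples per
group (1.08 million analyzed pixels per group), and 96–120 px frames for
unit-level checks; these sizes give stable group statistics while
keeping a complete run in the low minutes on one core. Recovery accuracy
is size-stable: the percentage-steatosis estimator is exact up to gating
error, which the phantom's pure-class pixels keep below 1% even at 5%
noise.

# Known limitations

- Phantom pixels are single-class; partial-volume mixing (a real effect
  at droplet boundaries) is not modeled, which flatters segmentation
  accuracy relative to real tissue.
- Droplet *counts* on dense frames are biased low by merging; diameter
  contrasts remain interpretable because both groups are processed
  identically.
- The cIEF peak model is Gaussian; strongly tailed or saturated peaks
  would need an asymmetric model.
- Nominal pI values, shift magnitudes and panel compositions are
  synthetic placeholders with correct directions, not calibrated to any
  instrument.
- The paired t-test follows the study design it reproduces; for general
  use the Welch option is the statistically safer default.
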