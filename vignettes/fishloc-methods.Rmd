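---
title: "Measuring chromatin compaction and nuclear position from dual-colour 3D FISH"
author: "fishloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromatin compaction and nuclear position from dual-colour 3D FISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fishloc)
```

## The two measurements

Dual-colour DNA FISH labels two fosmid probes (each ~40 kb) flanking a locus
of interest, one with digoxigenin and one with biotin, in fixed tissue
sections imaged as three-channel 3D stacks (DAPI counterstain plus the two
probe channels). `fishloc` extracts two per-nucleus quantities from such
stacks:

* **Squared inter-probe distance, d² (µm²).** The Euclidean distance d
  between the two probe centroids is squared because in interphase nuclei
  the *mean* squared physical distance between two genomic points grows
  linearly with their genomic separation. At a fixed separation, a smaller
  mean d² therefore reads out locally more compact chromatin, and d² can be
  compared across tissue regions or signalling conditions without modelling
  the full polymer.

* **Fractional radius, f (dimensionless).** Nuclear position of the locus,
  measured in 2D in the z-slice where the position probe (the
  biotin-labelled probe) is in sharpest focus: f = e / R, where e is the
  shortest distance from the probe centroid to the nuclear boundary and R is
  half the broadest distance across the nuclear cross-section (the maximum
  Feret diameter, halved). f = 0 is the nuclear periphery; f = 1 is
  reachable only at the centre of a circular section. The metric is
  deliberately 2D: tissue nuclei are too irregular for reliable 3D nuclear
  segmentation, so position is scored in the section where both the signal
  and the nuclear edge are in focus.

A note on orientation: dividing *edge distance by radius* (used here) maps
the periphery to 0 and the centre to 1. The inverse ratio would exceed 1
everywhere except the centre and compresses peripheral positions, and only
the chosen orientation matches reading radial distributions "with respect to
the nuclear edge". Because R varies between nuclei, the two orientations are
not monotone transforms of each other across a sample, so the choice
matters; it is fixed here and surfaced in the documentation rather than
configurable silently.

## The generative model behind the synthetic cohorts

No public image data accompany this kind of measurement, so the package
ships a generator whose ground truth exercises every stage of the analysis.

**Chain model.** The displacement between the two probe centroids is
isotropic Gaussian with per-axis variance c·g/3, the minimal model
satisfying E[d²] = c·g for compaction coefficient c (µm²/kb) and genomic
separation g (kb). Defaults around c ≈ 0.0008–0.0016 µm²/kb and
g = 60–120 kb give d in the 0.2–0.45 µm range typical of fosmid pairs
flanking a gene. d² then follows a scaled chi-squared(3) law — strongly
right-skewed, which is why the comparison layer is nonparametric.

**Radial placement.** The fractional radius of the *position probe* is drawn
either from a Beta(a, b) family (flexible, fits empirical radial
distributions) or from the `uniform_volume` law P(f ≤ x) = 1 − (1 − x)³ of a
point uniform in a sphere, which serves as a closed-form oracle in recovery
tests. The probe is placed in the nuclear mid-plane at in-slice fractional
position f, and probe A attaches to it via the chain displacement. Two
design points deserve emphasis:

* The sampled f is imposed on the *measured* quantity — the position probe's
  in-slice fractional radius — not on a 3D radial coordinate. A point placed
  uniformly in a sphere in 3D has an in-slice fractional radius following
  1 − (1 − x)², not the cubic law, so generator and measurement must agree
  on the 2D definition for recovery tests to be meaningful.
* Placing the position probe (rather than the pair midpoint) at f keeps
  placement feasible arbitrarily close to the boundary: a midpoint on the
  boundary cannot host a symmetric straddle, and at realistic separations a
  few per cent of uniform-volume placements would be geometrically
  impossible. With probe-anchored placement, only the second probe is
  boundary-checked, and displacement resampling (up to 100 retries, rate
  logged per nucleus) always terminates. The residual truncation bias
  compresses mean d² by a few per cent at the largest separations in the
  smallest nuclei; the recovery tolerances account for this.

**Nuclei.** Ellipsoids with independent semi-axes (default mean
1.6 × 2.2 × 1.8 µm, ~10% CV, random orientation about the optical axis),
emulating the non-spherical nuclei of tissue sections, tiled on a
non-overlapping grid, one stack per embryo × region.

**Imaging.** Probe spots are rendered as anisotropic 3D Gaussians
(diffraction-limited approximation), the DAPI channel as smooth-edged
ellipsoid interiors, on a uniform background with additive Gaussian noise
and a hard zero clip. Per-channel lateral chromatic shifts can be applied
(by offsetting rendered spot positions — over a uniform background this is
identical to translating the channel) and are corrected downstream by
`alignChannels()` with the recorded predetermined shifts, mirroring
bead-calibrated channel alignment. The default `imagingModel()` is SIM-like
(voxels 0.125 × 0.04 × 0.04 µm, spot σ ≈ 1.5 voxels per axis); cohort-scale
validation uses a coarser documented model (0.25 × 0.1 × 0.1 µm, same
σ-to-voxel ratio) so that hundreds of nuclei render in seconds. Spot σ
should stay ≥ ~1.2 voxels per axis: undersampled spots localise poorly
regardless of SNR.

What the generator does **not** emulate: photon (Poisson) statistics, SIM
reconstruction artefacts, autofluorescence structure, overlapping or mitotic
nuclei, chromatin polymer physics beyond the Gaussian chain, and probe-size
effects (probes are points). Passing recovery tests therefore demonstrates
that the *analysis chain* is faithful, not that real images of this kind
will be this clean.

## Segmentation choices

* **Otsu per ROI.** The threshold maximising between-class variance is
  computed on a 256-bin histogram of each ROI subvolume separately, because
  background varies across tissue sections. Plateaus of equally good cuts
  (common when bins are empty) resolve to the floored plateau midpoint.
* **ROIs are tight around the signals.** ROIs are expected to be drawn (or
  generated) closely around the hybridisation signal pair, as when they are
  placed by hand. This matters quantitatively: plain Otsu fails when the
  spot occupies less than roughly 2% of the ROI at low SNR, because
  splitting the background noise distribution then yields more between-class
  variance than isolating the spot. With tight ROIs, centroids are recovered
  to well under 0.3 voxel per axis down to SNR
  (amplitude − background)/noise ≈ 10.
* **Connectivity and component choice.** 26-connectivity for 3D spot
  foreground, 4-connectivity for 2D nuclear masks. Among surviving spot
  components the one with the greatest *integrated* intensity is kept,
  which is robust when a clipped second signal enters the ROI corner. For
  nuclear masks the component containing the probe is preferred (falling
  back to the largest), since the expanded DAPI window can include
  neighbouring nuclei.
* **Centroids** are intensity-weighted means of voxel positions (sub-voxel;
  a binary mode exists for sensitivity analysis), converted to µm with the
  anisotropic voxel sizes; distances are computed in µm, so z-anisotropy is
  handled once, at calibration.
* **Sharp-focus proxy.** The nuclear cross-section is segmented in the
  z-slice containing the position probe's centroid — an automated stand-in
  for the manual "signal and nuclear edge in sharp focus" criterion, which
  cannot be reproduced verbatim.
* **Half-pixel boundary correction.** Contour vertices are pixel centres,
  about half a pixel inside the true nuclear edge, so e and R both receive
  a half-pixel outward correction; without it, f is biased peripherally by
  ~0.02–0.05 at the validation scales.
* **Non-convex sections** can give e > R (f > 1). Such records are flagged,
  never clamped: clamping would bias the radial distributions, and the
  flags let downstream analysis decide.

## The statistics layer

Unpaired contrasts use the Mann-Whitney U test (U = number of pairs with
x < y, plus half-counts for ties; reported folded as min(U, n₁n₂ − U));
paired explant designs aggregate each pair to its median per arm and use the
Wilcoxon signed-rank test, with the pooled Mann-Whitney reported alongside.
Exact p-values (full enumeration, two-sided as 2·min(P(≤ obs), P(≥ obs))
capped at 1) are used for tie-free samples with n₁ + n₂ ≤ 20 (signed-rank:
up to 15 non-zero untied differences); otherwise the normal approximation
with tie and continuity corrections, and each result records which method
produced it. No multiplicity correction is applied by default — contrasts
are reported the way figure-level tests conventionally are — with an
optional Holm mode for stricter workflows. Box summaries use full-range
whiskers (no outlier trimming) and type-7 (linear-interpolation) quartiles.

Because squaring is strictly monotone on non-negative distances, the
Mann-Whitney p-value is identical on d and d²; the suite checks this
exactly, so the choice of reporting scale cannot change any conclusion.

## Determinism and validation design

Every sampler takes an explicit seed and restores the session RNG; cohort
generation derives per-nucleus child seeds from the master seed, so a
configuration is a pure function from seed to bit-identical output files.

Validation problem sizes (chosen once as the package's study conditions):
the d²-law check regresses per-separation mean measured d² on
g ∈ {60, 80, 100, 120} kb at fixed c with 150 rendered nuclei per
separation (2000 per separation in the geometry-only variant), using
*common random numbers* across separations — the same seeds, hence
chain draws that scale deterministically with √g — so the regression tests
the linearity of the law rather than chi-squared sampling noise, whose
standard error at n = 150 would otherwise dominate a 4-point fit. Radial
recovery uses 500 rendered spheres against the cubic law and 5·10⁴
geometry-only draws. Error calibration uses 2000 null cohorts (type-I at
α = 0.05) and 500 cohorts per arm for power at the design scale of 50
nuclei per group with a two-fold compaction difference, with a same-c
control arm mirroring a control locus. All of these run in minutes on one
CPU.

## Known limitations

* The fractional-radius measurement inherits the 2D convention's
  ambiguities: sections through the nuclear poles have small cross-sections
  and noisy Feret estimates; records whose mask touches the analysis window
  are flagged.
* Plain per-ROI Otsu degrades for foreground fractions below ~2% (see
  above); very loose ROIs at low SNR are the known failure mode, reported
  as rejections rather than silently mis-localised spots.
* One probe pair per nucleus is assumed (as when ROIs are drawn around one
  signal pair); allele disambiguation and multi-spot tracking are out of
  scope.
* The Gaussian-chain model is a deliberately minimal stand-in: it encodes
  the linear mean-d² law and nothing else about chromatin.
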