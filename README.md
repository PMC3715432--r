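# fishloc

Quantification of higher-order chromatin organisation from dual-colour 3D
DNA FISH images of tissue sections.

## The problem

Two fosmid probes (~40 kb each) flanking a locus, labelled in different
colours and hybridised to fixed nuclei, give two diffraction-limited spots
per nucleus in a three-channel 3D stack (DAPI + two probe channels). From
these, two per-nucleus statistics describe how the locus is organised:

* **Chromatin compaction — squared inter-probe distance d² (µm²).** In
  interphase nuclei the mean squared physical distance between two genomic
  points is linear in their genomic separation g (kb): **E[d²] = c·g**,
  with c (µm²/kb) the local compaction coefficient. At fixed g, a smaller
  mean d² means more compact chromatin. d² distributions are strongly
  right-skewed, so groups are compared with nonparametric rank tests.

* **Nuclear position — fractional radius f.** In the z-slice where the
  biotin-labelled (position) probe is in sharp focus, **f = e / R**: e is
  the shortest distance from the probe centroid to the nuclear boundary and
  R is half the broadest distance across the nuclear cross-section (max
  Feret diameter / 2). f = 0 at the periphery, f = 1 at the centre of a
  circular section.

The analysis chain mirrors the established workflow for such data: nucleus
ROIs drawn tightly around the signal pairs; per-ROI Otsu thresholding;
26-connected components; intensity-weighted xyz centroids; channel
alignment with predetermined chromatic shifts; Mann-Whitney U tests between
tissue regions/conditions and paired Wilcoxon signed-rank tests for explant
pairs. Because raw imaging data of this kind are rarely deposited, the
package also contains a fully ground-truthed synthetic cohort generator
(Gaussian-chain displacement model, parameterised radial placement,
Gaussian-spot rendering with anisotropic voxels, noise and chromatic
shifts) so the entire pipeline can be exercised and validated end to end
with no external data.

## Worked example

Simulate a two-region cohort (a loosely packed "stem-zone-like" region,
c = 0.0008 µm²/kb, peripheral radial placement, versus a two-fold more
extended "neural-tube-like" region, c = 0.0016, central placement; 3
embryos × 20 nuclei per region; probes 65 kb apart), then segment, measure
and compare:

```r
library(fishloc)

cfg <- list(
  mode = "simulate", seed = 5, output_dir = "demo_out",
  imaging = list(voxel_size_um = c(0.25, 0.1, 0.1),
                 psf_sigma_um  = c(0.4, 0.15, 0.15)),
  simulate = list(
    regions = list(
      list(region = "stem_zone",   compaction = 0.0008, genomic_sep_kb = 65,
           radial = list(family = "beta", shape1 = 2, shape2 = 6)),
      list(region = "neural_tube", compaction = 0.0016, genomic_sep_kb = 65,
           radial = list(family = "beta", shape1 = 3, shape2 = 3))),
    n_embryos = 3, n_nuclei = 20),
  plan = list(
    list(metric = "d2_um2",      group_a = "stem_zone", group_b = "neural_tube"),
    list(metric = "frac_radius", group_a = "stem_zone", group_b = "neural_tube")))

res <- runPipeline(cfg)
head(res$measurements[, c("nucleus_id", "region", "d_um", "d2_um2", "frac_radius")])
#>                       nucleus_id    region      d_um     d2_um2 frac_radius
#>  stem-zone_control_embryo01_n001 stem_zone 0.2959613 0.08759312  0.03036872
#>  stem-zone_control_embryo01_n002 stem_zone 0.2117043 0.04481872  0.28400057
#>  stem-zone_control_embryo01_n003 stem_zone 0.1480768 0.02192673  0.20141417
#>  stem-zone_control_embryo01_n004 stem_zone 0.2490594 0.06203058  0.20046492

res$report[, c("metric", "n1", "n2", "statistic", "p_value", "method",
               "median1", "median2")]
#>       metric n1 n2 statistic      p_value        method   median1   median2
#>       d2_um2 58 60      1076 3.547443e-04 normal_approx 0.0434234 0.0772579
#>  frac_radius 58 60       518 4.852840e-11 normal_approx 0.2003827 0.4475668
```

Reading the output: of 120 ROIs, 118 yielded measurements (2 rejections are
logged with reasons in `rejections.csv` and reconciled in `manifest.json`).
The median d² roughly doubles between the regions (0.043 → 0.077 µm²,
matching the two-fold compaction difference built into the simulation), and
the median fractional radius shifts from peripheral (0.20) to central
(0.45); both Mann-Whitney contrasts are significant, with the folded U
statistic and the p-value method (exact vs normal approximation) reported
per row. `plotGroupBox(res$measurements)` and
`plotRadialDistribution(res$measurements)` draw the box plots (full-range
whiskers) and radial-distribution curves.

The same configuration with `mode: analyse` and a `paths:` block (stack
directory, ROI CSV, fosmid BED) runs the identical chain on stacks read
from disk; `inst/scripts/fishloc.R` wraps the four verbs
(`simulate`, `analyse`, `compare`, `validate`) for shell use.

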