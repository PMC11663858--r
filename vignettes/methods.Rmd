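---
title: "Quantifying adipogenic differentiation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipogenic differentiation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## The measurement problem

Mesenchymal stem cells (MSCs) differentiating into adipocytes accumulate
neutral-lipid droplets. Given multichannel images of a confluent monolayer —
DAPI (nuclei), Nile Red red (total lipids, whole-cell signal), Nile Red green
(non-polar lipids, droplet signal), GFP (transgene reporter) and a
transmitted-light RGB Oil Red O (ORO) image — the quantities of interest are:

1. the percentage of cells that contain lipid droplets (the
   differentiated-cell fraction), per well and per condition;
2. in lentiviral rescue experiments, the number of *double-positive* cells:
   transduced (GFP above a gate) **and** lipid-laden (ORO-positive);
3. ratios ("fold changes") of those percentages between conditions, and group
   statistics over replicate wells.

`adipoquant` implements this chain with deterministic classical image
operations, so that every number is reproducible bit-for-bit from a
configuration and a seed.

## The analysis model

**Nile Red workflow.** Cells are bright in the total-lipid (red) channel, so
instances are segmented there: global Otsu threshold, hole filling, removal
of components below `min_area` (default 30 px, debris), then instance
splitting by watershed on the Gaussian-smoothed distance transform of the
foreground (smoothing sigma 2 px, watershed tolerance 2; both suppress
spurious splits caused by boundary roughness). Droplets are segmented in the
green channel by a plain intensity threshold, `green >= t`, with components
below `min_droplet_area` (default 4 px) removed. The threshold is an explicit
value, echoed in all outputs, and the batch pipeline derives it once (Otsu on
the first well) and reuses the same value across all wells of an experiment,
mirroring the practice of choosing one droplet threshold per staining batch.
A cell "has droplets" when its region overlaps the droplet mask by at least
`droplet_overlap_min` pixels (default 1 — pure intersection semantics). The
differentiated fraction is `100 * n_pos / n_total`, reported to one decimal.

**Rescue workflow.** Nuclei are detected in the DAPI image as bright spots:
Gaussian smoothing (sigma 2 px), Otsu threshold on the smoothed image, local
maxima with a minimum separation (`min_distance`, default 8 px), plateaus
collapsed to centroids, peaks thinned strongest-first with scan-order
tie-breaking. The monolayer is then partitioned among the nucleus seeds by
seeded region growing (`EBImage::propagate`), either by pure geometric
distance or steered by a support image. The GFP channel is normalized by
auto-contrast — a linear rescaling mapping the brightest pixel to 255, kept
in floating point — and the ORO image is converted to the per-pixel ratio
`R / (G + B)`. Per cell, the maxima of both images over the cell's pixels are
recorded; a cell is GFP-positive when its maximum exceeds 127 (strictly, on
the float scale) and ORO-positive when its maximum ratio exceeds 1
(strictly). The four quadrant counts partition the population and are
visualized as a gated scatterplot.

**Edge cases fixed by decision.** In the ratio image, `0/0` is defined as 0
(no signal, negative) and `r/0` with `r > 0` as `Inf` (pure red is maximally
positive). Values exactly at a gate are negative (strict inequalities, as the
">" rules are stated). An all-zero channel passes through auto-contrast
unchanged, with a warning. Droplet thresholding uses `>=` so the threshold
value itself is inside the mask. Fold changes divide the two percentages and
round half away from zero to one decimal, reproducing the arithmetic used
when percentages are printed to one decimal. All coordinates are 1-based
`(row, col)` with the origin at the top-left, R's native convention.

**Statistics.** Group comparisons of percentages use the tie-corrected
Kruskal–Wallis test followed by Dunn's pairwise z-tests on mean ranks with
Holm adjustment; "multiple comparisons" procedures are often left unnamed in
reports, and Dunn + Holm is the conventional default after Kruskal–Wallis.
(No Dunn implementation ships with our dependency set, so the z-tests are
computed directly from the rank sums and verified in the tests against
manual rank arithmetic.) Factorial designs (cell type x medium) use two-way
ANOVA with type-II sums of squares via `car::Anova` — identical to the
classical decomposition for balanced data — with Tukey HSD post hoc tests.
When every observation is identical the Kruskal–Wallis statistic is defined
as H = 0, p = 1 (the tie-correction denominator vanishes; there is no
evidence of any effect). Relative expression uses the 2^-ddCt rule: per
sample, fold = 2^-(Ct_target - Ct_reference), normalized by the *arithmetic*
mean fold of the control group, so the control mean is exactly 1 — matching
the convention of "assuming as 1 the mean level of each transcript in the
control group". (Normalizing by subtracting the mean control dCt inside the
exponent would fix the geometric mean instead.) Dye-elution readouts divide
absorbance at 500 nm by protein content, with the Bradford standard curve
fitted by ordinary least squares on (concentration, absorbance) standards
(duplicates averaged) and inverted linearly for prediction.

## The synthetic-well generator

Real micrographs for this assay are rarely published with ground truth, so
the package ships a generator that emulates the study conditions and carries
a full per-cell truth table.

Cells are convex perturbed ellipses (base radius uniform in 10–16 px, two
low-order angular harmonics with amplitudes up to 0.12 and 0.10) around a
circular nucleus of radius 5 px. Centers are placed by dart throwing with a
minimum separation of `1.7 x mean cell radius` (about 22 px), which keeps
nuclei disjoint while letting neighboring cell bodies touch, as in a
confluent monolayer; an impossible packing raises an explicit error rather
than silently truncating. Overlapping claims on a pixel are resolved by the
smallest normalized radial distance, so instance regions are disjoint by
construction.

A configured fraction of cells receives droplets: in the `"small"` regime
3–8 droplets of radius 2–4 px (the homogeneous small-droplet phenotype); in
`"large"`, one droplet of half the cell radius (the large-droplet
phenotype); `"mixed"` draws per cell. Droplet pixels are clipped to the
owning cell, and every droplet-bearing cell keeps at least one droplet
pixel. A configured fraction of cells (default 10%, the typical transduction
efficiency) is GFP-positive with uniformly bright cytoplasm; the
`gfp_suppresses_adipogenesis` flag reproduces the rescue scenario in which
transduced cells do not differentiate.

Channel intensities are flat foreground/background levels (8-bit defaults:
background 10, nuclei 200, cytoplasm 120 in the red channel, droplets 160
red / 180 green, GFP cytoplasm 220; 16-bit values scale by 257) plus
additive Gaussian noise (sd 5, clipped to the bit range). The ORO image uses
RGB triplets (200, 55, 55) on droplets and (170, 110, 100) elsewhere, so
before noise every droplet pixel satisfies `R/(G+B) > 1` and every other
pixel fails it; at the default noise level at least 99% of droplet pixels
remain positive. Densities and magnification are not tied to any particular
instrument: the defaults were chosen once as a realistic confluent-monolayer
geometry and are fully overridable.

What the generator does **not** model: point-spread blur, uneven
illumination, z-structure, cell debris, intensity gradients within cells, or
registration error between imaging stages (channels are perfectly aligned).
Tests passing on these images therefore validate the pipeline's logic and
its behavior under additive noise and touching cells — not robustness to
optical artifacts of any specific microscope.

## Design choices in the open

- **Classical segmenter in place of a learned one.** Commercial
  neural-network segmenters used for this assay are proprietary and cannot
  be redistributed; the lipid-red segmenter here is a deterministic
  threshold + distance-transform watershed with the same input/output
  contract (`LabelMask`), so a learned model can be swapped in without
  touching downstream code.
- **Watershed support.** Whether region growing should follow geometric
  distance or image intensity is left as an argument (`on =`); the default
  is distance. The rescue pipeline passes the GFP channel as an
  intensity support: boundaries between transduced and untransduced
  neighbors then follow the sharp GFP edge instead of cutting through
  bright cytoplasm, which measurably reduces spurious GFP-positive calls on
  touching cells.
- **Rescue foreground.** The rescue channels (DAPI/GFP/ORO) contain no
  cytoplasmic outline of untransduced cells, and the monolayer is confluent,
  so the default foreground is the entire image (a Voronoi-like partition
  among nuclei); a restricted mask can be supplied.
- **Edge cells are kept.** Nothing indicates edge-touching cells should be
  excluded; exclusion can be layered on by filtering the centroid table.
- **Field sampling.** The manual-counting estimator places rectangular
  fields uniformly at random (fields may overlap) and assigns cells by
  centroid, which avoids double counting; the pooled percentage over sampled
  cells is the estimate. With the field equal to the whole image it reduces
  exactly to the whole-well percentage.
- **Printed-percentage fold changes.** `fold_change()` operates on the
  one-decimal percentages as printed and rounds half away from zero; where
  published fold values disagree with the ratio of their own printed
  percentages, the computed ratio is reported rather than the printed one.

## Problem sizes and tolerances in the test-suite

The suite exercises the pipeline at the sizes the statistics demand, chosen
once: fraction-recovery runs use wells of 1,000 cells (1280 x 1280 px) at
true fractions 1–25%, five seeds per fraction, with a +/-1.5 percentage-point
band; rescue scoring uses 500-cell wells (1024 x 1024 px) with 10%
transduction and a 2%-of-cells error budget; oracle-equivalence checks run
100 random 64 x 64 instances against brute-force per-pixel loops (exact
equality); the Kruskal–Wallis null simulation uses 4 x 10 standard normals,
2,000 replicates, expecting a 5% +/- 1.5% rejection rate; determinism checks
compare pipeline outputs byte for byte. Numerical tolerances elsewhere are
exact or 1e-9 (auto-contrast idempotence).

## Known limitations

- Per-cell maxima are sensitive to single misassigned bright pixels at
  instance boundaries; the intensity-steered watershed mitigates but does
  not eliminate this on heavily touching cells.
- Otsu thresholding of the droplet channel remains well-behaved down to ~1%
  droplet-positive cells on the synthetic intensity model, but very sparse
  or low-contrast staining may require the manual per-experiment threshold
  (which the API treats as the first-class path).
- The statistics layer reproduces procedures, not published p-values: group
  sizes behind published significance claims are typically not recoverable.
- Repeated-measures designs (secretion time courses) are out of scope.
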