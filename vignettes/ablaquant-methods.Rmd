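---
title: "Methods behind ablaquant: field modelling, vascular morphometry and assay calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ablaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ablaquant packages the quantitative machinery of a sub-ablative
high-frequency irreversible electroporation (H-FIRE) study: predicting how
much of a tumor an electrode pair ablates, measuring vessels in stained
tissue sections, calibrating qPCR and ELISA readouts, and testing cohort
growth statistics. This vignette explains the models, the defaults, and the
choices made where the underlying procedures were interactive or
under-specified.

## The electric-field model

H-FIRE kills cells where the pulsed field magnitude exceeds a lethal
threshold (1077 V/cm for 4T1 cells in collagen constructs with the 2-5-2-5
waveform). Because the lethal dose is decided by the field distribution at
the nominal pulse amplitude, we model the stationary conduction problem

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with Dirichlet data $\pm V/2$ on the two needle surfaces and zero-flux outer
boundaries, instead of a time-dependent electromagnetic solve. The domain is
a box centred on the electrode midpoint, discretized on a regular lattice
(default step 0.1 mm) and solved by red-black successive over-relaxation on
the usual 5/7-point stencil to a relative residual of $10^{-6}$ (the worst
stencil defect in volts over the applied span); non-convergence within the
sweep cap is an error carrying the residual. $|E|$ comes from central
differences of $\varphi$ and is reported in V/cm.

Two numerical details matter:

* **Cut cells at the conductor surface.** Fixing all lattice cells inside
  the 0.4 mm needle radius overestimates the effective conductor radius by
  $O(h)$, which at $h = 0.1$ mm biases the whole field by roughly 15%.
  Cells whose stencil legs cross the true cylinder (or its end caps) use
  Shortley–Weller fractional-leg weights with the surface potential at the
  crossing point. With this, the 2-D solve agrees with the closed-form
  two-wire (bipolar coordinate) solution to better than 2% everywhere at
  least one electrode diameter from the conductor surface — the package's
  standing solver oracle.
* **Outer boundary in the oracle test.** An insulated finite box cannot
  reproduce the open-domain analytic solution near the walls, where the
  analytic field is wall-normal. The solver therefore also accepts Dirichlet
  outer data, and the oracle test pins the boundary to the analytic
  potential so that the comparison isolates interior discretization error.
  The default remains zero flux.

Default geometry is the in vivo configuration: 0.4 mm needles, 4 mm
spacing, 4 mm exposure, box extending three spacings beyond the midpoint on
every axis (24 mm), homogeneous conductivity. In a source-free homogeneous
problem the conductivity value cancels, so coverage predictions need no
tissue properties; a layered mode (sphere/slab/cylinder regions with user
conductivities, harmonic-mean face conductances) is available because
published tissue layer values vary and the study's own layer parameters are
cited rather than printed.

Coverage of a region is the fraction of its cells with $|E| \ge$ threshold
(cells exactly at threshold count as ablated). `coverage_curve()` exploits
linearity of the conduction problem: one solve at a reference voltage is
rescaled to every requested voltage-to-distance ratio, which the tests
verify against direct solves. `invert_threshold()` maps a measured lesion
area to the field magnitude whose superlevel set has that area — an order
statistic of the $|E|$ values, exact up to one grid quantile.

Reproducing the study's headline number — 23.32% coverage of a 142 mm³
spherical tumor at 600 V — with this homogeneous model gives about 19.3%
at the 0.1 mm grid (about 14 million unknowns, a few minutes on one CPU).
The deficit has the expected sign: the study's multilayer model surrounds
the tumor with less conductive fat and skin, which confines current and
raises the in-tumor field. We report the homogeneous number as-is rather
than fitting layer conductivities we do not know.

## Chromogenic IHC quantification

Brightfield CD31/podoplanin slides are separated into stains by classical
colour deconvolution: optical density $OD = -\log_{10}(I/I_0)$ per channel,
then per-pixel inversion of the stain matrix. The default vectors are the
published H-DAB pair with the residual direction completed orthogonally;
they are configurable per batch. On noiseless synthetic Beer–Lambert scenes
the round trip is exact to $10^{-6}$, which the tests assert.

Binarization uses the maximum-entropy criterion (Kapur–Sahoo–Wong), the
"Max Entropy" method of FIJI: the threshold maximizes the summed Shannon
entropies of the background and foreground histogram parts. We use 256 bins
over the observed range; the choice mirrors the 8-bit FIJI dialect while
remaining well-defined for float images. The implementation is checked
against an exhaustive scan on random images.

Area percent is positive pixels over ROI pixels; vessel density is
8-connected components per ROI area, attributing a component to an ROI by
centroid membership (the boundary-straddling rule the original macro leaves
unstated) and discarding components below 15 µm² — the same background
filter the lymph-node pipeline uses, applied here for consistency. ROI
polygons use 0-based pixel coordinates, shoelace areas, and point-in-polygon
with boundaries counted inside.

Picrosirius-red fibers under polarized light are classified by hue:
red-yellow = [330°, 70°), green = [70°, 170°), with saturation ≥ 0.2 and
value ≥ 0.1; all bands are configurable since no numeric bands are printed
anywhere we could adopt. Live/dead lesion area takes the dead-positive,
live-negative region's largest 8-connected component.

## The lymph-node dual-marker pipeline

The interactive whole-slide workflow is reproduced programmatically:

1. **Pixel features.** Gaussian-smoothed intensity plus Hessian
   determinant and extreme eigenvalues at scales 2 and 4 px of the 0.65
   µm/px image — eight feature planes.
2. **Pixel classifier.** A single-hidden-layer perceptron (5 hidden nodes,
   2 outputs) trained on a class-balanced pixel sample with a fixed seed.
   The original description ("3 layers, 3-5-2 nodes") conflicts with eight
   input features; we use input width 8, hidden 5, output 2 and record the
   discrepancy here.
3. **Segmentation.** Connected positive regions are traced to sub-pixel
   polygons by iso-contouring the lightly smoothed (σ = 1 px) component
   mask at 0.5. This matters for morphometry: pixel-edge perimeters of a
   digitized circle converge to the inflated discretized value (≈ π/2
   above the ideal), whereas sub-pixel contours land within 2% of
   $2\pi r$ at radius ≥ 10 px, so a single circular vessel scores a
   Vascular Complexity Index near 1, the analytic ideal.
4. **Object features and classification.** Per object: area, perimeter,
   circularity $4\pi A/P^2$, solidity, and intensity statistics on
   channels smoothed with a 2.0 µm Gaussian (our reading of the "ROI 2.0
   µm" measurements). Lymphatic vs blood classification is a seeded
   100-tree random forest over the seven features, standing in for
   interactive random-trees training; a deterministic fallback — LYVE-1
   mean above background + 2 SD — is always available and is what the
   reproducibility tests pin down. Interactive merge/split and
   low-intensity removal are replaced by polygon-overlap merging (≥ 50%
   of the smaller object) and a background + 2 SD CD31 cut.
5. **Filtering and summaries.** Objects below 15 µm² are removed (≥ keeps
   boundary cases, since the published description does not state
   strictness). Node summaries normalize per-class areas to the node area
   minus artifact areas.

The Vascular Complexity Index of a vessel set is
$(\sum_i P_i)^2 / (4\pi \sum_i A_i)$: 1 for one ideal circle, $4/\pi$ for a
square, $n$ for $n$ identical circles, scale- and rigid-motion-invariant,
and bounded below by 1 for any single convex object by the isoperimetric
inequality — all asserted in the tests.

## Assay calibration

qPCR uses per-plate absolute-relative quantification: a least-squares line
of Cq against $\log_{10}$(template) over the plate's seven standards (2000,
1000, 500, 250, 125, 61.25, 31.125 — the printed series, odd tail values
included). Efficiency is $10^{-1/\text{slope}} - 1$; a perfect doubling
gives slope $-1/\log_{10} 2 = -3.3219$. A fit with $R^2 \le 0.9$ is
unusable and `quantify_qpcr()` refuses it. Undetectable transcripts are
missing values, never zeros, and survive as `NA` through normalization to
the housekeeping (R18S) abundance.

ELISA uses the four-parameter logistic
$y = d + (a - d) / (1 + (x/c)^b)$ fitted by Levenberg–Marquardt from
heuristic starts (asymptotes from the extreme responses, $c$ from the
mid-response, Hill sign from the slope), with uniform weights by default
and optional $1/y^2$ weighting. Inversion is closed-form; signals at or
beyond the asymptotes are flagged rather than extrapolated. Concentrations
normalize to tissue as pg/ml × eluate ml / tissue mg.

## Cohort statistics

`percent_change()` and `predicted_treated_change()` encode the growth
bookkeeping: if controls grow by $c$% and treatment instantly removes a
fraction $f$, the surviving tissue grows at the control rate and the
treated arm changes by $100((1 + c/100)(1 - f) - 1)$ — with $c = 135$%
and $f = 0.2332$ this gives 80.2%, matching the treated-arm observation.
Group comparisons follow the study's workflow: optional $\log_{10}$
transform for variables declared lognormal (declared via argument, never
auto-detected — the original used QQ-plot judgment), unpaired t tests with
Welch's correction when the variance ratio exceeds 4 (the study's "unequal
standard deviations" is not operationalized, so we fixed a conventional
F-ratio rule), one-way ANOVA with Tukey's HSD beyond two groups, and
Pearson correlation with t-distribution p values. On 10,000 null lognormal
simulations the comparison path rejects at the nominal 5% within
Monte-Carlo error.

## Synthetic data: what it does and does not show

All generators are deterministic functions of their seed and return ground
truth alongside the rendered data:

* **IHC scenes** place non-overlapping annular vessel cross-sections
  (lognormal areas, median 80 µm², σ_log 0.5 — a plausible capillary
  range chosen once as a fixture, not an empirical claim) and render
  through the same Beer–Lambert model the deconvolution inverts, plus
  optional Gaussian noise.
* **Lymph-node fields** place filled circular vessels of both classes and
  sub-15 µm² debris inside a polygonal node.
* **Growth cohorts** use exponential growth (control day-1 increase 135%)
  with lognormal rate and measurement noise and an instantaneous treated-arm
  volume drop of 0.2332 at treatment — the study's anchor conditions.
* **Assay plates** draw Cq from a configured efficiency with σ = 0.2 cycle
  noise on the printed standard series, and absorbances from a configured
  4PL.
* **Live/dead images** threshold a field solution, closing the loop
  generator → lesion area → threshold inversion, which the tests require to
  return the generating threshold within grid tolerance.

Passing on these scenes demonstrates that the measurement machinery is
correct, not that it is robust to everything real slides do: the
generators model neither uneven illumination, stain variability,
out-of-focus tissue, touching vessels, nor segmentation-relevant texture.
The study's in vivo results (vessel-density time courses, chemokine
levels) are not reproducible from the publication at all — no raw images
or per-animal tables are deposited — so they are covered exclusively by
parameter recovery on these synthetic cohorts.

## Problem sizes and determinism

The test suite runs the 2-D solver oracle at 0.1 mm on a 24 mm box
(241² cells, sub-second) and the 3-D coverage reproduction at the default
0.1 mm grid (241³ ≈ 14 million cells, a few minutes); generator-based tests
use 256–400 px tiles. All randomized tests fix seeds; generators snapshot
and restore the caller's RNG state so library code never perturbs a user's
stream.
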