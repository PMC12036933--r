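---
title: "Soma morphometry and new-neuron quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soma morphometry and new-neuron quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamorph)
```

# The problem

Juvenile songbirds continuously add new neurons to the song nucleus HVC and
the auditory region NCM. A typical study of an experimental manipulation (here,
a statin given during juvenile development) quantifies two things from
immunolabeled brain sections: **how many** new neurons are present (densities
of birthdated BrdU+/Hu+ neurons and of immature DCX+ cells, region volumes,
extrapolated totals), and **what the neurons look like** (shape descriptors of
traced soma outlines for the new neurons and for the older, heterogeneous
Hu+ population that was largely born before treatment). The unit of analysis
throughout is the bird: cell-level measurements are averaged per bird before
any group statistics.

This package implements that pipeline — shape descriptors on closed 2D
contours, unbiased grid subsampling, Cavalieri stereology, and the
group-comparison battery — together with a hierarchical synthetic-study
generator that provides ground truth for calibration and recovery testing.

# Shape descriptors

A traced soma is a closed simple polygon with vertices in µm. From its area
$A$, perimeter $P$, and the maximum/minimum Feret diameters $F_{max}$ and
$F_{min}$ (caliper diameter and minimum width), five dimensionless
descriptors are computed:

* aspect ratio $= F_{min}/F_{max}$ — flatness; 1 for a circle, smaller for
  flatter somata;
* compactness $= \sqrt{4A/\pi}\,/\,F_{max}$ — 1 for a circle;
* roundness $= 4A/(\pi F_{max}^2)$ — the square of compactness, spreading out
  low-compactness contours;
* shape factor $= P/\sqrt{A}$ — large-scale boundary convolution; minimal
  ($2\sqrt{\pi} \approx 3.54$) for a circle;
* form factor $= 4\pi A/P^2$ — fine-scale boundary roughness; 1 for a circle.

Vendor manuals often print these formulas with radicals and exponents lost in
typesetting; the forms above are the unique dimensionless reconstructions
consistent with the standard circle anchors (compactness and form factor 1,
shape factor $2\sqrt{\pi}$) and with roundness $=$ compactness$^2$. Aspect
ratio is defined min/max so that its range is $(0, 1]$ and flatter means
smaller.

Numerical choices:

* Contours are stored *open* (implicit closing edge), counter-clockwise, with
  consecutive duplicates and a duplicated closing vertex dropped.
* Degenerate inputs (fewer than 3 distinct vertices, zero area) and
  self-intersecting outlines are **rejected, not repaired** — silent repair
  would bias the morphometrics. The simplicity test is a segment-pair
  intersection check with a sorted bounding-interval prefilter, so smooth
  tracings with thousands of vertices stay near-linear in cost.
* Feret diameters are computed on the convex hull (where both extremes are
  attained), raw polygon vertices as traced — no smoothing or spline
  interpolation is applied, since the tracing is the measurement. For typical
  hull sizes the exact vectorized hull sweep (all vertex pairs for the
  diameter; every edge's farthest vertex for the width) is used; hulls larger
  than `r somamorph:::.CALIPER_SWITCH` vertices switch to O(h) rotating
  calipers. Both paths are exact and are property-tested against brute-force
  oracles.

```{r anchors}
soma_metrics(regular_polygon(10000))
```

# Grid subsampling of the older population

Tracing every Hu+ neuron in a section is impractical, so the older population
is subsampled with a lattice of 100 µm × 100 µm squares laid over the region
tracing's bounding box, anchored at its top-left corner. "Every fourth
square" is implemented as a diagonal pattern — square $(c, r)$ is selected
when $(c-1)+(r-1) \equiv 0 \pmod 4$ — which samples ≈25% of squares without
the column-stripe artifacts of a fixed-offset stride. Within a selected
square the standard unbiased-counting-frame convention applies: a cell whose
contour crosses or touches the square's **top or left edge** (the forbidden
lines) is excluded; the right and bottom edges accept. The exclusion uses the
full traced contour, not just the marker point, because what touches a line
on the microscope is the visible cell body. A fixed-seed random-origin mode
exists for demonstrating unbiasedness: over many random grid placements the
sampled fraction of uniformly scattered points converges to the selected-
square fraction.

On very small grids the diagonal pattern deviates from 25% (a 1 × 5 grid
selects 2/5); region tracings in practice span many squares, where the
fraction stays within 0.2–0.3.

# Stereology

Densities are **pooled** per bird: total labeled cells across sections
divided by total outlined area across the same sections — not the mean of
per-section ratios, which would overweight small sections. Region volume is
the Cavalieri estimate $V = \sum_j A_j \times t \times k$ with section areas
$A_j$, thickness $t = 6$ µm, and sampling interval $k = 8$. Total cells per
region default to the dimensionally consistent conversion
$N = (D / t) \times V$ (areal density to volumetric density, then times
volume); a `"literal"` mode computes $D \times V$ directly for comparability
with reports that state that arithmetic. No Abercrombie or profile-count
correction is applied. The estimator is validated by planting known numbers
of cells in synthetic blocks (recovered within sampling error at interval 8)
and by slicing spheres of known volume (within 5%).

# Statistics

* **Independent t-tests** are pooled-variance Student tests
  ($df = n_1 + n_2 - 2$; 6 vs 7 birds gives $df = 11$). Pooling is a
  deliberate fidelity choice — the convention of the study design being
  emulated — and is stated prominently because group variances need not be
  equal; Welch would otherwise be the safer default.
* **Mixed 2 × 2 ANOVA** (between: treatment group; within: neuron population
  measured twice per bird) uses the classical error strata: group over the
  between-bird stratum, population and interaction over bird × population.
  Degenerate zero-variance data return $F = 0$ rather than 0/0. Post-hoc
  comparisons are paired t-tests within group.
* **Multiple testing**: the Benjamini–Hochberg step-up is applied within one
  family per population, defined as the eight size-and-shape measures (five
  dimensionless descriptors, area, both Feret diameters; perimeter is
  excluded as redundant with shape factor). Raw p-values are always retained
  alongside adjusted ones, since published reports do not always state which
  scale they print.
* **Covariate regressions**: ordinary least squares of each experimental
  covariate (age at treatment start, treatment duration, age at first BrdU,
  age at perfusion) on each density and bird-mean morphology outcome, with
  the two-tailed t-test on the slope. The full grid is emitted; under the
  null generator its rejection rate is the nominal level.

# The synthetic generator

Somata are radial Fourier ellipses:
$r(\theta) = r_e(\theta;\, q)\,\bigl(1 + \sum_k a_k \cos(k\theta + \phi_k)\bigr)$,
where $r_e$ is an ellipse with axis ratio $q$ and the harmonics fall in two
bands: $k \in [2, 6]$ (convolutions, raising shape factor) and
$k \in [12, 40]$ (roughness, lowering form factor). Amplitudes are Gaussian
draws scaled so each band's total RMS equals its amplitude parameter; phases
are uniform. Draws whose radius dips below 5% of the ellipse radius are
resampled (star-shapedness guarantees simplicity). Contours are rescaled to
the target area exactly. The band boundaries are conventions, not biological
facts, and are configurable. This model was chosen because the descriptor set
separates cleanly along its axes — axis ratio moves only the flatness
measures, the high-frequency band mostly the form factor, area only the size
measures — which is what makes direction-recovery testing interpretable.

The hierarchy mirrors the study design: group-level parameter means (shifted
by the declared effect in the treated group), a bird-level Gaussian random
effect, and per-cell jitter; traced-cell counts are clipped log-normals
matching the printed per-bird ranges (13–100, mean ≈ 40 for new neurons;
14–66, mean ≈ 38 for the older population). Counted markers are Poisson per
section at bird-varying densities identical across groups. Covariates are
drawn from the study's ranges: treatment start uniform on 18–49 d and
perfusion age uniform on 107–111 d (duration is their difference, 58–93 d —
slightly wider than the reported 62–92 d range, an accepted simplification);
first BrdU injection is 32 d before perfusion, so labeled cells are 30–32 d
old. All randomness flows from one master seed through named substreams
(`sub_seed`), so any component regenerates independently and byte-identically.

Default settings (chosen once as field-realistic magnitudes): new-neuron
target area 80 µm², older population 120 µm² (the older population is larger
within controls); baseline axis ratio 0.75; convolution amplitude 0.02;
roughness amplitude 0.01; bird-level SDs 0.03 (axis ratio), 0.08 (log area),
0.005 (amplitudes); cell-level jitter 0.08, 0.25, 0.01/0.005. The declared
study-direction effects are an aspect-ratio shift of −0.06 and a roughness
shift of +0.03 in new neurons, and a ×0.90 area factor in the older
population, with no density effect. The real study published only test
statistics, not per-bird effect sizes, so these declared effects are the
generator's ground truth, not estimates of the biological effect.

What the generator does *not* emulate: histological shrinkage, staining
artifacts, tracing error correlated with cell size, non-elliptical region
geometry, or mediolateral density gradients. Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is sound under its
assumed data-generating process, not that the biological findings replicate.

# Calibration and recovery testing

Two simulation suites close the loop:

* **Type-I calibration**: 2,000 studies under the null effect specification;
  the pooled t-test on bird-mean flatness rejects at 5% (±1.5% band). This
  suite runs at the parameter level (`gen_study_means`): bird means are drawn
  as group mean + bird random effect + mean of per-cell jitter, without
  rendering polygons. Descriptors are deterministic given parameters, so the
  bird-level sampling distribution the t-test sees is exactly the
  generator's; rendering 2,000 × ~1,000 polygons would add nothing but time.
* **Direction recovery**: 200 fully rendered studies (contours, markers,
  sections) under the declared effects; a study "recovers" when the signs of
  the statin−control bird-mean differences match for aspect ratio (down),
  shape factor (up) and form factor (down) in new neurons and area (down) in
  the older population, *and* the HVC new-neuron density test does not reject
  (the null-density finding). The acceptance bar is ≥80% joint recovery.

Problem sizes (full studies of 6 + 7 birds, ~40 traced cells per bird and
population, 10–12 sections per region) are the study's own conditions; the
simulation counts above are the package's declared test scale.

# Known limitations

* The pooled t-test inherits the equal-variance assumption; with 6 vs 7 birds
  a variance ratio of ~3 inflates the nominal level only mildly, but users
  comparing their own data should check spread.
* The grid rule treats 6 µm sections as 2D profiles (as the emulated design
  does); there is no optical disector or Z-exclusion plane, so over-counting
  of large somata across section boundaries is not corrected.
* `total_cells` in literal mode reproduces a dimensionally loose published
  arithmetic (cells·mm); the volumetric default is the defensible estimate.
* Validation of read studies requires markers strictly inside their section
  outline; points within ~0.005 µm of the boundary (the storage precision)
  may fall either side of the polygon test.
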