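---
title: "Linking thin-walled aneurysm regions to local haemodynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking thin-walled aneurysm regions to local haemodynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuwall)
```

## The problem

During microsurgical clipping, parts of an intracranial aneurysm dome can
appear red and translucent. These thin-walled regions are read by surgeons as
locally fragile, but they cannot be seen on preoperative imaging, so the
question of *what distinguishes their haemodynamic environment* matters for
rupture-risk assessment. `aneuwall` implements a reproducible version of the
analysis chain used to ask that question: segment the red regions in an
intraoperative photograph by colour distance, map them onto the 3D vessel
wall, summarise the time-resolved wall shear stress (WSS) field at matched
thin and normal sampling patches, and compare the two region types with a
mixed-effects model that respects the nesting of patches within patients.

Because the corresponding patient imaging and CFD data are not publicly
deposited, the package ships a first-class synthetic-data module that
generates cohorts with *known* injected effects. Every downstream stage is
validated by parameter recovery against that ground truth rather than against
irreproducible patient tables.

## Wall shear metrics

Given the tangential wall shear vector $\mathbf{w}(s,t)$ (Pa) at wall
location $s$ over one cardiac cycle of duration $T$, the package computes,
per mesh node:

* **TaWSS** $= \frac{1}{T}\int_0^T |\mathbf{w}(s,t)|\,dt$ (Pa);
* **OSI** $= \frac{1}{2}\left(1 -
  \frac{|\int_0^T \mathbf{w}\,dt|}{\int_0^T |\mathbf{w}|\,dt}\right)
  \in [0, 0.5]$, with 0 at nodes where the magnitude integral vanishes;
* **RRT** $= \big(\mathrm{TaWSS}\,(1 - 2\,\mathrm{OSI})\big)^{-1}$
  (Pa^-1^); the denominator is guarded at $10^{-9}$ and undefined nodes
  propagate as `NA`, never as clipped values;
* **WSSD** $= \partial_x w_x + \partial_y w_y + \partial_z w_z$ (Pa/mm);
* **WSS**: the instantaneous magnitude at systole, defined as the time index
  maximising the mesh-mean magnitude (ties resolve to the earliest instant);
* **Pressure**: the nodal pressure at that systolic instant (time average
  available as an option).

Quadrature is trapezoidal on the stored time grid. If a series spans two
cardiac cycles, only the second is summarised, mirroring the usual practice
of discarding the start-up transient. The printed form of the RRT definition
in the source literature has unbalanced parentheses; the implementation uses
the standard expression above, which is also the only reading consistent
with RRT's Pa^-1^ units.

### The discrete divergence and what it can estimate

WSSD is computed by a weighted least-squares linear fit over each node's
1-ring neighbourhood in ambient 3D coordinates (weights are inverse edge
lengths), followed by the trace of the fitted gradient. This estimator is
*exact* for fields that are linear in $(x, y, z)$, which is the basis of its
unit tests.

One genuine limitation deserves record. Surface samples carry no information
about how a field varies *normal* to the surface: for curved walls the
1-ring estimate of the normal-direction derivative is determined by the
quadratic sag of the ring and carries a curvature-coupled bias that does not
shrink under mesh refinement (it vanishes only for linear fields). The
ambient trace is therefore reported as-is — it is the quantity conventional
postprocessors extract — but `wssd(..., divergence = "surface")` additionally
offers the trace of the *tangent-projected* gradient. For tangential fields
(wall shear is tangential by definition) the projected trace is independent
of how the field is extended off the surface and converges to the analytic
surface divergence; the refinement test in the suite demonstrates first-order
convergence for that mode on a meridional test field. The default remains the
ambient trace so that linear-field exactness and conventional usage are
preserved.

## Delta E segmentation

Intraoperative images are converted from 8-bit sRGB to CIELAB (D65
illuminant). A user-selected reference region of clearly red wall is averaged
to a reference Lab triple, and each pixel's colour difference to that
reference is computed. The default formula is CIE76 — the Euclidean distance
in Lab, which is what the histogram-based tooling that popularised this
workflow computes — with CIEDE2000 available where perceptual uniformity at
small differences matters. Pixels with $\Delta E \le 10$ form the thin-wall
mask; the comparison is inclusive because the threshold is a bound on
acceptable colour deviation. The threshold is also reported as a percentage
of the observed map maximum (a threshold of 10 against a map spanning up to
80 is 12.5%), the bookkeeping that justifies carrying one absolute threshold
across cases. Pre-processing is restricted to manual-mask ROI exclusion and
an optional linear percentile stretch (1st–99th by default) inside the ROI;
both are deterministic and the identity settings leave the image untouched.

Colour matches on the parent vessel are *not* removed at segmentation time;
anatomical filtering belongs to the sampling stage, which excludes
parent-vessel nodes whatever the mask says.

## Regional sampling

The segmentation mask is projected onto the surface mesh through the known
camera: a node is provisionally thin if it is front-facing, unoccluded
(depth-buffer test with a half-pixel-footprint tolerance) and its projection
lands on a mask pixel. Parent-vessel nodes are forced to `excluded`; the
remaining dome nodes are `normal`.

Within each label, regions are eroded by a geodesic margin along the mesh
edge graph and centre points are chosen inside the eroded set to maximise
pairwise geodesic separation (exhaustive best pair, then farthest-point
additions; ties break to the lowest node index, making selection
deterministic). Around each centre, the `k = 10` nearest nodes by Euclidean
distance (centre included, ties again by index) contribute one row each to
the sample table, so the default design of 2 thin + 2 normal centres per
patient yields 40 rows per patient — 640 rows, 320 thin and 320 normal, for
a 16-patient cohort.

The erosion margin default is 1.0 mm. The margin has to do two jobs: keep
centres away from ambiguous label boundaries, and guarantee that the whole
10-node patch stays inside its label. On the synthetic meshes the node
spacing is ≈0.44 mm, so a 10-node patch reaches ≈0.75 mm from its centre; a
1.0 mm margin makes label leakage impossible, and the suite asserts exactly
that. On finer meshes (clinical CFD surface meshes are typically an order of
magnitude denser) a smaller margin is equally safe, and `margin_mm` is an
explicit argument. Real-data use can bypass algorithmic selection entirely by
supplying explicit centre coordinates to `extract_patch()`.

## The mixed model

For metric value $Y_{ij}$ of patient $i$ at region $j$:

$$Y_{ij} = \beta_0 + \beta_1\,\mathrm{RegionType}_{ij}
  + u_i + v_{ij} + \varepsilon_{ij},
  \qquad u_i \sim N(0, \sigma_P^2),\;
  v_{ij} \sim N(0, \sigma_R^2)$$

with random intercepts $u_i$ per patient and $v_{ij}$ per region nested
within patient ("model 2"). The alternative "model 1" replaces the nested
term with a two-level random intercept on region type and is kept for AIC
comparison. Fits use REML via `lmerTest`; the reference level is `normal`,
so $\beta_1$ is the thin-minus-normal difference; the 95% CI is Wald and the
p-value uses Satterthwaite degrees of freedom. Singular fits are reported,
not hidden; a genuine optimizer failure is an error carrying the optimizer
message.

Before fitting, metrics are transformed: `raw`, natural `log` (positive
columns only), or `patient_max` — dividing each signed value by that
patient's maximum of the metric over the *whole* model, parent vessel
included. OSI, already bounded and scaled, is always analysed raw, and the
transform machinery refuses anything else. For WSSD, which is signed, the
normalisation uses the signed patient maximum; this reproduces the
convention in which normalised WSSD can carry a negative intercept, and the
signed-versus-absolute choice is isolated in one place should a user prefer
the alternative. On the patient-max scale $\beta_1$ reads directly as a
fraction of the patient-specific maximum, and `summarize_effects()` reports
it as a percentage together with the implied thin-region mean
$\beta_0 + \beta_1$.

AIC comparison across transforms follows the applied convention of comparing
fits on differently scaled responses of the same rows; `compare_models_aic()`
only enforces equal row counts. Note one statistical subtlety validated in
the tests: on data with no region-level variance, the richer nested model's
REML likelihood can exceed the patient-only fit's by more than the +2 AIC
penalty in a minority of replicates (the boundary likelihood-ratio is
chi-bar-square distributed), so "the useless component never wins" holds in
the median, not per dataset.

## The synthetic generator

`simulate_cohort()` emulates the study conditions: 16 patients; triangulated
aneurysm geometry (spherical dome of radius 2.5 mm over a 1.5 mm-radius
parent vessel, built as a jittered surface of revolution so the dome and
vessel share the neck ring and the mesh is edge-connected by construction);
one cardiac cycle of `T = 1.0` s sampled at 64 instants; and a two-harmonic
pulsatile waveform with systole at 0.15 T. The solver that produced the
original fields used 3826 steps of 0.5 ms per cycle — the desk-scale grid
here is deliberately coarser and both `cycle_T` and `n_timesteps` are
configurable (the implied 1.91 s cycle of the original solver settings is
unusually long, so the generator does not assume it). Pressure is a
pulsatile component of 2666 Pa around an 80 mmHg (10665.76 Pa) baseline.

The shear field at node $s$ is
$\mathbf{w}(s,t) = M(s)\,[\,\phi(t)\,\mathbf{e}(s) + c(s)\sin(2\pi t/T)\,
\mathbf{c}(s)\,]$ with $\phi$ the unit-mean waveform, $\mathbf{e}$ a unit
tangential direction field, $\mathbf{c} = \mathbf{n}\times\mathbf{e}$ the
cross-flow direction, and $c(s)$ the cross-flow fraction. Design choices:

* **Base direction**: the unit azimuthal swirl about the vessel axis. It is
  divergence-free on the analytic surface, and the base magnitude is
  spatially uniform, so with all effects and noise switched off the thin and
  normal sampled distributions are *identical* — the null-recovery test is
  exact for five of six metrics. The sixth, WSSD, retains the 1-ring
  discretisation residue of the swirl field (largest near the apex, where
  the field's second derivatives blow up); under the null the sampled
  thin-normal WSSD difference is therefore only asserted to stay within one
  dome-wide standard deviation of that residue.
* **Thin patches**: one or two geodesic caps (radius 1.6 mm) seeded on the
  0.7 rad polar ring of the dome, at a seeded azimuth with evenly spaced
  partners. The polar placement keeps entire patches in the well-conditioned
  zone of the default overhead camera — near the silhouette, foreshortening
  compresses projected node spacing toward the pixel pitch and exact
  mask/mesh round-tripping would break down.
* **Injected effects**: inside patches the whole shear vector is multiplied
  by 1.35 (raising WSS and TaWSS, and through TaWSS lowering RRT), the
  direction field is blended toward a radially expanding pattern centred on
  the cap (positive surface divergence of known sign, hence positive WSSD),
  and pressure gains +250 Pa. Because the multiplier scales the *whole*
  vector, OSI is exactly unaffected — the generator encodes the null OSI
  finding structurally rather than by a zero coefficient.
* **OSI scale**: the cross-flow fraction defaults to 0.5, which puts OSI on
  the few-percent scale (≈0.02–0.08) typical of aneurysm domes; setting
  `cross_frac = 0` gives perfectly unidirectional shear and exactly zero
  OSI.
* **Random structure**: a patient-level log-normal intercept (sd 0.08),
  per-patch intercepts plus a smooth Gaussian-bump random field (sd 0.10)
  standing in for region-scale variability, and per-node log noise
  (sd 0.12), mirroring the nesting the mixed model assumes. All randomness
  flows from one master seed through documented per-patient sub-seeds, so
  any patient is regenerable in isolation.

Rendered images place thin pixels in a red cluster (sRGB 170, 40, 50),
normal wall in pinkish-purple (190, 120, 160) and background in a dark tone,
with seeded Gaussian CIELAB noise (sd 2.5 by default); the returned mask is
the exact ground-truth thin-pixel set. With zero noise the cluster bytes are
written untouched, so segmentation recovery is exact; under default noise
the Dice overlap against ground truth stays above 0.95 (typically ≈0.99).

For statistical calibration studies the field generator is bypassed:
`simulate_lmm_table()` draws tables directly from the nested model with the
design of the regional analysis. At the reference truth
($\beta_1 = 0.03$, sds 0.02 / 0.05 / 0.07, 16 patients × 40 rows) the suite
verifies mean bias within 10% over 200 replicates, Wald CI coverage between
90% and 98%, and a type-I error between 2% and 9% over 400 null replicates.

## What the synthetic validation does and does not show

Passing tests demonstrate that the *pipeline* is correct and calibrated:
exact colour segmentation recovers exact ground truth, injected effects are
recovered without bias, nominal error rates hold, and the direction pattern
(higher WSS, TaWSS, WSSD and pressure, lower RRT, null OSI in thin regions)
is reproduced in seeded replication runs. They do not validate the
*biological* claim on real data: the synthetic images have two colour
clusters with Gaussian noise (no glare, specularity or depth-of-field), the
camera is known exactly rather than manually registered, the fields come
from a structured generator rather than a Navier–Stokes solve, and vessel
walls are rigid. Those are the same respects in which any synthetic stand-in
falls short of patient data, and they mark the boundary of what a green test
suite means here.

## Problem sizes and runtime

The suite and the acceptance script run on desk-scale sizes chosen as
package defaults: "medium" meshes of 1081 nodes, 64 timesteps, cohorts of 16
patients, 200 + 400 calibration replicates and 20 replication runs. A full
cohort build plus all six fits takes a few seconds; the entire test suite
runs in roughly two to three minutes on one CPU.

## Known limitations

* The ambient WSSD trace on curved surfaces carries the non-vanishing
  normal-derivative bias discussed above; use `divergence = "surface"` when
  convergence to the analytic surface divergence matters.
* Geodesic quantities (patch growth, erosion, separation) use edge-graph
  shortest paths, which overestimate true geodesic distances by a
  mesh-dependent factor; margins are quoted in that metric.
* `patient_max` normalisation of signed WSSD divides by the signed maximum;
  a dome whose largest-magnitude WSSD is negative would flip signs, which is
  why the generator injects a dominant positive divergence and why real-data
  users should inspect the per-patient maxima table attached to the sample
  table.
* The renderer is deliberately minimal (orthographic camera, flat colour
  clusters); it exists to close the validation loop, not to emulate
  photographs.
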