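---
title: "Predicting spindle position from apical cell shape: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spindle position from apical cell shape: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindle2d)
```

## The biological question

Early ascidian embryos cleave in an invariant pattern: every blastomere
faces the outside of the embryo, divisions are parallel to the apical
surface, and in several lineages the mitotic spindle visibly rotates during
prometaphase before settling, at metaphase, along the long length of the
cell's apical surface — the classical long-axis (Hertwig) rule applied to
the apical plane. Whether the apical geometry alone is sufficient to
explain the final spindle orientation can be tested quantitatively: extract
the apical plane of each blastomere, feed its 2D outline to a mechanical
model of cytoskeletal pulling forces, and compare the predicted spindle
with the observed one. This package implements that pipeline — the
geometry, the mechanical model, the deviation metrics, the statistics, and
a synthetic-data generator so that every stage can be exercised and
validated without imaging data.

## The mechanical model

A mitotic spindle is represented by its two poles, joined by a rigid axis
of length $\ell$. From each pole, astral microtubules radiate along
$n$ fixed, equally spaced directions in the lab frame (default $n = 180$
per pole). A microtubule growing along direction $\hat d_k$ from pole $p$
reaches the cell cortex at distance $L_k$, the first intersection of the
ray with the cell outline, and pulls the pole toward the cortex with force

$$ f_k \;=\; L_k^{\beta}\,\hat d_k, $$

so that longer microtubules — which recruit more force generators along
their length — pull harder. The net force on the spindle and the torque
about the spindle center are

$$ F(c, \theta) = \sum_{\text{poles}} \sum_k L_k^\beta \hat d_k,
   \qquad
   \tau(c, \theta) = \sum_{\text{poles}} (p - c) \times
   \sum_k L_k^\beta \hat d_k . $$

For each candidate orientation $\theta$ on a $[0^\circ, 180^\circ)$ grid
(axial angles; a spindle is undirected) the center $c^*(\theta)$ is placed
at mechanical equilibrium by minimizing $\lVert F \rVert^2$ with a
deterministic compass search seeded at the area centroid. The torque at
the balanced center, $\tau(\theta) = \tau(c^*(\theta), \theta)$, is then
integrated into a rotational energy landscape

$$ E(\theta) = -\int_0^\theta \tilde\tau(\vartheta)\, d\vartheta,
   \qquad \tilde\tau = \tau - \bar\tau, $$

where subtracting the mean torque $\bar\tau$ enforces the
$180^\circ$ periodicity that the configuration space demands (the pulling
force field is not exactly conservative, so the raw integral would drift
by a small constant per period). By construction $\tau = -dE/d\theta$
holds exactly on the grid; stable orientations are minima of $E$, where
the torque crosses zero with restoring sign. The prediction is the global
minimum, refined by linear interpolation of the torque between the two
bracketing grid points, with the center re-balanced at the refined angle.

### Why the force exponent defaults to 1, and what happens at $\beta = 3$

Two exact identities of the uniform planar ray fan constrain the model
family and are worth stating because they rule out seemingly natural
alternatives:

* **Scalar landscapes fail.** The summed microtubule potential
  $W(p)=\sum_k L_k^{\beta+1}/(\beta+1)$ cannot serve as the energy whose
  minimum is the prediction. At $\beta = 1$,
  $\tfrac12\int_0^{2\pi} L(p,\phi)^2\, d\phi$ *is the cell area* for any
  interior point $p$ — the landscape is exactly flat. At $\beta = 3$,
  $\tfrac14\int_0^{2\pi} L(p,\phi)^4\, d\phi$ is the polar second moment of
  area about $p$, which by the parallel-axis theorem equals
  $J_c + A\,\lvert p - g\rvert^2$ ($g$ the centroid): it depends on the
  pole position only through its distance to the centroid, so rotating the
  spindle changes nothing. Both identities were verified numerically
  against the implementation.
* **The force model is torque-free at $\beta = 3$.** Integrating the
  pulling force over the fan gives
  $\int L^3 \hat d \, d\phi = 3A\,(g - p)$ exactly: a pure centering
  spring. The torque about the spindle center then cancels identically
  between the two poles. A cubic force law — motivated in the literature
  by the volume of cytoplasm explored by a microtubule in three
  dimensions — therefore cannot orient a spindle in a *planar* fan; in a
  thin, slab-like geometry the effective in-plane exponent is lower than
  the 3D one.

With forces that scale linearly with microtubule length ($\beta = 1$, the
default) or quadratically ($\beta = 2$), the torque profile of an
anisotropic cell has a single stable zero per $180^\circ$ at the shape's
long axis, and predictions are insensitive to the choice between the two
(asserted by the test suite on ellipses and superellipses: 100% of
predictions within one grid step of the principal axis for both
exponents). At $\beta = 3$ the landscape is flat to discretization noise
and the prediction is flagged degenerate rather than reported as
spuriously oriented. `placement_energy()` exposes the scalar potential
$W$ for inspection; `placement_force()` exposes $F$ and $\tau$.

### Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `beta` | — | 1 | force proportional to microtubule length; see above |
| `n_rays` | per pole | 180 | 2° angular sampling; predictions change < 1° when refined to 720 |
| `dtheta` | degrees | 1 | orientation grid; minimum refined by torque interpolation |
| `spindle_length_mode` | — | `"observed"` | observed pole separation when an observation exists; `"fraction"` otherwise |
| `spindle_fraction` | of major axis | 0.4 | metaphase spindle roughly half the cell's long length |
| `center_mode` | — | `"optimize"` | net-force balance per orientation; `"centroid"` pins the center for speed |
| `relief_tol` | relative | 1e-4 | degeneracy guard: landscape relief divided by the mean astral potential; circles sit near 1e-9, aspect-ratio-1.1 cells near 1e-3 |

The spindle length is clamped down in 5% steps until both poles are
interior at *every* grid orientation, because the torque integration needs
the full period. For strongly elongated cells this can make the effective
spindle shorter than the observed one; the orientation prediction is
insensitive to this (the torque profile scales but its zeros barely move).

## Deviation metrics

* **Orienting deviation**: the acute angle between observed and predicted
  spindle axes, in $[0^\circ, 90^\circ]$ — axial angles, so $170^\circ$
  vs $20^\circ$ differ by $30^\circ$.
* **Centering deviation**: distance between observed and predicted spindle
  centers as a percentage of the cell's major-axis length, so "centered
  within 20%" reads as within 20% of the cell's long length. The
  percentage needs a denominator and the natural alternatives differ; the
  major axis is the default and the equal-area-circle diameter is
  available (`normalization = "equiv_diameter"`).
* **Clone patterns**: two successive divisions from one mother produce
  four grand-daughters whose arrangement — square, T, or line — encodes
  how many daughters divided parallel to their mother (0, 1 or 2 oriented
  cell divisions), with parallel/orthogonal split at 45°, the midpoint of
  the axial range.
* **Misorientation incidence**: per lineage, the percentage of divisions
  whose axis differs from the lineage's invariant-pattern reference axis
  by more than 45° (threshold configurable); reference axes are inputs,
  not inferred.
* **Cell-cycle metrics**: percent cycle lengthening
  $100(\mathrm{curr}-\mathrm{prev})/\mathrm{prev}$ and animal–vegetal
  mitotic-entry asynchrony $\overline{t}_{\mathrm{animal}} -
  \overline{t}_{\mathrm{vegetal}}$ in minutes.

## 3D shape metrics and apical-plane extraction

Blastomere surfaces arrive as watertight triangle meshes with per-face
apical/basolateral labels (OFF or PLY; labels as a PLY integer face
property `label` or a sidecar CSV — no standard exists for face-partition
labels). Sphericity is $\Psi = \pi^{1/3}(6V)^{2/3}/A$, computed on the raw
mesh with $V$ from the signed tetrahedron sum and $A$ from triangle areas.
The ideal sphere ($\Psi = 1$) is the reference; an isolated rounded
blastomere measures slightly below it, so comparisons against an empirical
"spherical standard" of about 0.975 remain meaningful. The apical surface
ratio is the label-weighted area fraction.

The apical plane is defined as the plane through both spindle poles that
best separates apical from basolateral membrane. Among the one-parameter
family of planes containing the pole axis, the rotation angle is scanned
at 1° resolution and refined by golden-section search; each face votes
with its area on the side its centroid falls on, and the score is the
area fraction correctly separated (0.5 = no signal, 1 = perfectly planar
partition; below 0.6 a warning is raised). The mesh cross-section in the
chosen plane, expressed in plane coordinates with the pole axis along
$+x$ and origin at the pole midpoint, becomes the 2D outline passed to
the model. If the section has several loops, the loop containing the
poles is kept with a warning.

## Statistics

Pooled orienting deviations (metaphase only by default, configurable) are
summarized as fractions strictly below 10°, 20° and 30°, and tested
against the uniform null on $[0^\circ, 90^\circ]$ — "no relation between
shape and spindle" — with a one-sample two-sided Kolmogorov–Smirnov test
(exact null distribution for $n \le 150$, asymptotic beyond; the pivotal
cohort sizes in this field sit near $n = 149$). Group comparisons use the
Wilcoxon rank-sum test with continuity correction or the unpaired
two-tailed Student t-test (pooled variance), as named. Per-lineage bars
are means with s.e.m. Raw p-values are reported; no multiple-testing
correction is applied, and the summary JSON says so.

Lineages known to divide by a cortically imposed, shape-independent
mechanism (the germ-line precursors undergoing unequal cleavage) are
excluded from pooled statistics by a configurable lineage list
(default B5.2, B6.3, B4.1); degenerate (near-isotropic) cells stay in the
output table, flagged, but leave the statistics.

## The synthetic-data generator

The generator produces every input the pipeline consumes, as a pure
function of its seed:

* **Contours**: ellipses, superellipses (exponent 2.5–4), Fourier blobs
  (ellipse plus low-order radial harmonics, the closest mimic of manually
  traced outlines) and flattened variants; aspect ratios 1.1–3 and
  major-axis lengths 18–30 µm by default, the range a cleavage-stage
  blastomere's apical outline plausibly spans (the true distribution is
  not tabulated; this is a modeling choice). Ground-truth construction
  angle and aspect ratio are recorded.
* **Observations**: per cell, the model prediction perturbed by wrapped
  axial normal noise (default s.d. 15°) on the angle and isotropic
  Gaussian noise (1 µm) on the center, emitted as a metaphase record; a
  planted fraction of "rotating" cells additionally receives a prophase
  axis offset by Uniform(45°, 90°) with random sign — bracketing the
  prophase deviations of ~47–61° reported for rotating lineages — while
  non-rotating cells keep their metaphase axis at prophase. Which cells
  rotate is recorded as ground truth. The folded-normal identities give
  closed-form oracles: mean deviation $\sigma\sqrt{2/\pi}$, recoverable
  noise scale $\hat\sigma = \sqrt{\overline{d^2}}$.
* **Meshes**: icospheres, boxes, 2:1:1 ellipsoids and 2:2:1 flattened
  ellipsoids with hemisphere, area-fraction-cap or random labels, with the
  planted separating plane recorded.
* **Timing data**: two-hemisphere mitotic-entry times with a planted
  asynchrony (15 min mimics the control regime, 6–8 min the
  asynchrony-reduced regime) and per-cell jitter.

What the generator does *not* emulate — cell–cell packing, mitotic
rounding dynamics, segmentation error structure, the cortical
(CAB-driven) override in the germ lineage — bounds what passing tests
show: they validate the computational pipeline and its statistics under
controlled conditions, not the biological conclusion on real embryos,
whose raw imaging data are not redistributable.

## Numerical choices

* Contours are normalized to counter-clockwise orientation, the duplicate
  closing vertex dropped; simplicity is checked by exhaustive non-adjacent
  edge intersection. All angles are axial (mod 180°), degrees,
  counter-clockwise from $+x$.
* Principal axes come from the second area moments of the filled polygon
  (not vertex PCA), making them robust to uneven vertex spacing from
  manual tracing; axis lengths are those of the moment-equivalent ellipse.
  Shapes with a moment eigenvalue ratio below $1 +$ `tol` are flagged
  isotropic.
* Ray casting is exact per edge; convex polygons use an ordered sector
  walk (each direction hits exactly one edge), non-convex polygons fall
  back to exhaustive first-hit scans.
* The compass search halves its step until 0.005 µm; the orientation scan
  warm-starts each angle from the previous optimum. Exactly degenerate
  minima break ties toward the smallest angle, so runs are deterministic.
* The reference ("brute-force") scan evaluates every 0.5 µm lattice
  center at every 0.25° orientation, refining the lattice locally (×2,
  ×4) only if a tight cell admits no on-lattice placement at some
  orientation. Agreement between the gridded optimizer and this scan is
  asserted on 30 random anisotropic shapes.
* Problem sizes used by the test suite: 50 shapes for the long-axis
  sweep, 30 for the oracle comparison, 200 cells for parameter recovery,
  2000 uniform replicates (n = 149 each) for KS type-I calibration, 200
  aligned replicates for power. The full suite runs in a few minutes on
  one core.

## Known limitations

* The model is strictly 2D: it predicts position and orientation within
  the extracted apical plane and says nothing about out-of-plane tilt.
* Cortical polarity domains and the centrosome-attracting body are out of
  scope; lineages governed by them are expected to deviate and are
  excluded from pooled statistics rather than modeled.
* With a uniform planar fan the force law loses all shape sensitivity at
  $\beta = 3$ (see above); users who believe in a cubic law should treat
  it as a 3D statement and use the in-plane defaults here.
* The apical-plane search assumes the apical/basolateral partition is
  roughly planar around the pole axis; strongly non-planar partitions
  yield low separation scores and a warning rather than a hard failure.
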