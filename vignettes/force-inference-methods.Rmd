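---
title: "Methods: variational force inference and junction quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variational force inference and junction quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionforce)
```

# The mechanical model

An epithelial monolayer viewed apically is a polygonal cell packing. Each
cell–cell junction carries a contractile tension generated by the
actomyosin cortices of the two abutting cells; at every tri-cellular
vertex these tensions balance when the tissue is quasi-static, i.e. when
junction remodelling (hundreds of seconds) is slow compared with
cytoskeletal turnover (seconds). Pressure differences between cells would
curve the junctions; in the tissues this package targets junctional
curvature is negligible, so pressure is taken uniform and drops out of the
force balance.

Under these assumptions the tension pattern of a network whose vertices are
all three-fold is encoded by a **tension triangulation**: one node
$\vec Q_a$ per cell, one edge per junction, and force balance at a vertex
is exactly the closure of the triangle formed by the three dual edges,
rotated by 90° with respect to the cell edges. `infer_tensions()` fits this
dual by minimising
$$
\Omega \;=\; \tfrac12 \sum_{\langle a,b\rangle}
  \bigl[(\vec Q_a - \vec Q_b)\cdot \vec r_{ij}\bigr]^2
\;-\; \tfrac{\Lambda}{2} \sum_{\langle a,b\rangle}
  \bigl|\vec Q_a - \vec Q_b\bigr|^2 ,
$$
where $\vec r_{ij}$ is the end-to-end chord of the junction between cells
$a$ and $b$ (the chord, not the curved pixel path, because curvature is
negligible) and $\Lambda$ constrains the overall tension scale, which is
otherwise unidentifiable. Stationarity is the generalized eigenproblem
$A q = \Lambda B q$ over the stacked node coordinates; the fitted dual is
the generalized eigenvector with the smallest non-trivial eigenvalue, and
junctional tensions are $T_{ij} = |\vec Q_a - \vec Q_b|$, rescaled so that
their mean over included junctions is exactly one. $\Lambda$ is reported:
it is zero (machine precision) whenever an exactly perpendicular dual
exists, and grows with the departure of the tissue from equilibrium or
with segmentation noise.

## Restriction and exclusion policy

A triangulated dual requires three-fold vertices, so inference uses only
cells all of whose vertices are three-fold (`restrict_threefold()`); in
practice this keeps most cells. Cells touching the image frame are also
excluded, because their geometry is truncated and their force balance is
not observable. Nothing is deleted: every junction left out of the
inference carries an explicit reason code (`boundary_junction`,
`cell_excluded`, `ill_constrained_cell`, `bridge_junction`,
`degenerate_block`), and the pipeline log reconciles input counts against
retained-plus-excluded on every run.

## Numerical choices

* **Translation deflation.** Both quadratic forms annihilate global
  translations of $Q$ and nothing else on generic networks. The two
  translation modes are removed exactly by restricting to their orthogonal
  complement (the $Q$ centroid is pinned at the origin); the reduced
  constraint form is then positive definite on each connected dual
  component and is factored by Cholesky, turning the problem into an
  ordinary symmetric eigendecomposition.
* **Spurious null modes.** On imperfectly segmented networks three
  pathologies create *exact* null modes of the inner-product form that the
  minimiser would return instead of the physical solution: cells held by a
  single dual edge, cells whose incident chords are near-collinear (the
  smallest eigenvalue of the mean outer product of unit chords below
  0.02), and bridge edges or narrow cuts whose crossing chords are almost
  parallel. The first two are pruned structurally (iteratively, with
  `igraph::bridges()` for the cuts of width one). The last is handled by
  deflation: if a solved component is *localised* — median tension below
  5% of the mean, i.e. the whole weight sits on a few junctions — the node
  positions are split at the largest gap along their principal direction,
  the smaller block is dropped (`degenerate_block`), and the component is
  re-solved, up to 15 passes.
* **Degeneracy warning.** If the final spectrum has a relative eigen-gap
  below `1e-6` above the selected mode, a warning reports the gap.
* **Components.** A disconnected dual graph is solved and normalised per
  component, with a warning; tensions are only comparable within a
  component.
* **Sign and chirality.** The eigenvector's sign and the triangulation's
  chirality are irrelevant because tensions are norms.

## Shear stress

Cortical tensions $\theta_a(x)$, $\theta_b(x)$ on the two sides of a
junction sum to the (constant) junctional tension but may vary in opposing
gradients along it; the gradient is the shear stress exerted on the
adhesion complexes that anchor the two cortices to each other. Requiring
cortical tensions to be single-valued at the two end vertices gives the
average shear in terms of the four neighbouring junction tensions,
$$
\tau = \frac{1}{2L}\,\bigl|\,(T_1 + T_3) - (T_2 + T_4)\,\bigr| ,
$$
with the *diagonal* pairing: $T_1$ and $T_3$ lie on opposite cell sides at
opposite ends. `compute_shear()` reports the unsigned value plus the
dominant side as metadata, and a unit test pins the diagonal pairing
against a hand-worked four-cell configuration ($T = (3,1,2,1)$, $L = 2$,
$\tau = 0.75$), since the same-end pairing is the most likely
implementation error. Only the junction-average $\tau$ is computed; the
pointwise profile $\tau(x)$ is not identifiable from inferred tensions.

The selection rule for ablation experiments (`select_shear_increase()`)
follows from the same formula: cutting a junction on the strictly weaker
diagonal pair of a neighbour increases that neighbour's shear. The rule is
stated and implemented in a form invariant under relabelling the central
junction's cell sides, which swaps $(T_1,T_3)$ with $(T_2,T_4)$.

# Image quantification

* **Projection.** The in-focus plane of a z-stack is chosen by a per-tile
  (64 px) Sobel gradient-energy metric (plane with the largest median tile
  score); the signal image is the maximum projection of that plane plus
  the two planes basal to it, and the background image is the maximum
  projection of the three basal-most planes followed by a large-radius
  (default 50 px) median filter. The processed image is
  `pmax(signal - background, 0)`, which cancels any additive offset.
* **ROIs.** Junctional ROIs are bands of about 5 px around each junction
  path with 3-px disks around tri-cellular vertices excluded (the radius
  is a package choice; junctions shorter than twice this radius have empty
  ROIs and are flagged). Medial ROIs are cell interiors at least 2 px from
  any junctional band; the two classes are disjoint by construction. Line
  density = mean intensity over the junctional ROI; area density = mean
  over the medial ROI; empty ROIs yield `NaN` plus a flag, never silent
  zeros.
* **Polarity.** Junction angles relative to the AP axis (folded to
  [0, 90]°, invariant to path orientation) are grouped into six 15° bins;
  the averaged line density (ALD) per bin, the PCP amplitude as the ratio
  of the two extreme bins (orientation recorded), and the relative
  intensity profile (ALDs normalised by the smaller extreme bin) follow.
  The `vertical`/`transverse` classes default to [60, 90] and [0, 30]
  degrees; no canonical numeric cutoff exists, so the ranges are explicit,
  configurable arguments.
* **Pixel-scale ratio.** Marker-positive pixels are selected by SNR > 1,
  with SNR defined against a local median-filter background and a robust
  noise scale (1.4826 x MAD of the background-subtracted intensities over
  non-junctional pixels); qualifying pixels are binned by denominator
  intensity in 25-unit-wide bins and the mean per-pixel ratio is reported
  per bin. The exact estimator behind the original macros is not public;
  this stand-in is deliberately simple and fully configurable.
* **Junction-level ratio.** The Vinc/E-cad ratio of a junction is the
  ratio of mean densities (not the mean of pixel ratios); the two agree
  exactly when the denominator is constant along the junction, which a
  test asserts.

# Correlation statistics

Mean junctional densities and inferred tension are all roughly
proportional to 1/length, so raw correlations between them are confounded.
Two complementary statistics remove the confound:

* **Conditional correlation** sorts junctions by length within each
  snapshot (ties broken by index), chunks them into bins of exactly 10
  junctions of adjacent length (remainder dropped), and computes a
  coefficient inside each bin, where length is effectively constant.
  Binning is per snapshot; pooled coefficients form the distribution and
  bins grouped by mean length rounded to 1 px form the by-length curve
  (mean ± SE). The construction depends on the length *order* only.
* **Local correlation** computes a Pearson coefficient across the
  junctions of each cell (at least 4 junctions: three is the Pearson
  minimum, one more for stability), which is immune to slow spatial and
  temporal intensity drift. Its null is built by permuting the second
  variable across all junctions of the snapshot and recomputing the
  per-cell coefficients — this preserves the per-cell topology and both
  marginals; the permutation count and seed are explicit. Both the pooled
  null and the per-permutation medians are returned, the latter giving a
  central band for the observed median; a one-sided Mann-Whitney test
  against the pooled null is included.
* **Method rule.** Below 100 points rank (Spearman) correlation is used —
  small samples do not support the linearity assumption — otherwise
  Pearson; overridable.
* `bootstrap_mean()` provides seeded bootstrap resampling of sample means.

# The synthetic test bed

The generator provides ground truth for every stage; its defaults are the
package's study conditions.

* **Geometry.** Seeds are drawn from an isotropic hard-disk point process
  (exclusion radius `(1 - 0.45 * jitter)` times the mean spacing;
  `jitter = 0` gives an exact triangular lattice and hence a perfect
  hexagonal tissue). Isotropy matters: lattice-based seeding couples
  dual-edge length to orientation and would bias the realised polarity of
  any tension-coupled channel. The point process is padded 2.5 cell rows
  beyond the image so wall effects decay before reaching analysed cells,
  and one Lloyd sweep gives mild centroidal regularity (tension CV about
  0.18, matching a moderately heterogeneous epithelium). The Voronoi
  diagram is the cell network; each junction's true tension is the length
  of its dual Delaunay edge, so every interior vertex balances exactly
  (vertices are recomputed as exact circumcentres; median residual is at
  machine precision). Interior Voronoi edges shorter than
  `min_junction_px` (default 6 px, just above twice the vertex-exclusion
  radius — shorter junctions have no ROI and no separable vertices, and
  would not appear in a real segmentation either) are annealed away by
  nudging the involved seeds.
* **Scale.** Default 200 cells in a 640 x 640 px domain, i.e. ~45 px per
  cell diameter — a ~5 µm germband cell imaged at ~0.11 µm/px on a 100x
  spinning-disk system. Tests and the acceptance script use this scale
  (and up to 700 cells for polarity estimates); these sizes are the
  package's chosen study conditions.
* **Intensities.** Myosin-II is proportional to tension and DV-enriched;
  E-cadherin is AP-enriched with an additive `confound * e0 * mean(L) / L`
  term producing the 1/length density confound; Vinculin is recruited onto
  E-cadherin complexes constitutively (`alpha`) plus proportionally to the
  load per complex (`beta * T`), so the noiseless Vinc/E-cad ratio is
  `alpha + beta * T`, independent of junction length — the property that
  makes the ratio a useful load read-out. Polarity amplitudes are
  parameterised directly as the expected extreme-bin ALD ratio via a
  linear angular ramp between 15° and 75°, so recovery is exact in
  expectation. All noise flows from the single config seed.
* **Rendering.** Junction paths are painted as 7-px bands (band half-width
  3) at their line density using the same rasteriser as the ROI extractor,
  so ROI means recover painted densities exactly in a noise-free render;
  a medial Myosin pool fills cell interiors. Planes are blurred and
  attenuated away from the designated focus plane (attenuation
  `exp(-dz^2/2)`, leaving the basal-most planes with haze rather than
  structure, as under real defocus), and Poisson photon noise plus
  Gaussian read noise complete the camera model.
* **Ablation.** Cutting a junction zeroes its tension; vertices then move
  with overdamped dynamics `v = F / gamma` while the remaining tensions
  are held fixed (quasi-static cytoskeleton). The initial endpoint
  separation rate is exactly `2 T / gamma`, which anchors the simulator to
  a closed form. The default drag (`gamma = 20`) keeps the standard 2-s
  recoil window deep in the initial-recoil regime — sub-pixel
  displacements — which is the regime in which recoil velocity reads out
  released tension; with weak damping the window would span local
  re-equilibration and the read-out saturates. An optional E-cadherin
  turnover model `dE/dt = k_on - k_off0 (1 + s * tau) E` (with tau
  recomputed from current geometry each step) encodes the *hypothesis*
  that shear enhances dissociation; it is a synthetic device for testing
  pipeline logic, not a validated mechanism.

## What the generator does and does not emulate

It reproduces: exact vertex force balance, tension-coupled and
planar-polarised channel statistics, the 1/length confound, realistic
pixel scale, defocus, photon noise, and quasi-static ablation recoil. It
does **not** emulate: junction curvature, pressure heterogeneity,
four-fold/rosette intermediates of intercalation, myosin pulsing, drift or
photobleaching, or E-cadherin cluster granularity below the ROI scale.
Passing tests therefore demonstrate the correctness of the computational
chain under its stated assumptions, not the validity of those assumptions
in any particular real tissue.

# Segmentation and network extraction

`segment_cells()` runs a watershed on the distance transform of the
sub-threshold (cell-interior) pixels of a junctional probability map and
propagates the basin labels across the junctional band with strong spatial
regularisation, so fronts meet at the band midline; a one-pixel boundary
skeleton is redrawn between labels. `junction_probability()` provides a
classifier stand-in (logistic around the Otsu threshold) when no external
pixel classification is available.

`build_network()` classifies boundary pixels by their adjacent labels
(pair pixels vs triple points, the latter detected in a radius-2
neighbourhood because a one-sided skeleton can be locally two pixels
wide), orders pair runs into junction paths, attaches end vertices, and
refines each vertex to the least-squares intersection of total-least-squares
line fits of its incident paths — sub-pixel vertex accuracy roughly doubles
the fidelity of downstream tension inference. Junction length is the path
arc length including the links to the fitted vertices (never shorter than
the chord); angles use the chord.

# Known limitations

* Relative tensions only; no absolute force calibration, no pressure
  inference, no curved-junction (Young-Laplace) variant.
* Tensions are not comparable across disconnected dual components.
* The per-cell correlation null assumes exchangeability of junction values
  across the snapshot; strong global gradients would violate it.
* The recoil read-out assumes the overdamped, quasi-static regime; the
  simulator is not a viscoelastic model of the real cortex.
* Sub-resolution junctions are outside the model: the generator anneals
  them away, and the graph builder cannot recover junctions shorter than
  its vertex-detection kernel (~6 px).
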