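---
title: "Methods: level-set tooth segmentation and PCNN tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: level-set tooth segmentation and PCNN tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothseg)
```

## The problem

A single extracted tooth scanned by micro computed tomography (MicroCT) has
to be separated from its surroundings and split into its three tissues —
enamel (bright), dentine (intermediate) and pulp (dark) — before downstream
work such as finite-element stress analysis can assign material properties.
Manual slice-by-slice labelling by a dentist is the accepted reference but is
slow. Automation is harder than it looks: the scans are noisy, tissue
boundaries are weak, not every slice contains all three tissues, and the
physical bracket that holds the tooth during scanning touches the tooth base
and has tooth-like intensity.

`toothseg` implements a two-stage framework for this task plus everything
needed to evaluate it: a 3D region-based level set (GFRLS) that extracts the
whole tooth, an improved pulse-coupled neural network (PCNN) that resolves
intensity tiers inside it, a quasi-Monte Carlo volume estimator, the standard
agreement statistics, and a deterministic tooth phantom with exact ground
truth so the whole chain is testable without clinical data.

## Stage 1 — 3D GFRLS segmentation

The tooth/background separation uses a Selective Binary and Gaussian
Filtering Regularized Level Set. A level-set function $\phi(x,y,z)$ is
initialized to $+1$ inside an axis-aligned cuboid enclosing the tooth and
$-1$ outside. Each iteration:

1. compute the region means $c_1$ (inside, $\phi \ge 0$) and $c_2$ (outside)
   under the arctangent-regularized Heaviside
   $H_\varepsilon(z) = \frac12\bigl(1 + \frac{2}{\pi}\arctan(z/\varepsilon)\bigr)$;
2. form the signed pressure force
   $spf(I) = \dfrac{I - (c_1+c_2)/2}{\max\lvert I - (c_1+c_2)/2\rvert} \in [-1,1]$;
3. take one explicit Euler step
   $\phi \leftarrow \phi + \Delta t\,\alpha\,spf(I)\,\lvert\nabla\phi\rvert$,
   with $\lvert\nabla\phi\rvert$ from central differences (one-sided at the
   grid border);
4. re-binarize $\phi$ to $\pm 1$ ($\phi = 0$ counts as inside — the zero
   level is the surface itself);
5. regularize with a separable 3D Gaussian (kernel truncated at $3\sigma$,
   reflective boundaries).

Binarization plus Gaussian smoothing replaces signed-distance
re-initialization; the curvature and $\nabla spf \cdot \nabla\phi$ terms of
the general region-based evolution are deliberately absent in this
formulation. The sign of the SPF steers the front: a box inside a bright
object expands to its boundary, an enclosing box shrinks onto it. Because the
update is proportional to $\lvert\nabla\phi\rvert$, which vanishes away from
the interface of the binarized-then-smoothed field, interior regions (such as
the dark pulp, fully enclosed by dentine) are never carved out — the front
only ever moves at the current surface. On a noiseless two-level image the
converged mask coincides with midpoint thresholding, which is the oracle the
test suite checks against.

**Convergence.** The stopping rule is not part of the published formulation,
so the package defines it: stop when the fraction of voxels whose sign
changed over one full iteration is at most `conv_tol` (default $10^{-4}$), or
after `max_iter` (default 200) iterations, whichever comes first, with a
warning (not an error) in the latter case. Since $\phi$ is re-binarized every
iteration, sign changes fully describe the evolution. A velocity field that
is identically zero (e.g. a constant image) is detected as stationary
immediately, before any regularization, so the mask then equals the
initialization box exactly.

**Defaults.** $\alpha = 20$, $\sigma = 1$ voxel, $\Delta t = 1$,
$\varepsilon = 1.5$ — magnitudes conventional for this family of level sets;
all exposed in `gfrls_params()`. Intensities are min-max normalized to
$[0,1]$ internally, which makes the defaults portable and the segmentation
invariant to affine intensity rescaling. On a $128^3$ grid a segmentation
converges in a few dozen iterations (well under two minutes on one CPU);
unit tests use $24^3$–$48^3$ grids.

## Stage 2 — improved PCNN classification

Inside the tooth, tissues are classified per 2D slice by a pulse-coupled
neural network: one neuron per pixel, with feeding and linking channels

$$F(n) = e^{-\alpha_F \Delta t}F(n-1) + S + V_F (M \ast Y(n-1)), \qquad
  L(n) = e^{-\alpha_L \Delta t}L(n-1) + V_L (W \ast Y(n-1)),$$

multiplicative modulation $U = F(1 + \beta L)$, and a dynamic threshold
$\theta(n) = e^{-\alpha_\theta \Delta t}\theta(n-1) + V_\theta Y(n-1)$. The
$3\times 3$ synaptic kernel $W$ (used for $M$ too, the standard
simplification) weights 4-neighbors 0.1 and diagonals 0.07 with a zero
center. The classifier's distinguishing feature is the *graded* hierarchical
output that replaces the classic binary step:

$$\xi = U - \theta, \qquad Y = \frac{\xi}{\max \xi}\,k,$$

where $k$ is the number of intensity tiers to resolve. A local-variation map
$G_{ij} = \sum_{r,t} \lvert \xi_{ij} - \xi_{i+r,j+t} \rvert$ over the
$3\times3$ window is computed and returned as a diagnostic but does not enter
$Y$, faithfully to the printed formulation; an optional edge-aware variant
(`use_edge_weight`) divides $\xi$ by $(1+\lambda G)$ before normalization and
is off by default. Final classes are `round(clamp(Y, 0, k))`.

**Why the threshold gain is small.** In the classic binary PCNN the threshold
gain $V_\theta$ is set very large so that a fired neuron is silenced for many
iterations. With the graded output there is no firing/reset cycle: a large
$V_\theta$ makes $\theta$ exceed $U$ for *every* neuron within two or three
iterations, $\xi$ turns negative everywhere, and $\xi / \max\xi$ then maps
every pixel at or above $k$ — all hierarchy collapses into one class. A
steady-state argument ($\theta_\infty \approx V_\theta \bar Y /
(1 - e^{-\alpha_\theta \Delta t})$ must stay below the internal activity of
the darkest tier) puts the workable range below roughly $0.2$ for the other
defaults; the package uses $V_\theta = 0.1$. The remaining defaults
($\beta = 0.2$, $V_F = 0.1$, $V_L = 0.2$, $\alpha_F = 0.1$,
$\alpha_L = 0.3$, $\alpha_\theta = 0.2$, $\Delta t = 1$, $N = 10$) are
typical PCNN-literature magnitudes. All are configurable in `pcnn_params()`.

**Initialization and ordering.** All state grids start at zero, so the first
iteration's internal activity equals the stimulus and the first output is
exactly $S/\max S \cdot k$. Within an iteration the threshold is updated from
the *previous* output before the new output is formed; this makes the
threshold recursion and the output formula see consistent iteration indices.
The per-pixel firing counter (`firate`, counting $Y \ge k/2$) is kept as
telemetry only — nothing downstream consumes it.

**Border convention.** Kernel sums use zero padding and the $G$ window skips
out-of-grid neighbors. Zero padding attenuates border neurons, and the
attenuation travels inward one pixel per iteration; the uniformity invariant
("equal-intensity regions get equal output") therefore holds exactly only
outside that light cone, which is how the tests assert it. A related
practical consequence: a thin bright structure directly adjacent to near-zero
background loses its outermost pixel band to the class below, because its
neighborhood pulls the internal activity down. The pipeline never feeds the
PCNN that configuration — enamel is thresholded away *before*
classification, so the PCNN only sees the dentine/pulp interior, whose tier
gap is mild.

## The end-to-end pipeline

`run_pipeline()` chains the stages in the order: ROI crop around a seed
point → GFRLS segmentation → mask cleanup → grayscale masking → enamel
threshold → PCNN on the interior ($k = 2$) → label composition (enamel wins;
background where the mask is empty) → paste back into full-volume
coordinates. Design choices that were genuinely open:

* **Grayscale masking.** The published description ("subtraction" of the
  binary result from the CT data) is dimensionally incoherent if taken
  literally; the package keeps original intensities inside the mask and
  zeroes the rest, which reproduces the described outcome (a grayscale tooth
  image).
* **Mask cleanup.** Plain binary erosion removes speckle but also thins the
  tooth by one surface layer, which would bias every enamel volume low by the
  cap's outermost shell (the enamel cap is only a few voxels thick at 1 mm
  resolution). The pipeline therefore uses the eroded mask as a *marker* and
  reconstructs it inside the original mask (morphological opening by
  reconstruction, 26-connectivity): components wiped out by erosion stay
  deleted, everything else returns at full size. `erode_mask()` itself
  remains plain erosion; set `reconstruct = FALSE` in `pipeline_config()` for
  the plain behavior. As an additional safeguard the largest 26-connected
  component is retained.
* **Enamel threshold.** `"auto"` (default) is a maximal
  between-class-variance (Otsu) split of the nonzero masked intensities on a
  256-bin histogram; a fixed threshold in $(0,1)$ can be supplied instead.
* **Dentine/pulp assignment.** PCNN classes are per-slice; to label slices
  that contain only one interior tissue consistently, each slice-level class
  is mapped to dentine or pulp by comparing its mean original intensity
  against a single *global* Otsu split of all interior intensities (dentine
  is the brighter tissue in MicroCT).
* **Bracket handling.** The bracket rod survives segmentation (its intensity
  is tooth-like) and, where it touches the tooth, joins the largest
  component. The ROI crop removes most of its length; the residual
  contamination is small and shows up as a slight dentine over-estimate in
  the phantom evaluation.

## Volume estimation and evaluation statistics

Structure volumes are measured slice-wise by quasi-Monte Carlo: $N$ 2D Halton
points (bases 2 and 3; deterministic, no seed) are scattered over the
slice's bounding box of the structure, the hit fraction scales the box area,
and areas are summed times the slice thickness. The voxel-count volume is the
exact discrete reference; the estimator converges to it as $N$ grows, and the
test suite checks the error shrinks across $N \in \{10^3, 10^4, 10^5\}$ and
is below 2 % at $10^5$ on a fixed sphere.

Agreement statistics follow the standard definitions: signed relative volume
error $(V - V_{ref})/V_{ref}$; mean absolute deviation of paired volumes
(mm³); a correlation coefficient defined with an absolute-value numerator
(so it lives in $[0,1]$ and anti-correlation also scores 1 — the published
definition, kept as printed); and the overlap triple of Dice similarity
$S = 2\lvert A\cap D\rvert/(\lvert A\rvert + \lvert D\rvert)$, sensitivity
$\lvert A\cap D\rvert/\lvert D\rvert$ and specificity
$\lvert A\cap D\rvert/\lvert A\rvert$. The published similarity-index formula
omits the division sign; it is restored to the standard Dice form, consistent
with the stated property that total overlap scores 1 in all three indexes.
`reported_volume_table()` ships the published nine-pair volume benchmark
(three structures × three cases, five methods + manual ground truth);
feeding any method's column into `volume_mad()` reproduces that method's
published MAD — the package's desk-checkable worked example.

## The phantom: what it does and does not emulate

`phantom_generate()` builds a deterministic single-tooth volume with exact
labels: a crown ellipsoid (default semi-axes 45×30×30 voxels in a $128^3$
grid at 1 mm isotropic spacing, matching the scan geometry the framework
targets), an enamel cap (the outer 20 % shell of the upper crown), a pulp
chamber ellipsoid continued by a root-canal cylinder, dentine elsewhere, and
an optional bracket rod (radius 8, touching the tooth base, labelled
background but bright). Intensity tiers default to 0.05 / 0.35 / 0.65 / 0.95
(background / pulp / dentine / enamel) with the bracket at 0.70 — between
dentine and enamel precisely so it genuinely challenges the segmentation.
Additive Gaussian noise (default sd 0.02) is applied and clipped to $[0,1]$;
the geometry scales with the grid so small test phantoms remain nested, and
across the stack some slices contain one, some two and some three
structures, as in real crowns.

The phantom has sharp tier boundaries, no partial-volume blur, no beam
hardening, no ring artifacts, and spatially white noise. Passing the phantom
suite therefore demonstrates the *mechanics* of the method — front
propagation and stopping, tier separation, volume integration, bracket
robustness — not clinical-grade accuracy on real MicroCT, whose noise is
structured and whose boundaries are genuinely weak.

## Numerical choices and degenerate inputs

* Ties at $\phi = 0$ count as inside; the mask is `phi >= 0`.
* A constant image yields $spf \equiv 0$ and converges immediately to the
  initialization box; the pipeline short-circuits constant volumes to
  all-background with a warning.
* An empty enamel threshold result or an empty segmentation mask warns and
  degrades gracefully rather than erroring.
* `max(xi) = 0` in the PCNN output yields $Y \equiv 0$ by contract.
* Halton points are deterministic; every stochastic element of the package
  (phantom noise only) is governed by an explicit seed, and the generator
  restores the caller's RNG state.
* Min-max normalization maps a constant volume to zeros (idempotent
  otherwise).

## Known limitations

* The level set is two-phase and global: it separates tooth from background
  but cannot itself separate touching foreign objects of tooth-like
  intensity (the bracket) — that burden falls on the ROI crop and the
  component filter, and a residual in-ROI bracket stub is misclassified as
  dentine.
* The PCNN is slice-wise 2D (the neuron lattice has 3×3 in-plane
  neighborhoods); no 3D coupling across slices.
* The published parameter values for both stages are not stated in the
  source description; the defaults here are justified by the analyses above
  but cannot be claimed to reproduce the original implementation run for
  run.
* No DICOM input, no anisotropic resampling, no narrow-band or GPU
  acceleration; volumes of $256^3$ work but take several minutes per
  segmentation in pure R.
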