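---
title: "Depth-based canopy phenotyping from stereo pairs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based canopy phenotyping from stereo pairs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
```

stereophyte estimates visible 3D leaf areas and fruit-to-leaf ratios of
grapevines from pairs of RGB photographs taken from two nearby vantage
points. The central difficulty it addresses is that in a vineyard the
background — other vines, foliage, soil — shares the color statistics of the
plant in front of the camera, so color segmentation alone cannot isolate the
target canopy. Depth can: the plant of interest is meters closer than the
row behind it. The package therefore reconstructs a dense depth map first
and lets depth carry the foreground/background decision, with color only
deciding organ classes within the foreground.

```{r setup}
library(stereophyte)
```

## Dense depth by functional lifting

For a rectified pair $I_1, I_2$ the per-pixel disparity $v(x) \in [0,
\gamma_{\max}]$ minimizes a matching cost $|I_1(x) - I_2(x+\gamma)|$, which
is non-convex in $\gamma$. Following the convex-relaxation approach for such
labeling problems, the disparity choice is *lifted*: a field $\phi(x,
\gamma) \in [0,1]$ over the product of image domain and disparity range
encodes, per pixel, a monotone transition from 1 to 0, pinned by the
constraints $\phi(x, 0) = 1$ and $\phi(x, \gamma_{\max}) = 0$ (without which
$\phi \equiv 0$ would be a trivial global minimum). The energy

$$E(\phi) = \sum_{x,\gamma} \rho(x,\gamma)\,|\partial_\gamma \phi|
  \;+\; \lambda \sum_{x,\gamma} |D(x)\,\nabla_{xy} \phi|$$

is convex; its global minimum is found by a first-order primal-dual scheme,
and the disparity is read off by integrating $\phi$ over the disparity axis
(`extract_disparity()`), which retains sub-level precision where the
transition is fractional. Depth follows as $d = fb/v$ with focal length $f$
in pixels and stereo baseline $b$ in world units.

Choices a user should know about:

* **The anisotropy tensor** $D = e\, n n^\top + n_\perp n_\perp^\top$ with
  $e = \exp(-\alpha |\nabla I|^\beta)$ and $n$ the gradient direction damps
  smoothing *across* image edges while leaving smoothing *along* them
  untouched, preserving petioles and leaf margins. The functional form and
  the defaults $\alpha = 5/255$, $\beta = 1$ are package choices; no
  canonical values exist for this construction.
* **$D$ acts on the spatial gradient only.** A tensor acting on the full
  3D gradient would blend data and regularity terms; keeping the
  $\gamma$-derivative exclusively in the data term matches the lifting
  construction, where the data cost is exactly the price of the
  $1 \to 0$ transition.
* **Units of $\lambda$.** Intensities (and hence matching costs) are held
  on the 0–255 scale throughout the package because the color classifier
  thresholds below are defined on that scale. $\lambda$ multiplies a term
  whose natural scale is the cost scale, so values quoted for unit-scaled
  intensities must be multiplied by 255. The default `lambda_smooth = 5`
  corresponds to roughly 0.02 per unit intensity — deliberately mild, so
  fine structure survives; heavier smoothing (20–30) suits noisy captures
  of frontoparallel scenes.
* **Discretization and steps.** Forward differences with Neumann boundary;
  the squared operator norm of the combined gradient is at most 12, and
  `solver_config()` refuses step sizes violating
  $\tau\sigma \le 1/12$. Internally the cost volume is normalized by its
  maximum (the minimizer is invariant under joint scaling of $\rho$ and
  $\lambda$), which conditions the duals to an $O(1)$ scale; all reported
  energies are on the original scale.
* **Convergence.** The scheme is not monotone iteration-by-iteration, and
  pixels whose best and second-best costs nearly tie converge slowly —
  with 8 levels, 400 iterations separate candidates that differ by at
  least one intensity unit; the default 500 is sized for that regime.
  Out-of-range samples ($x + \gamma$ past the right border) cost 255, the
  maximum channel difference, so border pixels prefer in-range disparities
  without being excluded.
* **Initialization** is winner-takes-all over levels $0..\Gamma{-}2$ (the
  top level is pinned to 0), ties to the smallest level. With
  $\lambda = 0$ the solver provably has nothing to improve and the tests
  exploit this as an exhaustive-search oracle.

## Rectification

Field captures come from a hand-guided platform, so epipolar geometry is
estimated per pair: Harris corners with normalized patch descriptors,
mutual-nearest matching under a 0.8 ratio test, a seeded RANSAC around the
normalized 8-point algorithm, and epipole-to-infinity projective
rectification with an affine correction fitted on the inliers. Lens
distortion is *not* estimated — it is under-determined from two uncalibrated
views; a degenerate correspondence set (collinear points, too few inliers)
raises a reconstruction failure rather than returning a bad model, matching
the ~5% failure rate such pipelines see in the field. The median vertical
disparity of inliers after warping (`vertical_disparity_residual()`) is the
stage's quality gate.

## Segmentation from depth and color

Three pointwise classifiers drive the four-class labeling:

* $f_{\text{depth}} = d - c_{\text{depth}}$ — positive means background.
  $c_{\text{depth}}$ (world units) depends on the capture distance and is
  required per image pair; there is deliberately no default.
* $f_{\text{color}} = \text{green} - \text{blue} - c_{\text{color}}$ — the
  green-blue difference is a robust vegetation index; $c_{\text{color}} =
  20$ on the 0–255 scale.
* $f_{\text{grape}} = \max(\text{red}-\text{green},
  \text{blue}-\text{green}) - c_{\text{grape}}$ — red *or* blue excess over
  green marks berries of red and white/blue cultivars alike. The concrete
  form is a package decision; only the qualitative rule (red/blue pixels
  are grapes) is canonical.

The decision hierarchy is: far ⇒ background; else grape-colored ⇒ grape;
else vegetation-colored ⇒ leaf; else stem — with *strict* inequalities, so
exact-boundary scores fall to the foreground/stem side deterministically.
`assemble_costs()` encodes the hierarchy as per-label scores
($s_{\text{leaf}} = \min(-f_d, f_c)$ etc.); where several scores tie
exactly, the min-saturated scores lose the ordering information, so the
cost object carries its source fields and the unregularized path
(`nu = 0`) resolves ties by the hierarchy itself. With `nu > 0` the labels
are relaxed to the probability simplex and an edge-weighted Potts energy is
minimized primal-dually; the edge weight $g = \exp(-\alpha|\nabla I|)$
reuses the stereo $\alpha$. Ties in the final argmax resolve by ascending
label index. Data costs are in intensity units, so `nu` around 0.5 only
overrides weak (near-threshold) evidence — it removes speckle, not objects.

## Phenotypes

A pixel imaging a surface at depth $d$ covers a world area of $(d/f)^2$
(the world length per pixel at depth $d$ is $d/f$), so

$$\text{Area}(\Omega_i) = \sum_{x \in \Omega_i} \left(\frac{d(x)}{f}\right)^2$$

turns label regions into 3D surface areas, correcting the
near-objects-look-bigger projection bias. This matters for fruit-to-leaf
ratios: grapes usually hang closer to the camera than the leaf wall, so 2D
pixel ratios overstate fruit. Constant depth cancels exactly (3D ratio
equals 2D ratio), and doubling all depths quadruples every 3D area while
leaving 2D quantities unchanged — both are tested identities. The 2D
digital leaf area is the leaf pixel fraction scaled to 0–100; growth series
aggregate replicate plants per genotype and day with mean and sample
(n−1) standard deviation, omitted for single replicates. Pixels without a
valid depth estimate contribute nothing to 3D areas and their count is
reported alongside.

## The synthetic world

`build_scene()` + `render_stereo()` provide ground truth no field dataset
can: exact disparities, labels, occlusion masks, and areas. The generator
emulates the structure of the real problem — a near plant (green leaf
ellipses at 2.5–4.5 world units, a brown stem band, blue grape clusters) in
front of a distant background plane (10 units) whose default color is
*vegetation-like* (green–blue ≈ 45), reproducing the core difficulty that
color alone cannot separate plant from field. The second view is rendered
from the same world with per-primitive horizontal shifts $\gamma = fb/z$
(rectified by construction), then degraded with additive Gaussian noise
(default $\sigma = 2$ intensity units) and a 2% gain mismatch.

What it does *not* emulate: slanted or curved surfaces (all primitives are
frontoparallel, keeping truth areas analytic), specular highlights, wind
motion between exposures, and natural leaf texture. Textures are
band-limited noise with a ~1-pixel correlation length and RMS contrast 20:
coarser textures would leave adjacent disparity candidates differing by
less than the noise floor (aperture ambiguity), defeating the purpose of
texturing the scene. A green test on this world therefore establishes the
*machinery* — global optimization, calibrated geometry, area algebra — not
photometric robustness on real vineyards.

```{r example, eval = FALSE}
scene <- build_scene(width = 96, height = 96, seed = 1)
r <- render_stereo(scene)
cv <- compute_cost_volume(r$left, r$right, r$geom)
phi <- solve_lifted(cv, compute_anisotropy(r$left),
                    solver_config(iterations = 300))
d <- disparity_to_depth(extract_disparity(phi, r$geom), r$geom)
seg <- segment_image(r$left, d, segmentation_config(c_depth = 6))
autoplot(seg)
phenotype_record(seg, d, r$geom, "vine_1", 180)
```

## Degenerate inputs and numerical conventions

* Invalid pixels (unreliable depth, out-of-frame warps) travel in explicit
  masks, never as sentinel values; disparities below a quarter level
  (`v_min`) are marked invalid rather than mapped to huge depths.
* A zero leaf area makes the fruit-to-leaf ratio an error
  (`stereophyte_undefined_ratio`), and NA in `phenotype_record()` — never 0.
* Confusion-matrix rows for absent ground-truth classes are NA, not 0;
  grapes are excluded from the default three-class evaluation.
* The leaf-area regression runs ground truth on prediction (the fitted line
  predicts true area from a segmentation result); the reverse orientation
  is available via a flag. A constant predictor raises a degenerate-
  regression error.
* The baseline's world unit is a convention (meters in the examples); all
  outputs scale accordingly and nothing downstream assumes a unit.
* Scalar rasters are written as PFM (32-bit float, NaN for invalid pixels,
  bit-exact roundtrip); label maps as paletted PNG with a CSV legend.

## Known limitations

Leaf/stem discrimination is purely color-based; brown-green confusion under
extreme illumination would need geometric cues, which are out of scope, as
are occlusion modeling and left-right consistency checks in the stereo
stage, wire/trellis detection, and GPU-scale resolutions — the package
targets correctness at desk scale.
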