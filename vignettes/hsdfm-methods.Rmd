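---
title: "Classifying tissue types in hyperspectral dark-field microscopy cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissue types in hyperspectral dark-field microscopy cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdfm)
```

## The problem

Hyperspectral dark-field microscopy (HSDFM) records, for one microscopic
field of view, a stack of images at contiguous wavelength bands — a *data
cube* `I(m, n, lambda)`. Oblique illumination outside the objective's
collection cone rejects the specular beam, so contrast comes from light
backscattered in the upper tissue layers. Different breast-tissue
components — fat, blood, interconnected fibrous tissue (ICT), epithelium,
and carcinoma subtypes such as invasive ductal (IDC) and invasive mucinous
(IMC) carcinoma — backscatter with distinct spectral shapes, which makes
pixel-level tissue classification possible on fresh, unstained lumpectomy
specimens. This package implements the full analysis chain around that
idea: reflectance normalization, supervised spectral-angle classification
with thresholds calibrated against reference cubes, unsupervised K-means
unmixing, cross-validation of the two routes, and a Mie/Monte-Carlo
optical model of the bead phantoms used to validate the instrument.

Because real tissue cubes are not redistributable, the package ships a
synthetic scene generator whose templates reproduce the qualitative
spectral features reported for each tissue class. Everything downstream is
exercised — and its accuracy quantified — on those scenes.

## Reflectance cubes

A raw acquisition consists of a sample cube, a dark cube, and a white
reflectance-standard (reference) cube, each with per-band exposure times
`tau(lambda)` chosen to fill the camera's dynamic range. `normalize_cube()`
forms

$$X(m,n,\lambda) = \frac{I(m,n,\lambda)/\Delta\tau_1 -
I_{dark}(\lambda)/\Delta\tau_2}{I_{ref}(\lambda)/\Delta\tau_3 -
I_{dark}(\lambda)/\Delta\tau_4},$$

with the reference spectrum averaged over its field of view. Each cube
keeps its own exposure vector; the two dark terms may carry different
exposures but default to one dark acquisition. Negative numerator values
(dark exceeding signal in a dim band) are kept rather than clipped so the
linear mixing model stays linear; clipping is a display concern.

**Spatial flattening.** Long-range illumination non-uniformity (sample
tilt, vignetting) multiplies every pixel spectrum by a smooth spatial
factor. `flatten_cube()` estimates that factor as the unit-mean
Gaussian-blurred copy of the image (default `sigma = 50` pixels,
anisotropic sigma allowed) and divides it out, iterating
estimate-and-divide until the residual field is unity within `1e-5`; the
iteration makes the operator idempotent in practice (a second application
changes values by well under 0.1%). Two modes exist:

* `"broadband"` (default): one field is estimated from the band-mean
  image and divided out of all bands. Every pixel spectrum is scaled by a
  single positive number, so spectral shapes — and therefore all spectral
  angles, segmentations and thresholds — are *exactly* unchanged.
* `"per_band"`: an independent field per band, able to remove
  band-specific vignetting, at the cost of distorting the spectra of
  scenes that carry genuine long-range structure (a large fat lobule is
  long-range structure too, and a per-band field absorbs part of it).

Broadband is the default precisely because an iterated per-band field
converges onto real regional contrast: on test scenes it visibly
reorganized the K-means clusters by position rather than tissue. When
band-specific shading is the dominant artifact, `per_band` with a larger
sigma is the right tool. Band means are restored after division in both
modes, so flattening never changes a cube's overall radiometry.

## Supervised route: SAM with orthogonalized thresholds

An *endmember* is the mean spectrum over an annotated region of one
tissue type (`extract_endmember()`, which also records the per-band
spread and pixel count). The spectral correlation angle (SCA) between a
pixel spectrum and an endmember,

$$\alpha_i(m,n) = \cos^{-1}\frac{\vec X(m,n)\cdot\vec\mu_i}
{\lVert\vec X(m,n)\rVert\,\lVert\vec\mu_i\rVert},$$

is scale-invariant and lives in `[0, pi/2]`; zero-norm pixels are mapped
to `pi/2` and counted. A tissue map thresholds the angle map strictly:
pixel classified if `alpha < alpha_th`.

**Choosing the threshold.** Without a pixel-registered ground truth the
threshold is calibrated against a *reference cube* known to contain none
of the endmember's tissue: a fat-only cube for all non-fat endmembers and
a fat-free (fibroadenoma-like) cube for fat. The fill-factor curve
`f(beta)` — the fraction of reference pixels whose angle to the endmember
is at or below a sweeping threshold — rises sigmoidally to 1. The
orthogonalized SCA (OSCA) is the largest grid threshold that no reference
pixel falls strictly below, i.e. the minimum observed reference angle
rounded *down* to the threshold grid (default 0 to pi/2 in 0.01 rad
steps). This rounding direction is what makes the construction's
guarantee exact: segmenting the reference cube at its own OSCA yields
zero positive pixels, so the threshold admits no false positives of that
type on tissue known to lack it. Rounding up instead would admit the
minimum-angle pixel whenever the minimum falls off-grid. Thresholds
remain overridable per type (`threshold_overrides`) for the situations
where a tighter or looser sweep is wanted.

The integrated map assigns each pixel, among the types whose threshold it
passes, the type of *minimum* angle; ties (possible only at exactly equal
angles) go to the earlier library entry and are counted. Pixels passing
no threshold are background. The per-type area is nondecreasing in the
threshold and the min-rule can only shrink a type's solo segmentation.

## Unsupervised route: K-means and NNLS abundances

The cube (or several stacked cubes) becomes an `n x p` pixel matrix.
`kmeans_endmembers()` runs Lloyd's algorithm on the raw reflectance rows
(no per-pixel normalization — amplitude is informative), with `k = 5` and
10 random restarts by default; initial centers are drawn uniformly from
the distinct rows, empty clusters are re-seeded from the farthest point,
iterations stop when assignments stabilize or after 300 rounds, and the
restart with the lowest within-cluster sum of squares wins. The
"abundance" of each cluster is then refined from the hard assignment to a
continuous value by non-negative least squares per pixel:

$$m_j = \arg\min_{m \ge 0}\lVert U m - X_{j\cdot}^T\rVert_2,$$

with `U` the matrix of cluster centroids (Lawson–Hanson active set).
Abundances are deliberately not normalized to sum to one; only
nonnegativity is imposed. Clusters are ranked by their share of the
between-cluster variance (size-weighted squared centroid distance from
the global mean), the reading we adopt for "fraction of variance
explained by each cluster"; pixel-count share and within-cluster share
are the other candidates and are recoverable from the returned sizes and
objective.

## Cross-validating the two routes

`match_endmembers()` pairs centroids with library entries greedily by
ascending spectral angle (cap 0.3 rad). For each pair the *residual
ratio* is computed bandwise, in the printed argument order,

$$r(\lambda) = \frac{\mu^{sup}(\lambda) - \mu^{unsup}(\lambda)}
{\mu^{unsup}(\lambda)},$$

after normalizing both spectra to equal band-mean (toggleable): the
supervised endmember is scale-free by construction while a centroid
carries amplitude, and without alignment the ratio conflates gain with
shape. The headline agreement property is that the carcinoma pairs stay
below 2% in maximum absolute residual. Spatial agreement is scored with
a Dice coefficient between the supervised binary map and the abundance
map thresholded at half its maximum — colocalization is conventionally
judged visually, so the quantitative rule here is this package's own and
its threshold is exposed.

## The synthetic scene generator

`make_paper_templates()` returns ten analytic reflectance shapes on the
480–650 nm, 5 nm grid: blood (two oxyhemoglobin dips at 540/575 nm on a
red-rising base), fat (sigmoidal rise below ~550 nm, nearly flat above),
three ICT variants and an epithelium (net negative slope, 3–4% ripple,
reduced for epithelium), and four carcinoma shapes (IDC: broad shallow
510–610 nm depression; phyllodes: deeper and narrower; IMC and ILC:
concave-down humps red- and blue-shifted respectively). The analytic
forms are this package's invention constrained by the qualitative
descriptions — no quantitative tissue spectra are published — and their
free constants were fixed once so that all pairwise spectral angles
exceed 0.1 rad (the achieved minimum is 0.126 rad), giving classifiers
realistic but non-trivial contrast.

`generate_cube()` builds, per pixel, the linear mixture of templates
(weights nonnegative, summing to at most 1 per region), multiplies by a
smooth illumination field (default a ±10% tilt-plus-vignetting surface)
and a synthetic lamp-times-sensor response, adds a constant dark-current
rate, and converts to counts with per-band exposure scans, so that
`normalize_cube()` recovers the planted mixture exactly at zero noise.
Noise is multiplicative Gaussian on the signal (a shot-noise proxy;
Poisson counts would add realism but none of the classifiers here are
sensitive to the distinction at the 2% level used). Reference cubes for
the OSCA analysis are single-template cubes with uniform per-pixel
amplitude texture (0.7–1.3), exercising the scale-invariance of the
angle machinery. Fixed seeds make every cube byte-reproducible.

What the generator does *not* emulate: spatial texture within tissue
(regions are homogeneous), instrument point-spread, wavelength-dependent
illumination shape beyond the lamp curve, and spectral variability
between patients. Passing tests therefore demonstrate the correctness
and internal consistency of the algorithms under the stated statistical
model, not clinical performance.

**The carcinoma validation scene** (`carcinoma_validation_scene()`) is
the standard 128 x 128 configuration for the supervised/unsupervised
agreement check: blood and fat blocks, IDC and IMC discs (solid pure
masses, as an infiltrating carcinoma presents), ICT background — five
pure populations matching the five clusters sought, each at least 10% of
the frame, 2% noise. Planting exactly five populations is deliberate: a
mixed transition region would be a sixth population that `k = 5` must
absorb into its nearest cluster, biasing whichever centroid happens to be
spectrally closest; mixing is exercised instead in dedicated scenes where
the endmember matrix matches the population count.

## Phantom optics

Instrument validation uses dilute polystyrene-bead phantoms. For a
368 nm sphere the Lorenz–Mie series (truncated at the standard
`x + 4x^{1/3} + 2` terms) gives the scattering efficiency, asymmetry
`g(lambda)`, and phase function; refractive indices come from standard
Cauchy fits for polystyrene (Ma et al.-type coefficients) and water,
pinned in `ri_polystyrene()` / `ri_water()` so results are reproducible
from the repository alone. Independent scattering gives
`mu_s = rho Q_sca sigma_g` (number density times efficiency times
geometric cross-section), hence `mu_s' = mu_s (1 - g)` exactly — and
exactly linear in volume fraction, the property the phantom dilution
series verifies.

The Monte Carlo model launches photons at 15 degrees over a 5 mm source
disc onto a semi-infinite medium, samples free paths from `mu_t`,
scatters by inverse-CDF sampling of the tabulated Mie phase function
(1024-point cosine grid — not Henyey–Greenstein, since the bead phase
function is known exactly), applies absorption as survival weighting,
and collects photons exiting within the 1.6 mm field of view at polar
angles inside `asin(NA/n)` with `NA = 0.13`, `n = 1.33`. The boundary is
refractive-index matched; a Fresnel boundary was considered and left out
because the acquisition geometry (coverslip, immersion state) needed to
parameterize it honestly is not recorded, and the phantom analyses here
compare like with like through the same model. Photons diffusing deeper
than 10 mm (many transport lengths) or exceeding 20 000 steps are tallied
as transmitted: their chance of re-entering the 5.6-degree collection
cone within the field of view is negligible, and the truncation changes
the collected reflectance by about one standard error at 2e5 photons
while bounding the heavy tail of walk lengths. Weight is conserved to
1e-9 across the collected/escaped/truncated/absorbed tallies, and a
fixed seed reproduces results bit-for-bit (the sampler runs on R's RNG).

The reflectance look-up table `R(phi, lambda)` spans volume fractions
0.0005–0.005 (step 0.0005) and 400–800 nm (step 25 nm) by default, with
per-cell Monte Carlo standard errors and a companion `mu_s'` table.
Inversion of a measured spectrum interpolates linearly between rows —
piecewise-linear in the mixing parameter, so each interval's optimum is
closed-form — and is exact on grid nodes. Desk-scale photon budgets
(1e5–1e6 per cell) suffice for the monotonicity and recovery properties
tested; the standard error scales as the inverse square root of the
photon count, so tighter LUTs are a matter of budget, not code.

## Numerical choices and degenerate inputs

* Threshold grid 0 to pi/2 in 0.01 rad steps, endpoint included; a
  published sweep specified as `0.05 n` overshoots pi/2 under a radian
  reading, so the finer grid subsumes it and the unit question is moot.
* Strict inequality in segmentation (`alpha < alpha_th`): boundary
  pixels are excluded, matching the printed rule.
* Zero-norm pixels: angle pi/2, never classified, counted in the map.
* Min-angle ties in the integrated map: earlier library entry, counted.
* Empty K-means clusters: re-seeded from the point farthest from its
  assigned center; occurrences are reported.
* NNLS with rank-deficient endmember matrices warns and returns the
  (well-posed) solution.
* The K-means seed is a required, recorded input (default 0), and scene
  seeds live in the scene specification, so a run config reproduces its
  outputs exactly; manifests record config and artifact checksums.

## Problem sizes

The shipped tests run the full agreement check at 128 x 128 pixels, 35
bands, ten replicate seeds, `k = 5` with 10 restarts; oracle-equivalence
checks run at 16 x 16 or smaller where brute force is exact; Monte Carlo
properties use 1e6 photons for the ordering check and 2e4–1e5 per LUT
cell. These sizes were chosen so each property is measured well inside
its tolerance while the whole suite stays interactive.

## Known limitations

* Synthetic templates are qualitative stand-ins; absolute spectra,
  patient variability and intra-region texture are not modeled.
* The OSCA guarantee is exact on the reference cube used to set it;
  on new cubes it controls false positives only insofar as the reference
  represents the confusable tissue.
* Broadband flattening cannot remove band-specific shading; per-band
  mode can, but trades spectral fidelity on structured scenes.
* K-means with 10 uniform-random restarts occasionally converges to a
  merged local optimum on scenes whose largest cluster is worth
  splitting (roughly one run in ten at the validation-scene conditions;
  the merged solution's objective is clearly worse, 1069 vs 925 in one
  measured case, so more restarts recover the true partition). The
  matched spectral angle in the cross-validation report exposes such
  runs: a contaminated centroid matches its library endmember at an
  angle orders of magnitude above a clean one.
* The Monte Carlo model is scalar (no polarization), semi-infinite, and
  index-matched at the boundary; its reflectances are internally
  consistent rather than radiometrically absolute.
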