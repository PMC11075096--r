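# hsdfm

Tissue-type classification for hyperspectral dark-field microscopy
(HSDFM) data cubes, aimed at pixel-level delineation of carcinoma
regions in fresh breast lumpectomy specimens — and at anyone who needs a
tested, reproducible implementation of the underlying data-cube
analysis chain.

An HSDFM acquisition is a cube `I(m, n, λ)` of dark-field backscattering
images over 480–650 nm (5 nm steps, 35 bands). The package implements:

* **Reflectance construction** — per-band exposure normalization against
  dark and white-standard cubes,
  `X = (I/Δτ₁ − I_dark/Δτ₂) / (I_ref/Δτ₃ − I_dark/Δτ₄)`,
  plus iterative Gaussian flattening of long-range illumination
  non-uniformity and pseudo-color rendering (630/530/480 nm → RGB).
* **Supervised classification** — spectral angle mapper (SAM): the
  spectral correlation angle
  `α_i(m,n) = cos⁻¹( X·μ_i / (‖X‖‖μ_i‖) )`
  between each pixel and ROI-extracted endmembers `μ_i`; per-type
  segmentation by strict thresholding; thresholds calibrated as
  *orthogonalized* SCAs (OSCA) against reference cubes guaranteed free of
  the target tissue, which makes false positives on the reference exactly
  zero; integrated multi-type maps by the minimum-angle rule.
* **Unsupervised unmixing** — seeded Lloyd K-means (`k = 5`, 10
  restarts) on the pixel matrix, cluster ranking by between-cluster
  variance share, and per-pixel non-negative least squares abundances
  `m_j = argmin_{m≥0} ‖U m − x_j‖₂` against the discovered centroids.
* **Cross-validation** — greedy spectral-angle matching of centroids to
  library endmembers, the bandwise residual ratio
  `(μ_sup − μ_unsup)/μ_unsup` with a <2 % agreement verdict, and Dice
  colocalization of segmentations with abundance maps.
* **Phantom optics** — Lorenz–Mie scattering of polystyrene beads
  (368 nm default), bulk `μ_s`, `g`, `μ_s′ = μ_s(1−g)` in the dilute
  independent-scattering regime, a seeded Monte Carlo model of
  dark-field reflectance (15° incidence, collection within
  `asin(NA/n)`), reflectance look-up tables over volume fraction and
  wavelength, and closed-form LUT inversion back to volume fraction.
* **Synthetic scenes** — tissue-like spectral templates (blood, fat,
  ICT variants, epithelium, IDC/IMC/ILC/phyllodes) and a forward model
  of the acquisition (exposure scans, lamp response, dark current,
  illumination tilt, multiplicative noise) with planted ground truth, so
  the whole chain is testable without instrument data.

File I/O covers ENVI rasters (BSQ write; BSQ/BIL/BIP read), multi-page
TIFF stacks with JSON sidecars, JSON endmember libraries, text LUTs, and
YAML scene/run configurations with checksummed run manifests.

## Worked example

Generate the standard carcinoma validation scene (128 × 128, five planted
tissue types, 2 % noise), run both classification routes, and
cross-validate them:

```r
library(hsdfm)

scene <- carcinoma_validation_scene(seed = 0)
cfg   <- run_config(scene, k = 5, restarts = 10, seed = 0)
res   <- run_crossval(cfg)

print(res$supervised$library)
#> <endmember_library> 5 entries (hsdfm-library-1)
#>   blood        OSCA 0.2400  threshold 0.2400  ref 1  (2500 px)
#>   fat          OSCA 0.3200  threshold 0.3200  ref 2  (2500 px)
#>   ICT1         OSCA 0.3300  threshold 0.3300  ref 1  (7142 px)
#>   IDC          OSCA 0.3500  threshold 0.3500  ref 1  (2121 px)
#>   IMC          OSCA 0.1100  threshold 0.1100  ref 1  (2121 px)

print(res$report)
#> <match_report>
#>  label cluster        angle max_residual dice pass
#>    IMC       1 0.000000e+00            0    1 TRUE
#>    IDC       2 0.000000e+00            0    1 TRUE
#>  blood       3 0.000000e+00            0    1 TRUE
#>    fat       4 2.107342e-08            0    1 TRUE
#>   ICT1       5 2.107342e-08            0    1 TRUE
```

Reading the output: each library entry carries its endmember's OSCA —
the largest threshold angle at which its reference cube (fat-only for
non-fat tissues, a fat-free cube for fat) shows zero false positives —
and the ROI pixel count behind the mean spectrum. The match report pairs
every K-means centroid with a library endmember (`angle`, in radians),
gives the worst bandwise residual ratio between the two spectra
(`max_residual`; the carcinoma pairs here agree to far better than the
2 % margin), and the Dice overlap between the supervised segmentation
and the cluster's thresholded abundance map. `pass` combines the <2 %
residual with a Dice floor of 0.5.

The phantom side in three lines:

```r
op  <- bulk_optical_properties(bead_phantom(368, 0.003), seq(400, 800, 25))
mie <- mie_single_sphere(368, ri_polystyrene(550), ri_water(550), 550, phase = TRUE)
mc  <- mc_darkfield_reflectance(op$mus[7], phase = mie, photons = 1e6, seed = 1)
```

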