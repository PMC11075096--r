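#' Spectral template of a tissue type
#'
#' A strictly positive reflectance spectrum on a shared wavelength grid,
#' used by the synthetic scene generator as a stand-in endmember.
#'
#' @param label Tissue-type name.
#' @param spectrum Strictly positive numeric vector, one value per band.
#' @param grid A \code{\link{wavelength_grid}}.
#' @param provenance \code{"paper-shape"} for the built-in tissue-like
#'   shapes, \code{"user"} otherwise.
#' @return An object of class \code{spectral_template}.
#' @export
spectral_template <- function(label, spectrum, grid = wavelength_grid(),
                              provenance = "user") {
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != length(grid))
    stop("spectrum length must match the wavelength grid")
  if (any(!is.finite(spectrum)) || any(spectrum <= 0))
    stop("template spectrum must be strictly positive")
  structure(list(label = as.character(label), spectrum = spectrum,
                 grid = grid, provenance = provenance),
            class = "spectral_template")
}

#' @export
print.spectral_template <- function(x, ...) {
  cat(sprintf("<spectral_template> %s (%s), %d bands\n",
              x$label, x$provenance, length(x$spectrum)))
  invisible(x)
}

#' Built-in tissue-like spectral templates
#'
#' Analytic reflectance shapes emulating the qualitative spectral features
#' of breast-tissue backscattering in dark-field microscopy: blood carries
#' two oxy-hemoglobin absorption dips near 540 and 575 nm on a red-rising
#' baseline; fat rises sigmoidally below 550 nm and is nearly flat above;
#' three interconnected-tissue (ICT) variants and an epithelium share an
#' overall negative slope with a few-percent local ripple (weaker for
#' epithelium); four carcinoma shapes (IDC, phyllodes, IMC, ILC) carry
#' broad mid-band depressions or concave-down humps at distinct
#' wavelengths. The shapes are mutually separated by a pairwise spectral
#' angle of at least 0.1 rad so that classifiers can be exercised at
#' realistic contrast.
#'
#' @param grid A \code{\link{wavelength_grid}}; templates are evaluated at
#'   its band centers.
#' @return Named list of \code{\link{spectral_template}} objects:
#'   \code{blood}, \code{fat}, \code{ICT1}, \code{ICTb}, \code{ICTf},
#'   \code{epi}, \code{IDC}, \code{phyllodes}, \code{IMC}, \code{ILC}.
#' @export
#' @examples
#' tpl <- make_paper_templates()
#' names(tpl)
make_paper_templates <- function(grid = wavelength_grid()) {
  wl <- grid$wavelengths
  u <- (wl - 480) / 170          # 0..1 across the default grid
  dip <- function(center, width, depth)
    1 - depth * exp(-((wl - center)^2) / (2 * width^2))
  ripple <- function(period, phase, amp)
    1 + amp * sin(2 * pi * (wl - 480) / period + phase)

  shapes <- list(
    # two Hb dips on a baseline rising toward the red
    blood = (0.35 + 0.45 * u) * dip(540, 8, 0.45) * dip(575, 9, 0.35),
    # sigmoidal rise below ~550 nm, nearly flat above
    fat = 0.28 + 0.65 / (1 + exp(-(wl - 515) / 12)),
    # ICT family: net negative slope, 3-4% ripple, distinct slopes/curvature
    ICT1 = (0.88 - 0.22 * u) * ripple(53, 0.0, 0.035),
    ICTb = (0.72 - 0.48 * u) * ripple(70, 1.2, 0.040),
    ICTf = (0.98 - 1.34 * u + 0.92 * u^2) * ripple(45, 2.4, 0.030),
    # epithelium: ICT-like with reduced ripple, mild concavity
    epi = (0.82 + 0.26 * u - 0.73 * u^2) * ripple(60, 0.7, 0.012),
    # carcinoma shapes: broad 510-610 nm depression (IDC shallow/broad,
    # phyllodes deeper/narrower), concave-down humps (IMC red-shifted,
    # ILC blue-shifted)
    IDC = (0.84 - 0.17 * u) * dip(555, 38, 0.32),
    phyllodes = (0.80 - 0.10 * u) * dip(545, 20, 0.56),
    IMC = 0.40 + 0.38 * exp(-((wl - 592)^2) / (2 * 48^2)),
    ILC = 0.34 + 0.44 * exp(-((wl - 516)^2) / (2 * 34^2))
  )
  mapply(function(label, s) spectral_template(label, s, grid, "paper-shape"),
         names(shapes), shapes, SIMPLIFY = FALSE)
}

#' Pairwise spectral angles between templates
#'
#' @param templates List of \code{\link{spectral_template}} objects.
#' @return Symmetric matrix of spectral angles in rad.
#' @export
template_angle_matrix <- function(templates) {
  n <- length(templates)
  labs <- vapply(templates, `[[`, character(1), "label")
  a <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    a[i, j] <- spectral_angle(templates[[i]]$spectrum,
                              templates[[j]]$spectrum)
  a
}
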