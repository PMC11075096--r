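#' Wavelength grid of a hyperspectral acquisition
#'
#' Defines the band centers (nm) shared by every cube in an analysis. The
#' instrument default is 480 to 650 nm in 5 nm steps (35 bands) with an
#' 8 nm filter bandwidth.
#'
#' @param wavelengths Numeric vector of band centers in nm, strictly
#'   increasing.
#' @param bandwidth Filter bandwidth (FWHM) in nm.
#' @return An object of class \code{wavelength_grid}.
#' @export
#' @examples
#' g <- wavelength_grid()
#' length(g$wavelengths)  # 35
wavelength_grid <- function(wavelengths = seq(480, 650, by = 5),
                            bandwidth = 8) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || anyNA(wavelengths))
    stop("wavelengths must be a non-empty numeric vector")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive")
  structure(list(wavelengths = wavelengths, bandwidth = bandwidth),
            class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$wavelengths)

#' @export
print.wavelength_grid <- function(x, ...) {
  wl <- x$wavelengths
  cat(sprintf("<wavelength_grid> %d bands, %g-%g nm (bandwidth %g nm)\n",
              length(wl), min(wl), max(wl), x$bandwidth))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "cubes") {
  if (!same_grid(a, b))
    stop(sprintf("configuration error: %s do not share a wavelength grid",
                 what))
  invisible(TRUE)
}

# index of a band center, NA if absent
band_index <- function(grid, wavelength, tol = 1e-6) {
  i <- which(abs(grid$wavelengths - wavelength) <= tol)
  if (length(i) == 0L) NA_integer_ else i[1L]
}
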