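#' Refractive index of polystyrene (Cauchy dispersion)
#'
#' Standard Cauchy fit for polystyrene microspheres in the visible,
#' n = 1.5663 + 0.00785/lambda^2 + 0.000334/lambda^4 (lambda in um).
#'
#' @param wavelength Wavelength in nm (vectorized).
#' @return Refractive index.
#' @export
ri_polystyrene <- function(wavelength) {
  lu <- wavelength / 1000
  1.5663 + 0.00785 / lu^2 + 0.000334 / lu^4
}

#' Refractive index of water (Cauchy dispersion)
#'
#' Two-term Cauchy fit, n = 1.3241 + 0.0033946/lambda^2 (lambda in um),
#' accurate to a few 1e-4 across the visible.
#'
#' @param wavelength Wavelength in nm (vectorized).
#' @return Refractive index.
#' @export
ri_water <- function(wavelength) {
  lu <- wavelength / 1000
  1.3241 + 0.0033946 / lu^2
}

#' Polystyrene-bead liquid phantom
#'
#' @param diameter Sphere diameter in nm.
#' @param volume_fraction Bead volume fraction (dilute regime, below 0.01).
#' @param n_sphere,n_medium Refractive index functions of wavelength (nm);
#'   default polystyrene in water.
#' @param mua Absorption coefficient in 1/mm (scalar or function of nm);
#'   default 0.
#' @return Object of class \code{bead_phantom}.
#' @export
bead_phantom <- function(diameter = 368, volume_fraction = 0.003,
                         n_sphere = ri_polystyrene, n_medium = ri_water,
                         mua = 0) {
  if (diameter <= 0) stop("diameter must be positive")
  if (!(volume_fraction > 0 && volume_fraction < 0.01))
    stop("volume fraction must lie in (0, 0.01) (dilute regime)")
  mua_fun <- if (is.function(mua)) mua else function(wl) rep(mua, length(wl))
  if (any(mua_fun(500) < 0)) stop("mua must be nonnegative")
  structure(list(diameter = diameter, volume_fraction = volume_fraction,
                 n_sphere = n_sphere, n_medium = n_medium, mua = mua_fun),
            class = "bead_phantom")
}

#' Lorenz-Mie solution for a homogeneous sphere
#'
#' Computes the scattering efficiency Q_sca and asymmetry parameter g for
#' a non-absorbing homogeneous sphere in a non-absorbing medium, with the
#' series truncated at the standard x + 4 x^(1/3) + 2 term count. The
#' unpolarized phase function can be returned on a cosine grid for Monte
#' Carlo sampling.
#'
#' @param diameter Sphere diameter in nm.
#' @param n_s,n_m Sphere and medium refractive indices at this wavelength
#'   (scalars).
#' @param wavelength Vacuum wavelength in nm.
#' @param phase Logical; also tabulate the phase function.
#' @param n_mu Number of cosine-grid points for the phase table.
#' @return List with \code{q_sca}, \code{g}, \code{x} (size parameter),
#'   and when \code{phase} is TRUE: \code{mu} (cosine grid) and
#'   \code{p} (phase function, normalized so its mean over mu is 1).
#' @export
mie_single_sphere <- function(diameter, n_s, n_m, wavelength,
                              phase = FALSE, n_mu = 1024) {
  if (diameter <= 0 || wavelength <= 0 || n_s <= 0 || n_m <= 0)
    stop("inputs must be positive")
  x <- pi * diameter * n_m / wavelength
  if (!is.finite(x)) stop("size parameter not finite")
  m <- n_s / n_m
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  if (nmax < 1 || nmax > 1e5) stop("non-convergent series: pathological inputs")

  # logarithmic derivative D_n(mx) by downward recurrence
  mx <- m * x
  nstart <- nmax + 15L
  D <- numeric(nstart)
  for (n in seq(nstart - 1L, 1L)) {
    rn <- (n + 1) / mx
    D[n] <- rn - 1 / (D[n + 1L] + rn)
  }
  D <- D[1:nmax]

  # Riccati-Bessel psi, chi upward; xi = psi - i*chi
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  a <- complex(nmax); b <- complex(nmax)
  psi_nm1 <- psi_0; psi_nm2 <- psi_m1
  chi_nm1 <- chi_0; chi_nm2 <- chi_m1
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi_n <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    ta <- D[n] / m + n / x
    tb <- D[n] * m + n / x
    a[n] <- (ta * psi_n - psi_nm1) / (ta * xi_n - xi_nm1)
    b[n] <- (tb * psi_n - psi_nm1) / (tb * xi_n - xi_nm1)
    psi[n] <- psi_n; chi[n] <- chi_n
    psi_nm2 <- psi_nm1; psi_nm1 <- psi_n
    chi_nm2 <- chi_nm1; chi_nm1 <- chi_n
  }

  n <- seq_len(nmax)
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  # asymmetry parameter
  gsum <- 0
  if (nmax > 1) {
    n1 <- seq_len(nmax - 1L)
    gsum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                  Re(a[n1] * Conj(a[n1 + 1L]) + b[n1] * Conj(b[n1 + 1L])))
  }
  gsum <- gsum + sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- if (q_sca > 0) (4 / x^2) * gsum / q_sca else 0

  out <- list(q_sca = q_sca, g = g, x = x)
  if (phase) {
    mu <- seq(-1, 1, length.out = n_mu)
    S1 <- complex(length.out = n_mu)
    S2 <- complex(length.out = n_mu)
    pi_nm1 <- rep(0, n_mu)   # pi_0
    pi_n <- rep(1, n_mu)     # pi_1
    for (nn in seq_len(nmax)) {
      tau_n <- nn * mu * pi_n - (nn + 1) * pi_nm1
      fac <- (2 * nn + 1) / (nn * (nn + 1))
      S1 <- S1 + fac * (a[nn] * pi_n + b[nn] * tau_n)
      S2 <- S2 + fac * (a[nn] * tau_n + b[nn] * pi_n)
      pi_np1 <- ((2 * nn + 1) * mu * pi_n - (nn + 1) * pi_nm1) / nn
      pi_nm1 <- pi_n
      pi_n <- pi_np1
    }
    p <- Mod(S1)^2 + Mod(S2)^2
    # normalize to unit mean over the cosine grid (trapezoid)
    w <- rep(1, n_mu); w[c(1, n_mu)] <- 0.5
    p <- p / (sum(p * w) / sum(w))
    out$mu <- mu
    out$p <- p
  }
  out
}

#' Bulk optical properties of a dilute bead phantom
#'
#' Independent-scattering model: the number density follows from the
#' volume fraction and sphere volume, mu_s = density x Q_sca x geometric
#' cross-section, and mu_s' = mu_s (1 - g). Linear in volume fraction by
#' construction.
#'
#' @param phantom A \code{\link{bead_phantom}}.
#' @param wavelengths Wavelength grid in nm (default 400-800 nm, 25 nm
#'   steps).
#' @return Object of class \code{optical_properties}: data.frame-like list
#'   with \code{wavelength}, \code{mus}, \code{g}, \code{musp}, \code{mua}
#'   (all per mm), plus \code{phantom}.
#' @export
bulk_optical_properties <- function(phantom,
                                    wavelengths = seq(400, 800, by = 25)) {
  stopifnot(inherits(phantom, "bead_phantom"))
  d_mm <- phantom$diameter * 1e-6
  sphere_vol <- pi / 6 * d_mm^3              # mm^3
  density <- phantom$volume_fraction / sphere_vol   # 1/mm^3
  cross <- pi * (d_mm / 2)^2                 # mm^2
  mus <- numeric(length(wavelengths))
  g <- numeric(length(wavelengths))
  for (i in seq_along(wavelengths)) {
    wl <- wavelengths[i]
    mie <- mie_single_sphere(phantom$diameter, phantom$n_sphere(wl),
                             phantom$n_medium(wl), wl)
    mus[i] <- density * mie$q_sca * cross
    g[i] <- mie$g
  }
  structure(list(wavelength = wavelengths, mus = mus, g = g,
                 musp = mus * (1 - g), mua = phantom$mua(wavelengths),
                 phantom = phantom),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> %d wavelengths, musp %.3g-%.3g /mm\n",
              length(x$wavelength), min(x$musp), max(x$musp)))
  invisible(x)
}
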