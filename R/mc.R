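#' Dark-field illumination/collection geometry
#'
#' The microscope's Monte Carlo geometry: a 5 mm source disc illuminating
#' at 15 degrees incidence, collection through a 1.6 mm field of view
#' within the objective acceptance cone of half-angle asin(NA/n). The
#' dark-field condition requires the collection half-angle to stay below
#' the incidence angle, so the specular beam is rejected.
#'
#' @param incidence_deg Beam incidence angle from the surface normal.
#' @param source_diameter Source disc diameter in mm.
#' @param na Objective numerical aperture.
#' @param n_medium Refractive index used in the acceptance-cone formula.
#' @param fov_diameter Collection field-of-view diameter in mm.
#' @return Object of class \code{darkfield_geometry}.
#' @export
darkfield_geometry <- function(incidence_deg = 15, source_diameter = 5,
                               na = 0.13, n_medium = 1.33,
                               fov_diameter = 1.6) {
  half_angle <- asin(na / n_medium)
  if (half_angle >= incidence_deg * pi / 180)
    stop("dark-field condition violated: collection half-angle >= incidence angle")
  structure(list(incidence = incidence_deg * pi / 180,
                 source_radius = source_diameter / 2,
                 na = na, n_medium = n_medium,
                 collection_half_angle = half_angle,
                 fov_radius = fov_diameter / 2),
            class = "darkfield_geometry")
}

#' Monte Carlo dark-field reflectance at one wavelength
#'
#' Simulates photon random walks in a semi-infinite medium with the given
#' scattering/absorption coefficients and tabulated Mie phase function,
#' and returns the reflectance: collected photon weight over launched
#' photons, with its Monte Carlo standard error. Seeded through R's RNG,
#' bit-reproducible.
#'
#' @param mus,mua Scattering and absorption coefficients in 1/mm.
#' @param phase List with \code{mu} (cosine grid) and \code{p} (phase
#'   function) from \code{\link{mie_single_sphere}}; ignored when
#'   \code{mus} is 0.
#' @param geom A \code{\link{darkfield_geometry}}.
#' @param photons Number of photons to launch (default 1e6).
#' @param seed Optional integer seed applied via \code{set.seed}.
#' @param max_depth Depth cutoff in mm; photons diffusing deeper are
#'   tallied as transmitted (default 10 mm, several transport lengths for
#'   the bead phantoms; the deep tail cannot re-enter the narrow
#'   collection cone at meaningful weight).
#' @param max_steps Per-photon step cap (default 2e4).
#' @param collected_cap Optional early stop after this many collected
#'   photons (0 = off).
#' @param n_quantiles Resolution of the inverse-CDF table.
#' @return List with \code{reflectance}, \code{se}, \code{n_collected},
#'   \code{n_launched} and the weight tallies (\code{collected},
#'   \code{escaped}, \code{truncated}, \code{absorbed}).
#' @export
mc_darkfield_reflectance <- function(mus, mua = 0, phase = NULL,
                                     geom = darkfield_geometry(),
                                     photons = 1e6, seed = NULL,
                                     max_depth = 10, max_steps = 2e4,
                                     collected_cap = 0,
                                     n_quantiles = 2048) {
  stopifnot(inherits(geom, "darkfield_geometry"))
  if (photons < 1) stop("photons must be positive")
  if (mus + mua <= 0) {
    warning("ballistic medium (mu_t = 0): nothing scatters back")
    return(list(reflectance = 0, se = 0, n_collected = 0L,
                n_launched = as.integer(photons), collected = 0,
                escaped = 0, truncated = 0, absorbed = 0))
  }
  if (mus > 0 && is.null(phase))
    stop("a phase-function table is required when mus > 0")
  cq <- phase_inverse_cdf(phase, n_quantiles)
  if (!is.null(seed)) set.seed(seed)
  res <- mc_darkfield_cpp(mus, mua, cq, geom$incidence, geom$source_radius,
                          geom$fov_radius, cos(geom$collection_half_angle),
                          as.integer(photons), max_depth,
                          as.integer(max_steps), as.integer(collected_cap))
  n <- res$n_launched
  refl <- res$collected_weight / n
  # per-photon contribution variance (photon contributes its weight or 0)
  se <- sqrt(max(res$collected_weight_sq / n - refl^2, 0) / n)
  list(reflectance = refl, se = se, n_collected = res$n_collected,
       n_launched = n, collected = res$collected_weight,
       escaped = res$escaped_weight, truncated = res$truncated_weight,
       absorbed = res$absorbed_weight)
}

# inverse CDF of cos(theta) at uniform quantiles, from a phase table
phase_inverse_cdf <- function(phase, n_quantiles) {
  mu <- phase$mu
  p <- phase$p
  if (length(mu) != length(p) || length(mu) < 2L)
    stop("phase table must have matching mu and p of length >= 2")
  # cumulative trapezoid of p over mu
  dmu <- diff(mu)
  seg <- dmu * (utils::head(p, -1) + utils::tail(p, -1)) / 2
  cdf <- c(0, cumsum(seg))
  cdf <- cdf / cdf[length(cdf)]
  u <- seq(0, 1, length.out = n_quantiles)
  stats::approx(cdf, mu, xout = u, ties = "ordered")$y
}

#' Reflectance look-up table over volume fraction and wavelength
#'
#' Builds the Monte Carlo reflectance LUT R(vf, lambda) for a family of
#' bead phantoms differing only in volume fraction, together with the
#' companion mu_s' LUT, on the default grids of 0.0005-0.005 (step
#' 0.0005) and 400-800 nm (step 25 nm).
#'
#' @param diameter Bead diameter in nm.
#' @param vf_grid Volume-fraction grid.
#' @param wavelengths Wavelength grid in nm.
#' @param geom A \code{\link{darkfield_geometry}}.
#' @param photons Photons per (vf, lambda) cell.
#' @param seed Base seed; cell (i, j) uses seed + linear cell index.
#' @param ... Passed to \code{\link{mc_darkfield_reflectance}}.
#' @return Object of class \code{reflectance_lut}: \code{vf},
#'   \code{wavelength}, \code{R}, \code{se}, \code{musp} (matrices vf x
#'   wavelength), \code{provenance}.
#' @export
build_lut <- function(diameter = 368,
                      vf_grid = seq(0.0005, 0.005, by = 0.0005),
                      wavelengths = seq(400, 800, by = 25),
                      geom = darkfield_geometry(), photons = 1e5,
                      seed = 0, ...) {
  nv <- length(vf_grid)
  nw <- length(wavelengths)
  R <- matrix(0, nv, nw)
  SE <- matrix(0, nv, nw)
  MUSP <- matrix(0, nv, nw)
  for (j in seq_len(nw)) {
    wl <- wavelengths[j]
    mie <- mie_single_sphere(diameter, ri_polystyrene(wl), ri_water(wl),
                             wl, phase = TRUE)
    d_mm <- diameter * 1e-6
    cross <- pi * (d_mm / 2)^2
    sphere_vol <- pi / 6 * d_mm^3
    for (i in seq_len(nv)) {
      mus <- vf_grid[i] / sphere_vol * mie$q_sca * cross
      MUSP[i, j] <- mus * (1 - mie$g)
      run <- mc_darkfield_reflectance(
        mus, 0, phase = mie, geom = geom, photons = photons,
        seed = seed + (j - 1L) * nv + i, ...)
      R[i, j] <- run$reflectance
      SE[i, j] <- run$se
    }
  }
  structure(list(vf = vf_grid, wavelength = wavelengths, R = R, se = SE,
                 musp = MUSP,
                 provenance = list(diameter = diameter, photons = photons,
                                   seed = seed,
                                   incidence_deg = geom$incidence * 180 / pi,
                                   na = geom$na, n_medium = geom$n_medium)),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf("<reflectance_lut> %d volume fractions x %d wavelengths, R in [%.3g, %.3g]\n",
              length(x$vf), length(x$wavelength), min(x$R), max(x$R)))
  invisible(x)
}

#' Write a reflectance LUT as a plain-text table
#'
#' Long-format text file (columns vf, wavelength, R, se, musp) with a
#' provenance header; numbers use 17 significant digits so a reload is
#' bit-identical.
#'
#' @param lut A \code{\link{reflectance_lut}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "reflectance_lut"))
  con <- file(path, "w")
  on.exit(close(con))
  pv <- lut$provenance
  for (key in names(pv))
    writeLines(sprintf("# %s: %.17g", key, as.numeric(pv[[key]])), con)
  writeLines("vf\twavelength\tR\tse\tmusp", con)
  for (j in seq_along(lut$wavelength)) for (i in seq_along(lut$vf))
    writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g\t%.17g",
                       lut$vf[i], lut$wavelength[j], lut$R[i, j],
                       lut$se[i, j], lut$musp[i, j]), con)
  invisible(path)
}

#' Read a reflectance LUT written by \code{\link{write_lut}}
#'
#' @param path Path to the text table.
#' @return A \code{\link{reflectance_lut}}.
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  pv <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    pv[[key]] <- as.numeric(sub("^[^:]*: *", "", kv))
  }
  tab <- utils::read.table(text = lines[!grepl("^# ", lines)], header = TRUE,
                           sep = "\t")
  vf <- sort(unique(tab$vf))
  wl <- sort(unique(tab$wavelength))
  shape <- function(col) {
    m <- matrix(0, length(vf), length(wl))
    m[cbind(match(tab$vf, vf), match(tab$wavelength, wl))] <- col
    m
  }
  structure(list(vf = vf, wavelength = wl, R = shape(tab$R),
                 se = shape(tab$se), musp = shape(tab$musp),
                 provenance = pv),
            class = "reflectance_lut")
}

#' Invert a measured reflectance spectrum to a volume fraction
#'
#' Least-squares fit over volume fraction with linear interpolation
#' between LUT rows: within each grid interval the interpolated spectrum
#' is linear in the mixing parameter, so the per-interval optimum is
#' closed-form; the interval with the lowest residual wins. Inputs lying
#' exactly on a LUT row invert exactly. The companion mu_s' spectrum at
#' the estimate is returned from the mu_s' LUT.
#'
#' @param measured Named or plain numeric reflectance spectrum on (a
#'   subset of) the LUT wavelength grid.
#' @param lut A \code{\link{reflectance_lut}}.
#' @param wavelengths Wavelengths of \code{measured}; default the LUT
#'   grid.
#' @return List with \code{vf} (estimate), \code{residuals} (per
#'   wavelength), \code{rss}, \code{musp} (interpolated spectrum at the
#'   estimate).
#' @export
invert_volume_fraction <- function(measured, lut, wavelengths = NULL) {
  stopifnot(inherits(lut, "reflectance_lut"))
  if (is.null(wavelengths)) wavelengths <- lut$wavelength
  cols <- match(wavelengths, lut$wavelength)
  if (anyNA(cols))
    stop("extrapolation error: measured wavelengths outside the LUT grid")
  if (length(measured) != length(cols))
    stop("measured spectrum and wavelengths disagree in length")
  R <- lut$R[, cols, drop = FALSE]
  nv <- length(lut$vf)
  best <- NULL
  for (i in seq_len(nv - 1L)) {
    ra <- R[i, ]
    rb <- R[i + 1L, ]
    dr <- rb - ra
    den <- sum(dr^2)
    t <- if (den > 0) sum((measured - ra) * dr) / den else 0
    t <- min(max(t, 0), 1)
    pred <- ra + t * dr
    rss <- sum((measured - pred)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, i = i, t = t, pred = pred)
  }
  vf_hat <- lut$vf[best$i] + best$t * (lut$vf[best$i + 1L] - lut$vf[best$i])
  musp <- lut$musp[best$i, ] +
    best$t * (lut$musp[best$i + 1L, ] - lut$musp[best$i, ])
  list(vf = vf_hat, residuals = measured - best$pred, rss = best$rss,
       musp = musp)
}
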