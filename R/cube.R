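#' Raw intensity data cube
#'
#' A stack of band images I(m, n, lambda) together with the per-band
#' exposure times used during acquisition. Axis order is (row, col, band)
#' with pixel (1, 1) at the top-left.
#'
#' @param intensity Numeric array of shape (rows, cols, bands) with
#'   nonnegative values, or a single spectrum (length = bands) for a
#'   spatially uniform cube (stored as a 1 x 1 x bands array).
#' @param exposure Per-band exposure times in ms, strictly positive;
#'   recycled from a scalar.
#' @param grid A \code{\link{wavelength_grid}}.
#' @param meta Optional free-form provenance list.
#' @return An object of class \code{hypercube}.
#' @export
hypercube <- function(intensity, exposure, grid = wavelength_grid(),
                      meta = list()) {
  if (is.null(dim(intensity))) {
    intensity <- array(intensity, dim = c(1L, 1L, length(intensity)))
  }
  if (length(dim(intensity)) != 3L)
    stop("intensity must be a (rows, cols, bands) array")
  nb <- dim(intensity)[3L]
  if (nb != length(grid))
    stop("configuration error: band count does not match wavelength grid")
  exposure <- as.numeric(exposure)
  if (length(exposure) == 1L) exposure <- rep(exposure, nb)
  if (length(exposure) != nb)
    stop("exposure must have one entry per band")
  if (any(!is.finite(exposure)) || any(exposure <= 0))
    stop("exposure must be strictly positive in every band")
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensity must be nonnegative")
  structure(list(intensity = intensity, exposure = exposure, grid = grid,
                 meta = meta),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$intensity)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Reflectance data cube
#'
#' Normalized reflectance values X(m, n, lambda) produced by
#' \code{\link{normalize_cube}}; optionally spatially flattened.
#'
#' @param values Numeric array (rows, cols, bands), finite everywhere.
#' @param grid A \code{\link{wavelength_grid}}.
#' @param flattened Logical; has illumination flattening been applied.
#' @param meta Optional provenance list.
#' @return An object of class \code{reflectance_cube}.
#' @export
reflectance_cube <- function(values, grid = wavelength_grid(),
                             flattened = FALSE, meta = list()) {
  if (is.null(dim(values)))
    values <- array(values, dim = c(1L, 1L, length(values)))
  if (length(dim(values)) != 3L)
    stop("values must be a (rows, cols, bands) array")
  if (dim(values)[3L] != length(grid))
    stop("configuration error: band count does not match wavelength grid")
  if (any(!is.finite(values)))
    stop("propagation error: reflectance values must be finite")
  structure(list(values = values, grid = grid,
                 flattened = isTRUE(flattened), meta = meta),
            class = "reflectance_cube")
}

#' @export
dim.reflectance_cube <- function(x) dim(x$values)

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands%s\n",
              d[1], d[2], d[3], if (x$flattened) " (flattened)" else ""))
  invisible(x)
}

# exposure-normalized band rate cube (counts/ms), spatial dims kept
rate_cube <- function(hc) {
  sweep(hc$intensity, 3L, hc$exposure, "/")
}

# spatial mean spectrum of an exposure-normalized cube
mean_rate_spectrum <- function(hc) {
  apply(rate_cube(hc), 3L, mean)
}

#' Normalize a raw cube to reflectance
#'
#' Converts a raw intensity cube to reflectance using companion dark and
#' white-standard (reference) acquisitions, each intensity map first
#' normalized by its own per-band exposure time:
#' \deqn{X = \frac{I/\Delta\tau_1 - I_{dark}/\Delta\tau_2}
#'            {I_{ref}/\Delta\tau_3 - I_{dark}/\Delta\tau_4}}
#' The reference cube is spatially averaged over its field of view before
#' use, as is the dark cube wherever a single spectrum is required in the
#' denominator. Negative numerator values (dark exceeding signal) are kept
#' rather than clipped, preserving linearity for downstream unmixing.
#'
#' @param sample,dark,reference \code{\link{hypercube}} objects sharing one
#'   wavelength grid. \code{dark} and \code{reference} may be spatially
#'   uniform (1 x 1 rasters) and are broadcast.
#' @param dark_exposure_den Optional exposure vector for the dark term of
#'   the denominator when the dark acquisition paired with the reference
#'   used different exposures; defaults to \code{dark$exposure}.
#' @return A \code{\link{reflectance_cube}}.
#' @export
#' @examples
#' g <- wavelength_grid(500)
#' s <- hypercube(array(10, c(1, 1, 1)), 2, g)
#' d <- hypercube(array(1, c(1, 1, 1)), 1, g)
#' r <- hypercube(array(10, c(1, 1, 1)), 1, g)
#' normalize_cube(s, d, r)$values  # (5-1)/(10-1) = 4/9
normalize_cube <- function(sample, dark, reference,
                           dark_exposure_den = NULL) {
  stopifnot(inherits(sample, "hypercube"), inherits(dark, "hypercube"),
            inherits(reference, "hypercube"))
  stop_if_grid_mismatch(sample$grid, dark$grid, "sample and dark cubes")
  stop_if_grid_mismatch(sample$grid, reference$grid,
                        "sample and reference cubes")
  d <- dim(sample$intensity)
  nb <- d[3L]

  # numerator: per-pixel sample rate minus dark rate (broadcast if uniform)
  samp_rate <- rate_cube(sample)
  dark_rate <- rate_cube(dark)
  if (all(dim(dark)[1:2] == d[1:2])) {
    num <- samp_rate - dark_rate
  } else if (all(dim(dark)[1:2] == c(1L, 1L))) {
    num <- sweep(samp_rate, 3L, as.vector(dark_rate), "-")
  } else {
    stop("configuration error: dark cube must match sample dimensions or be uniform")
  }

  # denominator: FOV-averaged reference spectrum minus FOV-averaged dark,
  # each over its own exposure vector
  ref_spec <- mean_rate_spectrum(reference)
  if (is.null(dark_exposure_den)) dark_exposure_den <- dark$exposure
  dark_exposure_den <- as.numeric(dark_exposure_den)
  if (length(dark_exposure_den) == 1L)
    dark_exposure_den <- rep(dark_exposure_den, nb)
  if (any(dark_exposure_den <= 0))
    stop("dark_exposure_den must be strictly positive")
  dark_spec <- apply(dark$intensity, 3L, mean) / dark_exposure_den
  den <- ref_spec - dark_spec
  bad <- which(den <= 0)
  if (length(bad) > 0L)
    stop(sprintf(
      "degenerate-reference error: nonpositive denominator at band %d (%g nm)",
      bad[1L], sample$grid$wavelengths[bad[1L]]))

  x <- sweep(num, 3L, den, "/")
  reflectance_cube(x, sample$grid, flattened = FALSE,
                   meta = c(sample$meta, list(normalized = TRUE)))
}

#' Flatten long-range illumination non-uniformity
#'
#' Estimates a smooth multiplicative illumination field as the unit-mean
#' Gaussian-blurred copy of the image and divides it out, iterating the
#' estimate-and-divide step until the residual field is unity within
#' \code{tol}; the iteration makes the operator a fixed point, so
#' flattening an already-flattened cube changes it only marginally.
#'
#' In the default \code{"broadband"} mode one field is estimated from the
#' band-mean image and divided out of every band, so each pixel spectrum
#' is rescaled by a single positive scalar and spectral shapes (hence all
#' spectral angles) are preserved exactly. The \code{"per_band"} mode
#' estimates an independent field per band, which also removes
#' band-specific vignetting but can distort the spectra of scenes with
#' genuine long-range structure. Each output band is rescaled to its
#' input mean, so band means are preserved exactly. Anisotropic smoothing
#' is supported via a length-2 \code{sigma} (row, col), reflecting
#' directional intensity variation across the image.
#'
#' @param cube A \code{\link{reflectance_cube}}.
#' @param sigma Gaussian smoothing scale in pixels; scalar or
#'   \code{c(sigma_row, sigma_col)}. Default 50.
#' @param mode \code{"broadband"} (one field from the band-mean image;
#'   default) or \code{"per_band"}.
#' @param tol Convergence tolerance on the residual field (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @return A flattened \code{\link{reflectance_cube}}.
#' @export
flatten_cube <- function(cube, sigma = 50, mode = c("broadband", "per_band"),
                         tol = 1e-5, max_iter = 300) {
  stopifnot(inherits(cube, "reflectance_cube"))
  mode <- match.arg(mode)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  v <- cube$values
  if (any(!is.finite(v))) stop("propagation error: non-finite values")
  d <- dim(v)
  Br <- blur_operator(d[1L], sigma[1L])
  Bc <- blur_operator(d[2L], sigma[2L])
  out <- v
  if (mode == "broadband") {
    total <- iterate_field(apply(v, c(1L, 2L), mean), Br, Bc, tol, max_iter)
    for (b in seq_len(d[3L])) {
      band <- v[, , b]
      flat <- band / total
      m1 <- mean(flat)
      if (is.finite(m1) && m1 != 0) flat <- flat * (mean(band) / m1)
      out[, , b] <- flat
    }
  } else {
    for (b in seq_len(d[3L])) {
      band <- v[, , b]
      total <- iterate_field(band, Br, Bc, tol, max_iter)
      flat <- band / total
      m1 <- mean(flat)
      if (is.finite(m1) && m1 != 0) flat <- flat * (mean(band) / m1)
      out[, , b] <- flat
    }
  }
  reflectance_cube(out, cube$grid, flattened = TRUE, meta = cube$meta)
}

# accumulated unit-mean smooth field such that blur(img/field) is flat
iterate_field <- function(img, Br, Bc, tol, max_iter) {
  total <- matrix(1, nrow(img), ncol(img))
  flat <- img
  for (it in seq_len(max_iter)) {
    field <- Br %*% flat %*% t(Bc)
    mf <- mean(field)
    if (!is.finite(mf) || mf <= 0)
      stop("propagation error: nonpositive illumination field")
    field <- field / mf
    flat <- flat / field
    total <- total * field
    if (max(abs(field - 1)) < tol) break
  }
  total / mean(total)
}

# dense 1-D Gaussian blur operator with replicate boundary: out-of-range
# kernel mass folds onto the edge samples, matching replicate padding
blur_operator <- function(n, sigma) {
  if (n == 1L) return(matrix(1, 1, 1))
  r <- min(ceiling(3 * sigma), n - 1L)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq(-r, r)) {
    j <- pmin(pmax(i + t, 1L), n)
    B[cbind(i, j)] <- B[cbind(i, j)] + k[t + r + 1L]
  }
  B
}

#' Pseudo-color rendering of a reflectance cube
#'
#' Builds an RGB image from the 630 (red), 530 (green) and 480 nm (blue)
#' bands, each channel independently rescaled to [0, 1] by its 1st-99th
#' intensity percentile and clipped.
#'
#' @param cube A \code{\link{reflectance_cube}} whose grid contains 480,
#'   530 and 630 nm.
#' @param probs Lower/upper rescaling percentiles (default \code{c(0.01,
#'   0.99)}).
#' @return An array (rows, cols, 3) with values in [0, 1], channels in
#'   R, G, B order.
#' @export
pseudo_color <- function(cube, probs = c(0.01, 0.99)) {
  stopifnot(inherits(cube, "reflectance_cube"))
  need <- c(red = 630, green = 530, blue = 480)
  idx <- vapply(need, function(w) band_index(cube$grid, w), integer(1))
  if (anyNA(idx))
    stop(sprintf("configuration error: grid lacks band(s) %s nm",
                 paste(need[is.na(idx)], collapse = ", ")))
  d <- dim(cube$values)
  out <- array(0, dim = c(d[1L], d[2L], 3L))
  for (ch in 1:3) {
    band <- cube$values[, , idx[ch]]
    q <- stats::quantile(band, probs = probs, names = FALSE)
    rng <- q[2L] - q[1L]
    out[, , ch] <- if (rng > 0) pmin(pmax((band - q[1L]) / rng, 0), 1)
                   else array(0, dim = d[1:2])
  }
  out
}
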