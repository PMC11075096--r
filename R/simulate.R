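#' Synthetic scene specification
#'
#' Describes a synthetic tissue scene as a set of regions, each mixing the
#' spectral templates linearly with nonnegative weights summing to at most
#' one. Later regions overwrite earlier ones where they overlap; pixels
#' covered by no region take the \code{background} weights.
#'
#' @param shape Integer vector \code{c(rows, cols)}.
#' @param regions List of regions. Each region is a list with either
#'   \code{type = "rect"} and fields \code{r0, r1, c0, c1} (inclusive pixel
#'   bounds) or \code{type = "disc"} and fields \code{row, col, radius},
#'   plus \code{weights}: a named numeric vector of template mixing
#'   weights (nonnegative, sum at most 1).
#' @param background Named weights applied outside all regions; default
#'   pure first template.
#' @param noise_sd Relative (multiplicative) Gaussian noise level on the
#'   sample signal; 0.02 emulates a well-exposed acquisition.
#' @param illumination One of \code{"tilt"} (default; a smooth multiplicative
#'   tilt-plus-vignetting field spanning roughly +/-10 percent), \code{"none"},
#'   or a user matrix of shape \code{shape} with positive entries.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(shape, regions = list(), background = NULL,
                       noise_sd = 0.02, illumination = "tilt", seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be c(rows, cols)")
  for (rg in regions) {
    w <- rg$weights
    if (is.null(names(w)) || any(w < 0) || sum(w) > 1 + 1e-12)
      stop("specification error: region weights must be named, nonnegative, sum <= 1")
  }
  if (!is.null(background) &&
      (any(background < 0) || sum(background) > 1 + 1e-12))
    stop("specification error: background weights must be nonnegative, sum <= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(shape = shape, regions = regions, background = background,
                 noise_sd = noise_sd, illumination = illumination,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

region_mask <- function(rg, shape) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  if (identical(rg$type, "rect")) {
    m[rg$r0:rg$r1, rg$c0:rg$c1] <- TRUE
  } else if (identical(rg$type, "disc")) {
    rr <- row(m) - rg$row
    cc <- col(m) - rg$col
    m[rr^2 + cc^2 <= rg$radius^2] <- TRUE
  } else stop("specification error: unknown region type")
  m
}

# weights over the full template list, zero-filled
full_weights <- function(w, labels) {
  out <- stats::setNames(numeric(length(labels)), labels)
  if (is.null(w)) return(out)
  unknown <- setdiff(names(w), labels)
  if (length(unknown) > 0L)
    stop(sprintf("specification error: unknown template(s): %s",
                 paste(unknown, collapse = ", ")))
  out[names(w)] <- w
  out
}

scene_abundance <- function(spec, labels) {
  sh <- spec$shape
  nT <- length(labels)
  A <- array(0, dim = c(sh[1L], sh[2L], nT), dimnames = list(NULL, NULL, labels))
  bg <- full_weights(if (is.null(spec$background))
    stats::setNames(1, labels[1L]) else spec$background, labels)
  for (t in seq_len(nT)) A[, , t] <- bg[t]
  for (rg in spec$regions) {
    m <- region_mask(rg, sh)
    w <- full_weights(rg$weights, labels)
    for (t in seq_len(nT)) {
      plane <- A[, , t]
      plane[m] <- w[t]
      A[, , t] <- plane
    }
  }
  A
}

default_illumination <- function(shape) {
  r <- (row(matrix(0, shape[1L], shape[2L])) - (shape[1L] + 1) / 2) /
    max(shape[1L], 2)
  c <- (col(matrix(0, shape[1L], shape[2L])) - (shape[2L] + 1) / 2) /
    max(shape[2L], 2)
  1 + 0.06 * r + 0.04 * c - 0.08 * (r^2 + c^2)
}

# synthetic lamp x sensor spectral response, counts/ms at unit reflectance
lamp_response <- function(grid) {
  wl <- grid$wavelengths
  1200 * exp(-((wl - 560) / 120)^2)
}

# EMCCD-like per-band exposure scan: longer where the lamp is dim
exposure_scan <- function(grid) {
  L <- lamp_response(grid)
  round(20 * max(L) / L, 1)
}

DARK_RATE <- 5  # counts/ms, constant dark-current proxy

# Shared forward model: reflectance field -> (sample, dark, reference)
# counts with per-band exposures, so that normalize_cube recovers the
# reflectance field (times illumination) exactly at zero noise.
forward_model <- function(refl, grid, noise_sd, illumination, seed) {
  sh <- dim(refl)[1:2]
  nb <- dim(refl)[3L]
  L <- lamp_response(grid)
  tau1 <- exposure_scan(grid)
  tau2 <- rep(50, nb)
  tau3 <- round(0.8 * tau1, 1)

  ill <- if (is.matrix(illumination)) {
    if (!all(dim(illumination) == sh)) stop("illumination field shape mismatch")
    illumination
  } else if (identical(illumination, "none") || is.null(illumination)) {
    matrix(1, sh[1L], sh[2L])
  } else if (identical(illumination, "tilt")) {
    default_illumination(sh)
  } else stop("specification error: unknown illumination option")

  set.seed(seed)
  signal <- sweep(refl * as.vector(ill), 3L, L, "*")  # counts/ms
  if (noise_sd > 0) {
    eps <- array(stats::rnorm(prod(dim(signal)), sd = noise_sd),
                 dim = dim(signal))
    signal <- signal * (1 + eps)
  }
  samp_counts <- sweep(sweep(signal, 3L, rep(DARK_RATE, nb), "+"),
                       3L, tau1, "*")
  dark_counts <- array(rep(DARK_RATE * tau2, each = prod(sh)),
                       dim = c(sh, nb))
  if (noise_sd > 0) {
    dark_counts <- dark_counts *
      (1 + array(stats::rnorm(prod(dim(dark_counts)), sd = noise_sd),
                 dim = dim(dark_counts)))
  }
  ref_counts <- array(rep((L + DARK_RATE) * tau3, each = prod(sh)),
                      dim = c(sh, nb))

  list(sample = hypercube(pmax(samp_counts, 0), tau1, grid,
                          meta = list(synthetic = TRUE, seed = seed)),
       dark = hypercube(pmax(dark_counts, 0), tau2, grid,
                        meta = list(synthetic = TRUE)),
       reference = hypercube(ref_counts, tau3, grid,
                             meta = list(synthetic = TRUE)),
       illumination = ill)
}

#' Generate a synthetic data-cube triplet with ground truth
#'
#' Builds, per pixel, the linear mixture of the given templates, applies a
#' smooth multiplicative illumination field and a band-dependent synthetic
#' lamp-times-sensor response, converts to intensity counts with per-band
#' exposure times, and returns the sample/dark/reference cubes a real
#' acquisition would produce, so that \code{\link{normalize_cube}} recovers
#' the mixed reflectance. Multiplicative Gaussian noise at
#' \code{spec$noise_sd} is applied to the sample signal (and dark counts).
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param templates List of \code{\link{spectral_template}} objects on the
#'   scene's grid.
#' @return A list with \code{sample}, \code{dark}, \code{reference}
#'   (\code{\link{hypercube}} objects), \code{labels} (integer raster of
#'   dominant-template indices, with template labels as levels attribute),
#'   \code{abundance} (rows x cols x templates array of planted weights),
#'   and \code{illumination} (the field used).
#' @export
generate_cube <- function(spec, templates = make_paper_templates()) {
  stopifnot(inherits(spec, "scene_spec"))
  grid <- templates[[1L]]$grid
  for (tp in templates) stop_if_grid_mismatch(grid, tp$grid, "templates")
  labels <- vapply(templates, `[[`, character(1), "label")
  A <- scene_abundance(spec, labels)
  sh <- spec$shape
  nb <- length(grid)

  Tmat <- vapply(templates, `[[`, numeric(nb), "spectrum")  # nb x nT
  refl <- array(0, dim = c(sh, nb))
  Aflat <- matrix(A, nrow = prod(sh))                        # n x nT
  Rflat <- Aflat %*% t(Tmat)                                 # n x nb
  refl <- array(Rflat, dim = c(sh, nb))

  out <- forward_model(refl, grid, spec$noise_sd, spec$illumination,
                       spec$seed)
  lab <- apply(Aflat, 1L, function(w)
    if (max(w) > 0) which.max(w) else 0L)
  lab <- matrix(as.integer(lab), sh[1L], sh[2L])
  attr(lab, "labels") <- labels
  out$labels <- lab
  out$abundance <- A
  out
}

#' Generate a single-endmember reference cube triplet
#'
#' A spatially textured cube of one tissue type: the spectral shape is
#' fixed (up to noise) while the per-pixel amplitude varies, standing in
#' for the fat-only and fibroadenoma-only reference acquisitions used to
#' determine OSCA thresholds.
#'
#' @param template A \code{\link{spectral_template}}.
#' @param spec A \code{\link{scene_spec}} providing shape, noise level,
#'   illumination and seed.
#' @param amplitude_range Per-pixel amplitude texture range (uniform).
#' @return Same structure as \code{\link{generate_cube}} (labels are all
#'   1, abundance is the amplitude field).
#' @export
generate_reference_cube <- function(template, spec,
                                    amplitude_range = c(0.7, 1.3)) {
  stopifnot(inherits(template, "spectral_template"),
            inherits(spec, "scene_spec"))
  sh <- spec$shape
  grid <- template$grid
  set.seed(spec$seed + 1L)  # amplitude stream distinct from the noise stream
  amp <- matrix(stats::runif(prod(sh), amplitude_range[1L],
                             amplitude_range[2L]), sh[1L], sh[2L])
  refl <- array(outer(as.vector(amp), template$spectrum),
                dim = c(sh, length(grid)))
  out <- forward_model(refl, grid, spec$noise_sd, spec$illumination,
                       spec$seed)
  lab <- matrix(1L, sh[1L], sh[2L])
  attr(lab, "labels") <- template$label
  out$labels <- lab
  out$abundance <- amp
  out
}

#' Read a scene specification from a YAML file
#'
#' The file mirrors the \code{\link{scene_spec}} arguments: \code{shape},
#' \code{regions} (each with \code{type}, geometry fields and a
#' \code{weights} mapping), optional \code{background}, \code{noise_sd},
#' \code{illumination} and \code{seed}.
#'
#' @param path Path to a YAML file.
#' @return A \code{\link{scene_spec}}.
#' @export
read_scene_spec <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- lapply(y$regions, function(rg) {
    rg$weights <- unlist(rg$weights)
    rg
  })
  scene_spec(shape = unlist(y$shape), regions = regions,
             background = if (is.null(y$background)) NULL
                          else unlist(y$background),
             noise_sd = if (is.null(y$noise_sd)) 0.02 else y$noise_sd,
             illumination = if (is.null(y$illumination)) "tilt"
                            else y$illumination,
             seed = if (is.null(y$seed)) 0L else y$seed)
}

#' Carcinoma cross-validation scene
#'
#' The standard synthetic scene for validating the supervised library
#' against the unsupervised clustering: two carcinoma types (IDC, IMC)
#' planted as solid pure masses -- mirroring the infiltrating-mass
#' morphology of ductal carcinoma -- and three normal types (blood, fat,
#' interconnected tissue), five spectral populations matching the five
#' clusters sought. Every planted type contributes at least 10 percent
#' pure pixels of the frame.
#'
#' @param seed Scene seed.
#' @param shape Raster shape (default 128 x 128).
#' @param noise_sd Relative noise (default 0.02).
#' @param illumination Passed to \code{\link{scene_spec}}.
#' @return A \code{\link{scene_spec}}.
#' @export
carcinoma_validation_scene <- function(seed = 0, shape = c(128, 128),
                                       noise_sd = 0.02,
                                       illumination = "tilt") {
  f <- shape / 128  # keep layout proportions for other raster sizes
  rect <- function(r0, r1, c0, c1, w)
    list(type = "rect", r0 = max(1L, round(r0 * f[1L])),
         r1 = round(r1 * f[1L]), c0 = max(1L, round(c0 * f[2L])),
         c1 = round(c1 * f[2L]), weights = w)
  disc <- function(row, col, radius, w)
    list(type = "disc", row = round(row * f[1L]), col = round(col * f[2L]),
         radius = round(radius * min(f)), weights = w)
  scene_spec(
    shape = shape,
    regions = list(
      rect(6, 55, 6, 55, c(blood = 1)),
      rect(6, 55, 74, 123, c(fat = 1)),
      disc(95, 32, 26, c(IDC = 1)),
      disc(95, 96, 26, c(IMC = 1))),
    background = c(ICT1 = 1),
    noise_sd = noise_sd, illumination = illumination, seed = seed)
}
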