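#' Spectral angle between two spectra
#'
#' The spectral correlation angle (SCA): the arccosine of the cosine
#' similarity between two spectra viewed as vectors in band space, clamped
#' to [0, pi/2]. Insensitive to positive rescaling of either argument.
#'
#' @param x,mu Numeric spectra of equal length, nonzero norm.
#' @return Angle in radians in [0, pi/2].
#' @export
#' @examples
#' spectral_angle(c(1, 1), c(1, 0))  # pi/4
spectral_angle <- function(x, mu) {
  if (length(x) != length(mu))
    stop("spectra must share a grid")
  nx <- sqrt(sum(x^2))
  nm <- sqrt(sum(mu^2))
  if (nx == 0 || nm == 0)
    stop("degenerate-pixel error: zero-norm spectrum")
  cosang <- sum(x * mu) / (nx * nm)
  min(acos(min(max(cosang, -1), 1)), pi / 2)
}

#' Extract an endmember from a region of interest
#'
#' The endmember spectrum is the per-band mean over the ROI pixels; the
#' per-band standard deviation and the pixel count are retained.
#'
#' @param cube A \code{\link{reflectance_cube}}.
#' @param roi Logical matrix (rows x cols) marking the ROI, or an integer
#'   two-column matrix of (row, col) indices.
#' @param label Tissue-type label.
#' @param color Display color for segmentation maps.
#' @return An object of class \code{endmember} with fields \code{label},
#'   \code{mu}, \code{spread}, \code{n_pixels}, \code{color}, \code{grid}.
#' @export
extract_endmember <- function(cube, roi, label, color = "gray") {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$values)
  if (is.logical(roi)) {
    if (!all(dim(roi) == d[1:2])) stop("roi shape mismatch")
    idx <- which(roi)
  } else {
    roi <- as.matrix(roi)
    if (ncol(roi) != 2L) stop("roi must be logical mask or (row, col) matrix")
    idx <- (roi[, 2L] - 1L) * d[1L] + roi[, 1L]
  }
  if (length(idx) == 0L) stop("empty roi")
  flat <- matrix(cube$values, nrow = d[1L] * d[2L])  # pixels x bands
  px <- flat[idx, , drop = FALSE]
  mu <- colMeans(px)
  spread <- if (nrow(px) > 1L) apply(px, 2L, stats::sd) else rep(0, ncol(px))
  if (sqrt(sum(mu^2)) == 0) stop("degenerate endmember: zero-norm mean")
  structure(list(label = as.character(label), mu = mu, spread = spread,
                 n_pixels = length(idx), color = color, grid = cube$grid),
            class = "endmember")
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("<endmember> %s: %d bands, %d ROI pixels\n",
              x$label, length(x$mu), x$n_pixels))
  invisible(x)
}

#' Spectral angle map of a cube against an endmember
#'
#' Computes the SCA between every pixel spectrum and the endmember mean.
#' Zero-norm (degenerate) pixels are assigned pi/2 and counted.
#'
#' @param cube A \code{\link{reflectance_cube}}.
#' @param em An \code{\link{endmember}} (or a bare numeric spectrum).
#' @return An object of class \code{angle_map}: \code{values} raster in
#'   [0, pi/2], \code{label}, \code{n_degenerate}.
#' @export
angle_map <- function(cube, em) {
  stopifnot(inherits(cube, "reflectance_cube"))
  mu <- if (inherits(em, "endmember")) em$mu else as.numeric(em)
  label <- if (inherits(em, "endmember")) em$label else "spectrum"
  if (inherits(em, "endmember"))
    stop_if_grid_mismatch(cube$grid, em$grid, "cube and endmember")
  d <- dim(cube$values)
  if (length(mu) != d[3L]) stop("configuration error: band count mismatch")
  nm <- sqrt(sum(mu^2))
  if (nm == 0) stop("degenerate-pixel error: zero-norm endmember")
  flat <- matrix(cube$values, nrow = d[1L] * d[2L])
  nx <- sqrt(rowSums(flat^2))
  degen <- nx == 0
  cosang <- as.vector(flat %*% mu) / (pmax(nx, .Machine$double.xmin) * nm)
  ang <- pmin(acos(pmin(pmax(cosang, -1), 1)), pi / 2)
  ang[degen] <- pi / 2
  structure(list(values = matrix(ang, d[1L], d[2L]), label = label,
                 n_degenerate = sum(degen)),
            class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  cat(sprintf("<angle_map> %s: %d x %d, range [%.4f, %.4f] rad (%d degenerate)\n",
              x$label, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values), x$n_degenerate))
  invisible(x)
}

#' Binary segmentation of one tissue type
#'
#' A pixel is classified as the type when its angle is strictly below the
#' threshold.
#'
#' @param am An \code{\link{angle_map}}.
#' @param threshold Threshold angle in (0, pi/2].
#' @return Integer matrix of 0/1 with attributes \code{label} and
#'   \code{threshold}.
#' @export
segment_type <- function(am, threshold) {
  stopifnot(inherits(am, "angle_map"))
  if (!(threshold > 0 && threshold <= pi / 2))
    stop("threshold must lie in (0, pi/2]")
  seg <- (am$values < threshold) * 1L
  attr(seg, "label") <- am$label
  attr(seg, "threshold") <- threshold
  seg
}

# default threshold grid: 0 to pi/2 in 0.01 rad steps, endpoint included
default_threshold_grid <- function(step = 0.01) {
  g <- seq(0, pi / 2, by = step)
  if (g[length(g)] < pi / 2) g <- c(g, pi / 2)
  g
}

#' Fill-factor curve of a reference angle map
#'
#' For each threshold on the grid, the fraction of pixels whose angle is
#' at or below it: \eqn{f(\bar\beta) = N^{-1}\#\{\beta(m,n) \le
#' \bar\beta\}}. Nondecreasing, reaching 1 when the grid reaches pi/2.
#'
#' @param am An \code{\link{angle_map}} computed against a reference cube.
#' @param thresholds Increasing numeric grid within [0, pi/2].
#' @return Object of class \code{fill_factor_curve} with fields
#'   \code{thresholds}, \code{fractions}, \code{n_pixels}.
#' @export
fill_factor_curve <- function(am, thresholds = default_threshold_grid()) {
  stopifnot(inherits(am, "angle_map"))
  if (any(diff(thresholds) <= 0) || any(thresholds < 0) ||
      any(thresholds > pi / 2 + 1e-12))
    stop("thresholds must be increasing within [0, pi/2]")
  b <- as.vector(am$values)
  frac <- vapply(thresholds, function(th) mean(b <= th), numeric(1))
  structure(list(thresholds = thresholds, fractions = frac,
                 n_pixels = length(b), label = am$label),
            class = "fill_factor_curve")
}

#' Coverage (segmented-area fraction) versus threshold
#'
#' Like the fill-factor curve but with the strict inequality of the
#' segmentation rule: the fraction of pixels with angle strictly below
#' each threshold. At pi/2 the coverage equals one minus the degenerate
#' pixel fraction (degenerate pixels sit exactly at pi/2).
#'
#' @param am An \code{\link{angle_map}}.
#' @param thresholds Increasing numeric grid.
#' @return List with \code{thresholds} and \code{coverage}.
#' @export
coverage_vs_threshold <- function(am, thresholds = default_threshold_grid()) {
  stopifnot(inherits(am, "angle_map"))
  if (any(diff(thresholds) <= 0)) stop("thresholds must be increasing")
  b <- as.vector(am$values)
  cov <- vapply(thresholds, function(th) mean(b < th), numeric(1))
  list(thresholds = thresholds, coverage = cov, label = am$label)
}

#' Orthogonalized SCA (OSCA) threshold from a fill-factor analysis
#'
#' The OSCA of an endmember is the classification threshold determined
#' against a reference cube known to contain none of that tissue: the
#' largest grid threshold such that no reference pixel falls strictly
#' below it (every pixel angle is at or above the threshold). Segmenting
#' the reference cube at this threshold therefore yields zero positive
#' pixels by construction. Equivalently it is the minimum pixel angle
#' rounded down to the threshold grid.
#'
#' @param curve A \code{\link{fill_factor_curve}} (its threshold grid and
#'   minimum observed angle are used).
#' @return The OSCA in radians.
#' @export
determine_osca <- function(curve) {
  stopifnot(inherits(curve, "fill_factor_curve"))
  th <- curve$thresholds
  if (length(th) == 0L) stop("empty fill-factor curve")
  # smallest observed angle: first grid point with nonzero fill factor
  # bounds it above; recover it exactly from the stored minimum if present
  minb <- attr(curve, "min_angle")
  if (is.null(minb)) {
    nz <- which(curve$fractions > 0)
    if (length(nz) == 0L)
      stop("fill factor identically zero over the grid")
    # without the raw map, the first nonzero grid point caps min angle
    minb <- th[nz[1L]]
  }
  ok <- which(th <= minb + 1e-15)
  if (length(ok) == 0L)
    stop("no grid threshold at or below the minimum reference angle")
  th[ok[length(ok)]]
}

#' @export
print.fill_factor_curve <- function(x, ...) {
  cat(sprintf("<fill_factor_curve> %s: %d thresholds, f in [%.3f, %.3f]\n",
              x$label, length(x$thresholds), min(x$fractions),
              max(x$fractions)))
  invisible(x)
}

#' Build an endmember library with OSCA thresholds
#'
#' For each endmember, computes its angle map against the assigned
#' reference cube (reference 1, the fat-only cube, is used for non-fat
#' endmembers; reference 2, the fibroadenoma-only cube, for fat
#' endmembers), derives the fill-factor curve and the OSCA, and stores the
#' classification threshold (default equal to the OSCA, overridable per
#' type).
#'
#' @param endmembers List of \code{\link{endmember}} objects.
#' @param ref_cubes Named list with elements \code{"1"} (fat-only
#'   reference \code{\link{reflectance_cube}}) and \code{"2"}
#'   (fibroadenoma-only).
#' @param thresholds Threshold grid for the fill-factor analysis.
#' @param threshold_overrides Named numeric vector of manual threshold
#'   angles replacing the OSCA for specific labels.
#' @param fat_labels Labels routed to reference cube 2; defaults to labels
#'   starting with "fat" (case-insensitive).
#' @return Object of class \code{endmember_library}: a list of entries,
#'   each with \code{endmember}, \code{osca}, \code{threshold},
#'   \code{reference_id}, \code{fill_factor}.
#' @export
build_library <- function(endmembers, ref_cubes,
                          thresholds = default_threshold_grid(),
                          threshold_overrides = NULL,
                          fat_labels = NULL) {
  if (length(endmembers) == 0L) stop("no endmembers")
  if (!all(c("1", "2") %in% names(ref_cubes)))
    stop("configuration error: ref_cubes must contain elements \"1\" and \"2\"")
  for (rc in ref_cubes[c("1", "2")])
    if (!inherits(rc, "reflectance_cube"))
      stop("configuration error: reference cubes must be reflectance cubes")
  entries <- lapply(endmembers, function(em) {
    is_fat <- if (is.null(fat_labels))
      grepl("^fat", em$label, ignore.case = TRUE)
    else em$label %in% fat_labels
    ref_id <- if (is_fat) 2L else 1L
    am <- angle_map(ref_cubes[[as.character(ref_id)]], em)
    ffc <- fill_factor_curve(am, thresholds)
    attr(ffc, "min_angle") <- min(am$values)
    osca <- determine_osca(ffc)
    th <- osca
    if (!is.null(threshold_overrides) &&
        em$label %in% names(threshold_overrides))
      th <- unname(threshold_overrides[em$label])
    list(endmember = em, osca = osca, threshold = th,
         reference_id = ref_id, fill_factor = ffc)
  })
  names(entries) <- vapply(endmembers, `[[`, character(1), "label")
  structure(list(entries = entries, version = "hsdfm-library-1"),
            class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("<endmember_library> %d entries (%s)\n",
              length(x$entries), x$version))
  for (e in x$entries)
    cat(sprintf("  %-12s OSCA %.4f  threshold %.4f  ref %d  (%d px)\n",
                e$endmember$label, e$osca, e$threshold, e$reference_id,
                e$endmember$n_pixels))
  invisible(x)
}

#' Integrated multi-type segmentation map
#'
#' Per pixel, among the tissue types whose angle falls strictly below
#' their threshold, the type with the minimum angle wins; pixels passing
#' no threshold are background (0). Ties are broken toward the earlier
#' library entry and counted.
#'
#' @param cube A \code{\link{reflectance_cube}}.
#' @param lib An \code{\link{endmember_library}}.
#' @return Object of class \code{segmentation_map}: \code{labels} integer
#'   raster (0 = background), \code{level_labels}, \code{colors},
#'   \code{n_ties}, \code{angle_stack} (rows x cols x types).
#' @export
integrate_segmentation <- function(cube, lib) {
  stopifnot(inherits(cube, "reflectance_cube"),
            inherits(lib, "endmember_library"))
  if (length(lib$entries) == 0L) stop("empty library")
  d <- dim(cube$values)
  k <- length(lib$entries)
  ang <- array(NA_real_, dim = c(d[1L], d[2L], k))
  pass <- array(FALSE, dim = c(d[1L], d[2L], k))
  for (i in seq_len(k)) {
    e <- lib$entries[[i]]
    am <- angle_map(cube, e$endmember)
    ang[, , i] <- am$values
    pass[, , i] <- am$values < e$threshold
  }
  angm <- matrix(ang, ncol = k)
  passm <- matrix(pass, ncol = k)
  lab <- integer(nrow(angm))
  n_ties <- 0L
  masked <- angm
  masked[!passm] <- Inf
  best <- max.col(-masked, ties.method = "first")
  any_pass <- rowSums(passm) > 0L
  minv <- masked[cbind(seq_len(nrow(masked)), best)]
  n_ties <- sum(any_pass & rowSums(masked == minv & passm) > 1L)
  lab[any_pass] <- best[any_pass]
  labels <- vapply(lib$entries, function(e) e$endmember$label, character(1))
  colors <- vapply(lib$entries, function(e) e$endmember$color, character(1))
  structure(list(labels = matrix(lab, d[1L], d[2L]),
                 level_labels = unname(labels), colors = unname(colors),
                 n_ties = n_ties, angle_stack = ang),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:length(x$level_labels),
                      labels = c("background", x$level_labels)))
  cat("<segmentation_map>\n")
  print(tab)
  if (x$n_ties > 0) cat(sprintf("  (%d min-angle ties broken by order)\n",
                                x$n_ties))
  invisible(x)
}

#' Render a segmentation map as an RGB array
#'
#' @param seg A \code{\link{segmentation_map}}.
#' @param background Background color.
#' @return Array (rows, cols, 3) in [0, 1].
#' @export
segmentation_to_rgb <- function(seg, background = "black") {
  stopifnot(inherits(seg, "segmentation_map"))
  cols <- c(background, seg$colors)
  rgb <- grDevices::col2rgb(cols) / 255
  lab <- seg$labels + 1L
  d <- dim(seg$labels)
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, lab], d[1L], d[2L])
  out
}
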