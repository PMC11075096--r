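#' Write a cube in ENVI format
#'
#' Writes the raster as a binary ENVI file (BSQ interleave, 64-bit float,
#' little-endian) with a text \code{.hdr} header carrying the wavelength
#' list in nm; exposures (for raw cubes) go into the header as a
#' nonstandard \code{exposure times} field.
#'
#' @param cube A \code{\link{hypercube}} or \code{\link{reflectance_cube}}.
#' @param path Path of the binary file; the header is written to
#'   \code{<path>.hdr}.
#' @return \code{path}, invisibly.
#' @export
write_envi <- function(cube, path) {
  vals <- if (inherits(cube, "hypercube")) cube$intensity else cube$values
  d <- dim(vals)
  hdr <- c(
    "ENVI",
    "description = {hsdfm data cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", cube$grid$wavelengths),
                  collapse = ", ")))
  if (inherits(cube, "hypercube"))
    hdr <- c(hdr, sprintf("exposure times = {%s}",
                          paste(sprintf("%.17g", cube$exposure),
                                collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, each band row-major (line, then sample)
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3L]))
    writeBin(as.vector(t(vals[, , b])), con, size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?mi)^%s *= *[^\\{\\n]+", key),
                                 txt, perl = TRUE))
    if (length(m) == 0L) return(NA_character_)
    trimws(sub("^[^=]*=", "", m))
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?si)%s *= *\\{[^}]*\\}", key),
                                 txt, perl = TRUE))
    if (length(m) == 0L) return(NULL)
    body <- sub("^[^{]*\\{", "", sub("\\}.*$", "", m))
    as.numeric(strsplit(body, ",")[[1L]])
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       byte_order = as.integer(get_scalar("byte order")),
       wavelength = get_list("wavelength"),
       exposure = get_list("exposure times"))
}

#' Read an ENVI cube (BSQ, BIL or BIP interleave)
#'
#' @param path Path to the binary file; the header is looked up at
#'   \code{<path>.hdr}.
#' @param as Return type: \code{"reflectance"} (default) or \code{"raw"}
#'   (a \code{\link{hypercube}}; requires exposures in the header or via
#'   \code{exposure}).
#' @param exposure Optional exposure vector overriding the header.
#' @return A \code{\link{reflectance_cube}} or \code{\link{hypercube}}.
#' @export
read_envi <- function(path, as = c("reflectance", "raw"), exposure = NULL) {
  as <- match.arg(as)
  h <- parse_envi_header(paste0(path, ".hdr"))
  if (!h$data_type %in% c(4L, 5L))
    stop("only float (4) and double (5) ENVI data types are supported")
  size <- if (h$data_type == 5L) 8L else 4L
  endian <- if (isTRUE(h$byte_order == 1L)) "big" else "little"
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = size, endian = endian)
  arr <- switch(h$interleave,
    bsq = aperm(array(raw, dim = c(h$samples, h$lines, h$bands)),
                c(2L, 1L, 3L)),
    bil = aperm(array(raw, dim = c(h$samples, h$bands, h$lines)),
                c(3L, 1L, 2L)),
    bip = aperm(array(raw, dim = c(h$bands, h$samples, h$lines)),
                c(3L, 2L, 1L)),
    stop("unsupported interleave: ", h$interleave))
  grid <- if (!is.null(h$wavelength)) wavelength_grid(h$wavelength)
          else wavelength_grid(seq_len(h$bands))
  if (as == "raw") {
    expo <- if (!is.null(exposure)) exposure else h$exposure
    if (is.null(expo))
      stop("raw cube requested but no exposure times available")
    hypercube(arr, expo, grid)
  } else {
    reflectance_cube(arr, grid)
  }
}

#' Write a cube as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit-float page per band, values scaled to [0, 1] by the cube
#' maximum; the sidecar (\code{<path>.json}) records the scale factor,
#' wavelengths and (for raw cubes) exposure times.
#'
#' @param cube A \code{\link{hypercube}} or \code{\link{reflectance_cube}}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_tiff_stack <- function(cube, path) {
  vals <- if (inherits(cube, "hypercube")) cube$intensity else cube$values
  mx <- max(vals, 1e-300)
  pages <- lapply(seq_len(dim(vals)[3L]), function(b)
    pmin(pmax(vals[, , b] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(scale = mx, wavelengths = cube$grid$wavelengths,
               bandwidth = cube$grid$bandwidth,
               kind = if (inherits(cube, "hypercube")) "raw" else "reflectance")
  if (inherits(cube, "hypercube")) meta$exposure <- cube$exposure
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a multi-page TIFF stack written by \code{\link{write_tiff_stack}}
#'
#' @param path TIFF path with its \code{<path>.json} sidecar.
#' @return A \code{\link{hypercube}} or \code{\link{reflectance_cube}}
#'   per the sidecar's \code{kind}.
#' @export
read_tiff_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]] * meta$scale
  grid <- wavelength_grid(meta$wavelengths, meta$bandwidth)
  if (identical(meta$kind, "raw"))
    hypercube(arr, meta$exposure, grid)
  else
    reflectance_cube(arr, grid)
}

#' Serialize an endmember library to versioned JSON
#'
#' @param lib An \code{\link{endmember_library}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "endmember_library"))
  entries <- lapply(lib$entries, function(e) list(
    label = e$endmember$label,
    mu = e$endmember$mu,
    spread = e$endmember$spread,
    n_pixels = e$endmember$n_pixels,
    color = e$endmember$color,
    wavelengths = e$endmember$grid$wavelengths,
    bandwidth = e$endmember$grid$bandwidth,
    osca = e$osca,
    threshold = e$threshold,
    reference_id = e$reference_id))
  jsonlite::write_json(list(version = lib$version,
                            entries = unname(entries)),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read an endmember library from JSON
#'
#' @param path Path written by \code{\link{write_library}}.
#' @return An \code{\link{endmember_library}} (without fill-factor
#'   curves, which are not serialized).
#' @export
read_library <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(y$version, "hsdfm-library-1"))
    stop("unrecognized library version: ", y$version)
  entries <- lapply(y$entries, function(r) {
    grid <- wavelength_grid(unlist(r$wavelengths), r$bandwidth)
    em <- structure(list(label = r$label, mu = unlist(r$mu),
                         spread = unlist(r$spread),
                         n_pixels = as.integer(r$n_pixels),
                         color = r$color, grid = grid),
                    class = "endmember")
    list(endmember = em, osca = r$osca, threshold = r$threshold,
         reference_id = as.integer(r$reference_id), fill_factor = NULL)
  })
  names(entries) <- vapply(entries, function(e) e$endmember$label,
                           character(1))
  structure(list(entries = entries, version = y$version),
            class = "endmember_library")
}

#' Write an ROI label raster with a legend
#'
#' 8-bit single-page TIFF (label values 0-255) plus a JSON legend mapping
#' label values to tissue names.
#'
#' @param labels Integer matrix of label values (0 = unannotated).
#' @param legend Named character vector or list: names are label values
#'   as strings, values are tissue names.
#' @param path Output TIFF path; legend goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_roi_mask <- function(labels, legend, path) {
  labels <- as.matrix(labels)
  if (any(labels < 0 | labels > 255)) stop("labels must fit 8 bits")
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(as.list(legend), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an ROI label raster and its legend
#'
#' @param path TIFF path written by \code{\link{write_roi_mask}}.
#' @return List with \code{labels} (integer matrix) and \code{legend}.
#' @export
read_roi_mask <- function(path) {
  img <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  legend <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  list(labels = labels, legend = legend)
}
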