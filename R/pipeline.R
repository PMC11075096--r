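#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything a reproducible run needs: the scene (a
#' \code{\link{scene_spec}} or a YAML path), the template set, flattening
#' and clustering parameters, reference-cube template labels for the OSCA
#' analysis, and an optional output directory. A run's config plus seed
#' reproduce its outputs.
#'
#' @param scene A \code{\link{scene_spec}} or path to a scene YAML.
#' @param templates List of \code{\link{spectral_template}}s; default the
#'   built-in tissue shapes.
#' @param flatten Apply illumination flattening (default TRUE).
#' @param sigma Flattening scale in pixels.
#' @param ref1,ref2 Template labels for the two reference cubes: ref1 is
#'   the fat-only cube (used for non-fat endmembers), ref2 a fat-free
#'   cube standing in for the fibroadenoma-only acquisition (used for fat
#'   endmembers).
#' @param k,restarts Clustering parameters (defaults 5 and 10).
#' @param seed Seed for the unsupervised stage (scene seed lives in the
#'   scene spec).
#' @param threshold_overrides Named numeric vector of manual threshold
#'   angles.
#' @param out_dir Optional output directory; when set, artifacts and a
#'   manifest are written.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(scene, templates = make_paper_templates(),
                       flatten = TRUE, sigma = 50,
                       ref1 = "fat", ref2 = "ICT1",
                       k = 5, restarts = 10, seed = 0,
                       threshold_overrides = NULL, out_dir = NULL) {
  if (is.character(scene)) scene <- read_scene_spec(scene)
  stopifnot(inherits(scene, "scene_spec"))
  labs <- vapply(templates, `[[`, character(1), "label")
  for (r in c(ref1, ref2))
    if (!r %in% labs)
      stop(sprintf("configuration error: reference template '%s' not in template set", r))
  structure(list(scene = scene, templates = templates, flatten = flatten,
                 sigma = sigma, ref1 = ref1, ref2 = ref2, k = k,
                 restarts = restarts, seed = seed,
                 threshold_overrides = threshold_overrides,
                 out_dir = out_dir),
            class = "run_config")
}

default_palette <- function(labels) {
  pal <- c("red", "yellow", "blue", "skyblue", "navy", "cyan", "purple",
           "magenta", "white", "green", "orange", "brown")
  stats::setNames(rep(pal, length.out = length(labels)), labels)
}

# normalize (+ flatten) one generated triplet
process_triplet <- function(trip, flatten, sigma) {
  rc <- normalize_cube(trip$sample, trip$dark, trip$reference)
  if (flatten) rc <- flatten_cube(rc, sigma) else rc
}

#' Supervised pipeline: extract, calibrate, segment
#'
#' Generates (or accepts) the scene, normalizes and flattens it, extracts
#' one endmember per planted tissue type from the ground-truth regions
#' (standing in for histopathology-annotated ROIs), determines each
#' endmember's OSCA against the two synthetic reference cubes, and builds
#' the integrated minimum-angle segmentation map.
#'
#' @param config A \code{\link{run_config}}.
#' @param scene_data Optional precomputed result of
#'   \code{\link{generate_cube}} for the config's scene.
#' @return List with \code{cube} (flattened reflectance), \code{library},
#'   \code{segmentation}, \code{endmembers}, \code{scene_data},
#'   \code{ref_cubes}.
#' @export
run_supervised <- function(config, scene_data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(scene_data))
    scene_data <- generate_cube(config$scene, config$templates)
  rc <- process_triplet(scene_data, config$flatten, config$sigma)

  labs <- attr(scene_data$labels, "labels")
  # ROIs emulate histopathology-annotated pure regions: only pixels whose
  # planted weight for the type is 1 qualify; mixed pixels are excluded
  pure <- scene_data$abundance == 1
  present <- which(apply(pure, 3L, any))
  pal <- default_palette(labs)
  endmembers <- lapply(present, function(t)
    extract_endmember(rc, pure[, , t], labs[t], pal[labs[t]]))
  names(endmembers) <- labs[present]

  tpl_by_label <- stats::setNames(config$templates,
                                  vapply(config$templates, `[[`,
                                         character(1), "label"))
  ref_spec <- config$scene
  ref_spec$regions <- list()
  ref_spec$seed <- config$scene$seed + 7777L
  ref1 <- generate_reference_cube(tpl_by_label[[config$ref1]], ref_spec)
  ref_spec$seed <- config$scene$seed + 8888L
  ref2 <- generate_reference_cube(tpl_by_label[[config$ref2]], ref_spec)
  ref_cubes <- list(`1` = process_triplet(ref1, config$flatten, config$sigma),
                    `2` = process_triplet(ref2, config$flatten, config$sigma))

  lib <- build_library(endmembers, ref_cubes,
                       threshold_overrides = config$threshold_overrides)
  seg <- integrate_segmentation(rc, lib)

  out <- list(cube = rc, library = lib, segmentation = seg,
              endmembers = endmembers, scene_data = scene_data,
              ref_cubes = ref_cubes)
  if (!is.null(config$out_dir)) write_supervised_outputs(out, config)
  out
}

#' Unsupervised pipeline: cluster and unmix
#'
#' Stacks the reflectance cube(s), runs seeded K-means with restarts,
#' ranks clusters by between-cluster variance share, and solves the NNLS
#' abundances against the discovered centroids.
#'
#' @param config A \code{\link{run_config}}.
#' @param cubes Optional reflectance cube or list of cubes (default: the
#'   config's scene is generated and processed).
#' @param scene_data Optional precomputed \code{\link{generate_cube}}
#'   output.
#' @param nnls Compute abundance maps (default TRUE).
#' @return List with \code{pixels} (\code{pixel_matrix}),
#'   \code{clusters}, \code{ranking}, \code{abundance}, \code{maps}.
#' @export
run_unsupervised <- function(config, cubes = NULL, scene_data = NULL,
                             nnls = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cubes)) {
    if (is.null(scene_data))
      scene_data <- generate_cube(config$scene, config$templates)
    cubes <- process_triplet(scene_data, config$flatten, config$sigma)
  }
  pm <- stack_cubes(cubes)
  cr <- kmeans_endmembers(pm, k = config$k, restarts = config$restarts,
                          seed = config$seed)
  ranking <- rank_clusters(cr, pm)
  ab <- NULL
  maps <- NULL
  if (nnls) {
    ab <- nnls_abundances(pm, cr)
    maps <- abundance_to_maps(ab, pm, ranking)
  }
  out <- list(pixels = pm, clusters = cr, ranking = ranking,
              abundance = ab, maps = maps)
  if (!is.null(config$out_dir)) write_unsupervised_outputs(out, config)
  out
}

#' Cross-validation pipeline
#'
#' Runs (or accepts) the supervised and unsupervised stages on the same
#' scene and validates the library against the clustering: centroid
#' matching, residual ratios, and segmentation/abundance colocalization.
#'
#' @param config A \code{\link{run_config}}.
#' @param sup,unsup Optional precomputed stage outputs.
#' @return A \code{match_report} (see \code{\link{validate_library}})
#'   plus the two stage outputs, invisibly bundled.
#' @export
run_crossval <- function(config, sup = NULL, unsup = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(sup)) sup <- run_supervised(config)
  if (is.null(unsup))
    unsup <- run_unsupervised(config, cubes = sup$cube,
                              scene_data = sup$scene_data)
  report <- validate_library(sup$library, unsup$clusters,
                             sup$segmentation, unsup$abundance,
                             unsup$pixels)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_match_report(report, file.path(config$out_dir,
                                         "crossval_report.json"))
    write_manifest(config)
  }
  list(report = report, supervised = sup, unsupervised = unsup)
}

write_supervised_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_library(out$library, file.path(config$out_dir, "library.json"))
  write_envi(out$cube, file.path(config$out_dir, "reflectance.envi"))
  seg <- out$segmentation
  utils::write.csv(seg$labels,
                   file.path(config$out_dir, "segmentation_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(level_labels = seg$level_labels,
                            colors = seg$colors, n_ties = seg$n_ties),
                       file.path(config$out_dir, "segmentation_meta.json"),
                       auto_unbox = TRUE)
  write_manifest(config)
  invisible(NULL)
}

write_unsupervised_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cent <- as.data.frame(t(out$clusters$centroids))
  names(cent) <- paste0("cluster", seq_len(ncol(cent)))
  cent <- cbind(wavelength = out$pixels$grid$wavelengths, cent)
  utils::write.table(cent, file.path(config$out_dir, "centroids.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(out$ranking, file.path(config$out_dir, "ranking.csv"),
                   row.names = FALSE)
  if (!is.null(out$abundance)) {
    for (i in seq_len(ncol(out$abundance$M))) {
      m <- unstack_vector(out$abundance$M[, i], out$pixels)[[1L]]
      utils::write.csv(m, file.path(config$out_dir,
                                    sprintf("abundance_%02d.csv", i)),
                       row.names = FALSE)
    }
  }
  write_manifest(config)
  invisible(NULL)
}

# serialize a config to canonical JSON for hashing (functions by name)
config_fingerprint <- function(config) {
  tpl <- lapply(config$templates, function(t)
    list(label = t$label, spectrum = t$spectrum))
  scn <- unclass(config$scene)
  keep <- list(scene = scn, templates = tpl, flatten = config$flatten,
               sigma = config$sigma, ref1 = config$ref1,
               ref2 = config$ref2, k = config$k,
               restarts = config$restarts, seed = config$seed,
               threshold_overrides = config$threshold_overrides)
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = I(17))
}

#' Write a run manifest with config hash and file checksums
#'
#' The manifest records the package version, the md5 of the canonical
#' config serialization, the seeds, and the md5 of every artifact in the
#' output directory; reruns of the same config produce identical hashes.
#'
#' @param config A \code{\link{run_config}} with a set \code{out_dir}.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(config) {
  stopifnot(!is.null(config$out_dir))
  tmp <- tempfile()
  writeLines(config_fingerprint(config), tmp)
  cfg_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package = as.character(utils::packageVersion("hsdfm")),
    config_md5 = cfg_md5,
    scene_seed = config$scene$seed,
    kmeans_seed = config$seed,
    files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(config$out_dir, "manifest.json"))
}
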