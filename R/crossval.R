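#' Match unsupervised centroids to library endmembers
#'
#' Greedy one-to-one assignment by ascending spectral angle between each
#' K-means centroid and each library endmember; candidate pairs with an
#' angle above \code{angle_cap} are left unmatched.
#'
#' @param lib An \code{\link{endmember_library}}.
#' @param cr A \code{\link{cluster_result}}.
#' @param angle_cap Maximum pairing angle in rad (default 0.3).
#' @return Object of class \code{match_report}: \code{pairs} (data.frame
#'   label/cluster/angle), \code{unmatched_clusters},
#'   \code{unmatched_labels}.
#' @export
match_endmembers <- function(lib, cr, angle_cap = 0.3) {
  stopifnot(inherits(lib, "endmember_library"),
            inherits(cr, "cluster_result"))
  labels <- names(lib$entries)
  nl <- length(labels)
  k <- cr$k
  if (nl == 0L || k == 0L) stop("library and clustering must be nonempty")
  A <- matrix(NA_real_, nl, k, dimnames = list(labels, NULL))
  for (i in seq_len(nl)) for (j in seq_len(k))
    A[i, j] <- spectral_angle(lib$entries[[i]]$endmember$mu,
                              cr$centroids[j, ])
  pairs <- data.frame(label = character(0), cluster = integer(0),
                      angle = numeric(0))
  free_l <- rep(TRUE, nl)
  free_c <- rep(TRUE, k)
  repeat {
    sub <- A
    sub[!free_l, ] <- Inf
    sub[, !free_c] <- Inf
    m <- min(sub)
    if (!is.finite(m) || m > angle_cap) break
    w <- which(sub == m, arr.ind = TRUE)[1L, ]
    pairs <- rbind(pairs, data.frame(label = labels[w[1L]],
                                     cluster = unname(w[2L]),
                                     angle = m))
    free_l[w[1L]] <- FALSE
    free_c[w[2L]] <- FALSE
  }
  structure(list(pairs = pairs,
                 unmatched_clusters = which(free_c),
                 unmatched_labels = labels[free_l],
                 angle_cap = angle_cap),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  if (nrow(x$pairs) > 0) print(x$pairs, row.names = FALSE)
  if (length(x$unmatched_clusters) > 0)
    cat("  unmatched clusters:", paste(x$unmatched_clusters, collapse = ", "),
        "\n")
  if (length(x$unmatched_labels) > 0)
    cat("  unmatched labels:", paste(x$unmatched_labels, collapse = ", "),
        "\n")
  invisible(x)
}

#' Bandwise residual ratio between supervised and unsupervised endmembers
#'
#' Computes, per band, (mu_sup - mu_unsup) / mu_unsup, exactly in that
#' argument order, plus its maximum absolute value. Because the
#' SCA-extracted supervised endmember is scale-free while a K-means
#' centroid carries amplitude, both spectra are by default first
#' normalized to equal band-mean (\code{align_scale = TRUE}); with
#' alignment off the raw spectra are compared.
#'
#' @param mu_sup,mu_unsup Numeric spectra; \code{mu_unsup} must be
#'   strictly positive in every band.
#' @param align_scale Normalize both spectra to unit band-mean first.
#' @return List with \code{ratio} (per band), \code{max_abs}, and
#'   \code{within_2pct} (logical verdict, max below 0.02).
#' @export
residual_ratio <- function(mu_sup, mu_unsup, align_scale = TRUE) {
  if (length(mu_sup) != length(mu_unsup))
    stop("spectra must share a grid")
  if (any(mu_unsup <= 0))
    stop("mu_unsup must be strictly positive in every band")
  if (align_scale) {
    mu_sup <- mu_sup / mean(mu_sup)
    mu_unsup <- mu_unsup / mean(mu_unsup)
  }
  ratio <- (mu_sup - mu_unsup) / mu_unsup
  list(ratio = ratio, max_abs = max(abs(ratio)),
       within_2pct = max(abs(ratio)) < 0.02)
}

#' Dice colocalization between a segmentation and an abundance mask
#'
#' Thresholds the abundance raster and computes the Dice coefficient
#' 2|A.B| / (|A| + |B|) against the binary segmentation. When both masks
#' are empty the score is returned as 0 and flagged undefined.
#'
#' @param seg Binary matrix (0/1 or logical).
#' @param abundance Numeric matrix of same shape.
#' @param abundance_threshold Absolute threshold; default half the
#'   raster's maximum.
#' @return List with \code{dice}, \code{threshold}, \code{undefined}.
#' @export
colocalization_score <- function(seg, abundance, abundance_threshold = NULL) {
  seg <- as.matrix(seg)
  abundance <- as.matrix(abundance)
  if (!all(dim(seg) == dim(abundance)))
    stop("shape mismatch between segmentation and abundance rasters")
  if (is.null(abundance_threshold))
    abundance_threshold <- 0.5 * max(abundance)
  a <- seg > 0
  b <- abundance >= abundance_threshold
  denom <- sum(a) + sum(b)
  if (denom == 0)
    return(list(dice = 0, threshold = abundance_threshold, undefined = TRUE))
  list(dice = 2 * sum(a & b) / denom, threshold = abundance_threshold,
       undefined = FALSE)
}

#' Full cross-validation of a library against an unsupervised run
#'
#' Matches K-means centroids to library endmembers, then for each matched
#' pair computes the spectral angle, the maximum absolute residual ratio,
#' and the Dice colocalization between the supervised segmentation of the
#' type and the thresholded abundance map of the cluster. A pair passes
#' when its residual stays below 2 percent and its Dice at or above the
#' floor.
#'
#' @param lib An \code{\link{endmember_library}}.
#' @param cr A \code{\link{cluster_result}}.
#' @param seg A \code{\link{segmentation_map}} of the same scene.
#' @param ab An \code{\link{abundance_matrix}} for \code{cr}'s centroids.
#' @param pm The \code{\link{pixel_matrix}} behind \code{cr} and
#'   \code{ab}.
#' @param cube_id Which source cube's rasters to score (default 1).
#' @param dice_floor Minimum Dice for a pass verdict (default 0.5).
#' @param angle_cap Matching cap passed to
#'   \code{\link{match_endmembers}}.
#' @param align_scale Passed to \code{\link{residual_ratio}}.
#' @return A \code{match_report} whose \code{pairs} gains
#'   \code{max_residual}, \code{dice} and \code{pass} columns.
#' @export
validate_library <- function(lib, cr, seg, ab, pm, cube_id = 1L,
                             dice_floor = 0.5, angle_cap = 0.3,
                             align_scale = TRUE) {
  rep0 <- match_endmembers(lib, cr, angle_cap)
  pairs <- rep0$pairs
  if (nrow(pairs) > 0) {
    pairs$max_residual <- NA_real_
    pairs$dice <- NA_real_
    pairs$pass <- NA
    for (i in seq_len(nrow(pairs))) {
      lab <- pairs$label[i]
      cl <- pairs$cluster[i]
      rr <- residual_ratio(lib$entries[[lab]]$endmember$mu,
                           cr$centroids[cl, ], align_scale = align_scale)
      type_idx <- match(lab, seg$level_labels)
      seg_bin <- (seg$labels == type_idx) * 1L
      ab_map <- unstack_vector(ab$M[, cl], pm)[[cube_id]]
      dice <- colocalization_score(seg_bin, ab_map)
      pairs$max_residual[i] <- rr$max_abs
      pairs$dice[i] <- dice$dice
      pairs$pass[i] <- rr$max_abs < 0.02 && dice$dice >= dice_floor
    }
  }
  rep0$pairs <- pairs
  rep0$dice_floor <- dice_floor
  rep0
}

#' Serialize a match report to JSON
#'
#' @param report A \code{match_report}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_match_report <- function(report, path) {
  out <- list(pairs = report$pairs,
              unmatched_clusters = report$unmatched_clusters,
              unmatched_labels = report$unmatched_labels,
              angle_cap = report$angle_cap,
              dice_floor = report$dice_floor)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized match report
#'
#' @param path JSON file written by \code{\link{write_match_report}}.
#' @return A \code{match_report}.
#' @export
read_match_report <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = as.data.frame(y$pairs),
                 unmatched_clusters = as.integer(y$unmatched_clusters),
                 unmatched_labels = as.character(y$unmatched_labels),
                 angle_cap = y$angle_cap, dice_floor = y$dice_floor),
            class = "match_report")
}
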