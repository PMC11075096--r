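#' Stack reflectance cubes into a pixel matrix
#'
#' Converts one or more cubes sharing a grid into an n x p matrix (n
#' pixels, p wavelengths) with an index mapping each row back to its
#' source cube and raster position, so maps can be reconstructed.
#'
#' @param cubes A \code{\link{reflectance_cube}} or list of them.
#' @return Object of class \code{pixel_matrix}: \code{X} (n x p),
#'   \code{index} (data.frame cube/row/col), \code{grid}, \code{dims}.
#' @export
stack_cubes <- function(cubes) {
  if (inherits(cubes, "reflectance_cube")) cubes <- list(cubes)
  if (length(cubes) == 0L) stop("no cubes")
  grid <- cubes[[1L]]$grid
  Xs <- vector("list", length(cubes))
  idx <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    cb <- cubes[[i]]
    stopifnot(inherits(cb, "reflectance_cube"))
    stop_if_grid_mismatch(grid, cb$grid, "stacked cubes")
    d <- dim(cb$values)
    Xs[[i]] <- matrix(cb$values, nrow = d[1L] * d[2L])
    idx[[i]] <- data.frame(cube = i,
                           row = rep(seq_len(d[1L]), times = d[2L]),
                           col = rep(seq_len(d[2L]), each = d[1L]))
  }
  structure(list(X = do.call(rbind, Xs), index = do.call(rbind, idx),
                 grid = grid,
                 dims = lapply(cubes, function(cb) dim(cb$values)[1:2])),
            class = "pixel_matrix")
}

#' Reconstruct per-cube rasters from a pixel vector
#'
#' Inverse of the stacking order used by \code{\link{stack_cubes}}.
#'
#' @param v Numeric vector with one value per pixel row.
#' @param pm The \code{\link{pixel_matrix}} the vector is aligned to.
#' @return List of matrices, one per source cube.
#' @export
unstack_vector <- function(v, pm) {
  stopifnot(inherits(pm, "pixel_matrix"))
  if (length(v) != nrow(pm$X)) stop("length mismatch")
  out <- vector("list", length(pm$dims))
  offset <- 0L
  for (i in seq_along(pm$dims)) {
    d <- pm$dims[[i]]
    n <- d[1L] * d[2L]
    out[[i]] <- matrix(v[(offset + 1L):(offset + n)], d[1L], d[2L])
    offset <- offset + n
  }
  out
}

#' K-means endmember discovery
#'
#' Lloyd's algorithm on the pixel spectra as-is (no per-pixel
#' normalization): initial centers are drawn uniformly from the distinct
#' rows, iterations stop when assignments no longer change (or after
#' \code{max_iter}), empty clusters are re-seeded from the point farthest
#' from its current center, and the best of \code{restarts} random starts
#' by within-cluster sum of squares is returned.
#'
#' @param pm A \code{\link{pixel_matrix}} (or bare numeric matrix).
#' @param k Number of clusters (default 5).
#' @param restarts Number of random starts (default 10).
#' @param seed Integer seed; required for reproducibility (default 0).
#' @param max_iter Iteration cap per start (default 300).
#' @return Object of class \code{cluster_result}: \code{k},
#'   \code{centroids} (k x p), \code{assignment} (length n),
#'   \code{objective}, \code{sizes}, \code{iterations}, \code{restarts},
#'   \code{seed}, \code{n_reseeded}.
#' @export
kmeans_endmembers <- function(pm, k = 5, restarts = 10, seed = 0,
                              max_iter = 300) {
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  n <- nrow(X)
  distinct <- unique(X)
  if (k > nrow(distinct))
    stop("k exceeds the number of distinct pixel spectra")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    fit <- lloyd_once(X, centers, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(c(best, list(k = k, restarts = restarts, seed = seed)),
            class = "cluster_result")
}

# one Lloyd run from given centers
lloyd_once <- function(X, centers, max_iter) {
  n <- nrow(X)
  k <- nrow(centers)
  xsq <- rowSums(X^2)
  assign_old <- integer(n)
  n_reseeded <- 0L
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # squared distances via ||x||^2 - 2 x.c + ||c||^2
    cr <- rowSums(centers^2)
    D <- outer(xsq, cr, "+") - 2 * X %*% t(centers)
    asg <- max.col(-D, ties.method = "first")
    trace <- c(trace, sum(pmax(D[cbind(seq_len(n), asg)], 0)))
    # recompute means; re-seed empty clusters from the farthest point
    for (i in seq_len(k)) {
      members <- which(asg == i)
      if (length(members) == 0L) {
        far <- which.max(D[cbind(seq_len(n), asg)])
        asg[far] <- i
        members <- far
        n_reseeded <- n_reseeded + 1L
      }
      centers[i, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (identical(asg, assign_old)) break
    assign_old <- asg
  }
  obj <- sum((X - centers[asg, , drop = FALSE])^2)
  list(centroids = centers, assignment = asg, objective = obj,
       sizes = tabulate(asg, nbins = k), iterations = it,
       n_reseeded = n_reseeded, objective_trace = trace)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, objective %.6g, sizes: %s\n",
              x$k, x$objective, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Rank clusters by between-cluster variance share
#'
#' Scores each cluster by its size-weighted squared centroid distance from
#' the global mean spectrum, normalized to shares summing to one (the
#' between-cluster variance decomposition); clusters are ranked in
#' descending share, the "most abundant" endmembers first.
#'
#' @param cr A \code{\link{cluster_result}}.
#' @param pm The \code{\link{pixel_matrix}} it was fit to.
#' @return data.frame with \code{cluster}, \code{share}, \code{size},
#'   ordered by descending share; attribute \code{degenerate} flags an
#'   all-zero between-cluster variance (e.g. k = 1).
#' @export
rank_clusters <- function(cr, pm) {
  stopifnot(inherits(cr, "cluster_result"))
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  xbar <- colMeans(X)
  dev <- sweep(cr$centroids, 2L, xbar)
  score <- cr$sizes * rowSums(dev^2)
  tot <- sum(score)
  degenerate <- tot <= 0
  share <- if (degenerate) rep(0, cr$k) else score / tot
  out <- data.frame(cluster = seq_len(cr$k), share = share,
                    size = cr$sizes)
  out <- out[order(-out$share, out$cluster), ]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Non-negative least-squares abundance estimation
#'
#' Solves, for every pixel spectrum x_j, \eqn{\min_{m \ge 0} \|U m -
#' x_j\|_2} where the columns of U are the endmember spectra
#' (Lawson-Hanson active set via \code{pracma::lsqnonneg}). Abundances are
#' not sum-to-one normalized.
#'
#' @param pm A \code{\link{pixel_matrix}} (or bare matrix, pixels in rows).
#' @param U Endmember matrix, p x k (columns are spectra); a
#'   \code{\link{cluster_result}} or list of templates/endmembers is also
#'   accepted.
#' @return Object of class \code{abundance_matrix}: \code{M} (n x k,
#'   nonnegative), \code{U}, \code{residuals} (per-pixel L2 residual).
#' @export
nnls_abundances <- function(pm, U) {
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  U <- endmember_matrix(U, ncol(X))
  if (any(colSums(U^2) == 0)) stop("U columns must be nonzero")
  if (qr(U)$rank < ncol(U))
    warning("endmember matrix is rank-deficient; NNLS solutions may be non-unique")
  n <- nrow(X)
  k <- ncol(U)
  M <- matrix(0, n, k)
  res <- numeric(n)
  for (j in seq_len(n)) {
    sol <- pracma::lsqnonneg(U, X[j, ])
    M[j, ] <- sol$x
    res[j] <- sqrt(sum((U %*% sol$x - X[j, ])^2))
  }
  structure(list(M = M, U = U, residuals = res),
            class = "abundance_matrix")
}

# coerce various endmember carriers to a p x k matrix
endmember_matrix <- function(U, p) {
  if (inherits(U, "cluster_result")) U <- t(U$centroids)
  if (is.list(U) && !is.matrix(U)) {
    cols <- lapply(U, function(e) {
      if (inherits(e, "endmember")) e$mu
      else if (inherits(e, "spectral_template")) e$spectrum
      else as.numeric(e)
    })
    U <- do.call(cbind, cols)
  }
  U <- as.matrix(U)
  if (nrow(U) != p) stop("configuration error: U must be p x k")
  U
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d pixels x %d endmembers, max residual %.4g\n",
              nrow(x$M), ncol(x$M), max(x$residuals)))
  invisible(x)
}

#' Reshape abundance columns into rasters and a top-3 composite
#'
#' Each abundance column is reshaped back to the source cube rasters; the
#' three top-ranked clusters are combined into an RGB composite with each
#' channel scaled to its own maximum.
#'
#' @param ab An \code{\link{abundance_matrix}}.
#' @param pm The \code{\link{pixel_matrix}} the abundances align to.
#' @param ranking Optional data.frame from \code{\link{rank_clusters}};
#'   default order 1..k.
#' @return List with \code{maps} (list over clusters of lists of rasters
#'   per cube) and \code{composite} (list of (rows, cols, 3) arrays per
#'   cube, channels = top three clusters).
#' @export
abundance_to_maps <- function(ab, pm, ranking = NULL) {
  stopifnot(inherits(ab, "abundance_matrix"), inherits(pm, "pixel_matrix"))
  k <- ncol(ab$M)
  maps <- lapply(seq_len(k), function(i) unstack_vector(ab$M[, i], pm))
  top <- if (is.null(ranking)) seq_len(min(3L, k)) else
    utils::head(ranking$cluster, 3L)
  ncube <- length(pm$dims)
  composite <- vector("list", ncube)
  for (ci in seq_len(ncube)) {
    d <- pm$dims[[ci]]
    comp <- array(0, dim = c(d[1L], d[2L], 3L))
    for (ch in seq_along(top)) {
      m <- maps[[top[ch]]][[ci]]
      mx <- max(ab$M[, top[ch]])
      comp[, , ch] <- if (mx > 0) m / mx else m
    }
    composite[[ci]] <- comp
  }
  list(maps = maps, composite = composite, top = top)
}
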