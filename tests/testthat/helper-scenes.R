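# Shared fixtures, all generated in code.

tiny_grid <- function(n = 3) wavelength_grid(seq(500, by = 10, length.out = n))

# small random reflectance cube with positive values
random_cube <- function(rows, cols, grid = wavelength_grid(), seed = 1) {
  set.seed(seed)
  vals <- array(stats::runif(rows * cols * length(grid), 0.1, 1),
                dim = c(rows, cols, length(grid)))
  reflectance_cube(vals, grid)
}

# four pure quadrant blocks inside an ICT background border (5 pure types)
quadrant_scene <- function(shape = c(24, 24), noise_sd = 0,
                           illumination = "none", seed = 5) {
  h <- shape[1L] %/% 2
  w <- shape[2L] %/% 2
  scene_spec(shape, regions = list(
    list(type = "rect", r0 = 2, r1 = h, c0 = 2, c1 = w,
         weights = c(blood = 1)),
    list(type = "rect", r0 = 2, r1 = h, c0 = w + 1, c1 = shape[2L] - 1L,
         weights = c(fat = 1)),
    list(type = "rect", r0 = h + 1, r1 = shape[1L] - 1L, c0 = 2, c1 = w,
         weights = c(IDC = 1)),
    list(type = "rect", r0 = h + 1, r1 = shape[1L] - 1L, c0 = w + 1,
         c1 = shape[2L] - 1L, weights = c(IMC = 1))),
    background = c(ICT1 = 1),
    noise_sd = noise_sd, illumination = illumination, seed = seed)
}

# direct (loop) spectral angle for oracle comparisons
oracle_angle <- function(x, mu) {
  num <- sum(x * mu)
  den <- sqrt(sum(x^2)) * sqrt(sum(mu^2))
  min(acos(min(max(num / den, -1), 1)), pi / 2)
}

# brute-force NNLS by active-set enumeration with KKT verification
oracle_nnls <- function(U, y) {
  k <- ncol(U)
  best <- NULL
  for (mask in 0:(2^k - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    m <- numeric(k)
    if (length(on) > 0) {
      sol <- tryCatch(qr.solve(U[, on, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < -1e-12)) next
      m[on] <- pmax(sol, 0)
    }
    grad <- t(U) %*% (U %*% m - y)     # KKT: grad >= 0, grad[m > 0] = 0
    if (any(grad < -1e-8)) next
    if (any(m > 0 & abs(grad) > 1e-8)) next
    rss <- sum((U %*% m - y)^2)
    if (is.null(best) || rss < best$rss) best <- list(m = m, rss = rss)
  }
  best$m
}

# generate + normalize (+ flatten) a config's scene cube
process_triplet_for_test <- function(cfg) {
  gdat <- generate_cube(cfg$scene, cfg$templates)
  rc <- normalize_cube(gdat$sample, gdat$dark, gdat$reference)
  if (cfg$flatten) flatten_cube(rc, cfg$sigma) else rc
}
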