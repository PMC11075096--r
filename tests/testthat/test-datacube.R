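test_that("reflectance normalization matches the exposure-corrected formula", {
  g <- tiny_grid(1)
  s <- hypercube(array(10, c(1, 1, 1)), 2, g)
  d <- hypercube(array(1, c(1, 1, 1)), 1, g)
  r <- hypercube(array(10, c(1, 1, 1)), 1, g)
  expect_equal(as.vector(normalize_cube(s, d, r)$values), 4 / 9)

  # zero dark and sample equal to reference gives unit reflectance exactly
  g35 <- wavelength_grid()
  vals <- array(rep(runif(35, 5, 50), each = 16), dim = c(4, 4, 35))
  s2 <- hypercube(vals, 30, g35)
  d2 <- hypercube(array(0, c(1, 1, 35)), 30, g35)
  r2 <- hypercube(vals, 30, g35)
  expect_equal(as.vector(normalize_cube(s2, d2, r2)$values),
               rep(1, 4 * 4 * 35))

  # randomized cubes match a direct per-pixel re-evaluation
  set.seed(11)
  tau <- list(runif(35, 10, 60), runif(35, 10, 60), runif(35, 10, 60))
  I <- array(runif(4 * 4 * 35, 100, 1000), dim = c(4, 4, 35))
  Id <- array(runif(4 * 4 * 35, 1, 5), dim = c(4, 4, 35))
  Ir <- array(runif(4 * 4 * 35, 500, 2000), dim = c(4, 4, 35))
  out <- normalize_cube(hypercube(I, tau[[1]], g35),
                        hypercube(Id, tau[[2]], g35),
                        hypercube(Ir, tau[[3]], g35))
  ref_spec <- apply(sweep(Ir, 3, tau[[3]], "/"), 3, mean)
  dark_spec <- apply(sweep(Id, 3, tau[[2]], "/"), 3, mean)
  expected <- array(0, dim = c(4, 4, 35))
  for (m in 1:4) for (n in 1:4) for (b in 1:35)
    expected[m, n, b] <- (I[m, n, b] / tau[[1]][b] - Id[m, n, b] / tau[[2]][b]) /
      (ref_spec[b] - dark_spec[b])
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("normalization is scale-consistent and rejects bad inputs", {
  g <- wavelength_grid()
  set.seed(2)
  I <- array(runif(2 * 2 * 35, 100, 500), dim = c(2, 2, 35))
  d <- hypercube(array(1, c(1, 1, 35)), 10, g)
  r <- hypercube(array(rep(runif(35, 50, 100), each = 4), c(2, 2, 35)), 10, g)
  x1 <- normalize_cube(hypercube(I, 20, g), d, r)
  x2 <- normalize_cube(hypercube(3 * I, 60, g), d, r)
  expect_equal(x1$values, x2$values, tolerance = 1e-12)

  # grid mismatch and degenerate reference
  g2 <- wavelength_grid(seq(480, 650, by = 5), bandwidth = 10)
  g3 <- wavelength_grid(seq(400, 570, by = 5))
  expect_error(normalize_cube(hypercube(I, 20, g3), d, r), "grid")
  dark_big <- hypercube(array(1000, c(1, 1, 35)), 1, g)
  expect_error(normalize_cube(hypercube(I, 20, g), dark_big, r),
               "degenerate-reference")
})

test_that("flattening removes a smooth ramp but preserves constants and means", {
  g <- tiny_grid(2)
  const <- reflectance_cube(array(0.7, c(40, 40, 2)), g)
  flat <- flatten_cube(const, sigma = 8)
  expect_lt(max(abs(flat$values - 0.7)), 1e-9)
  expect_true(flat$flattened)

  # template band times a smooth linear ramp spanning 2x the smoothing scale
  ramp <- matrix(seq(0.5, 1.5, length.out = 40), 40, 40)
  vals <- array(0, c(40, 40, 2))
  vals[, , 1] <- 0.8 * ramp
  vals[, , 2] <- 0.6 * ramp
  rc <- reflectance_cube(vals, g)
  out <- flatten_cube(rc, sigma = 20)
  cv <- function(m) stats::sd(rowMeans(m)) / mean(m)
  expect_lt(cv(out$values[, , 1]), 0.1 * cv(vals[, , 1]))
  # band means preserved
  expect_equal(apply(out$values, 3, mean), apply(vals, 3, mean),
               tolerance = 1e-6)
  # idempotent within tolerance
  out2 <- flatten_cube(out, sigma = 20)
  expect_lt(max(abs(out2$values - out$values) / abs(out$values)), 1e-3)
})

test_that("pseudo-color picks the 630/530/480 bands with percentile scaling", {
  g <- wavelength_grid()
  vals <- array(0.001, c(8, 8, 35))
  vals[, , band <- which(g$wavelengths == 630)] <- runif(64, 0.5, 1)
  rc <- reflectance_cube(vals, g)
  img <- pseudo_color(rc)
  expect_gt(max(img[, , 1]), 0.5)   # red channel carries the signal
  expect_equal(max(img[, , 2]), 0)  # constant channels collapse to zero
  expect_equal(max(img[, , 3]), 0)

  # equal values in the three channels per pixel give a gray image
  set.seed(3)
  vals2 <- array(0.2, c(6, 6, 35))
  pix <- matrix(runif(36, 0.1, 1), 6, 6)
  for (w in c(480, 530, 630)) vals2[, , which(g$wavelengths == w)] <- pix
  img2 <- pseudo_color(reflectance_cube(vals2, g))
  expect_equal(img2[, , 1], img2[, , 2])
  expect_equal(img2[, , 2], img2[, , 3])

  # percentile clipping against a direct sort-based computation
  band630 <- matrix(runif(64, 0, 2), 8, 8)
  vals3 <- array(0.5, c(8, 8, 35))
  vals3[, , which(g$wavelengths == 630)] <- band630
  img3 <- pseudo_color(reflectance_cube(vals3, g))
  q <- as.numeric(quantile(band630, c(0.01, 0.99)))
  expect_equal(img3[, , 1], pmin(pmax((band630 - q[1]) / (q[2] - q[1]), 0), 1),
               tolerance = 1e-12)

  g_nored <- wavelength_grid(seq(480, 600, by = 5))
  expect_error(pseudo_color(reflectance_cube(array(1, c(2, 2, 25)), g_nored)),
               "configuration error")
})

test_that("ENVI and TIFF round-trips preserve cubes", {
  g <- wavelength_grid()
  set.seed(7)
  vals <- array(runif(5 * 4 * 35, 0, 2), dim = c(5, 4, 35))
  rc <- reflectance_cube(vals, g)
  path <- tempfile(fileext = ".envi")
  write_envi(rc, path)
  back <- read_envi(path)
  expect_equal(back$values, rc$values, tolerance = 0)
  expect_equal(back$grid$wavelengths, g$wavelengths)

  # raw cube with exposures through ENVI
  hc <- hypercube(abs(vals) + 1, runif(35, 5, 50), g)
  path2 <- tempfile(fileext = ".envi")
  write_envi(hc, path2)
  raw <- read_envi(path2, as = "raw")
  expect_equal(raw$intensity, hc$intensity)
  expect_equal(raw$exposure, hc$exposure, tolerance = 1e-12)

  # TIFF stack with sidecar
  path3 <- tempfile(fileext = ".tif")
  write_tiff_stack(rc, path3)
  back3 <- read_tiff_stack(path3)
  expect_equal(back3$values, rc$values, tolerance = 1e-6)
})
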