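test_that("spectral angle has the closed-form values and scale invariance", {
  expect_equal(spectral_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(spectral_angle(c(1, 1), c(1, 0)), pi / 4)
  set.seed(1)
  x <- runif(35, 0.1, 1)
  y <- runif(35, 0.1, 1)
  expect_equal(spectral_angle(3.7 * x, y), spectral_angle(x, 0.2 * y),
               tolerance = 1e-12)
  expect_error(spectral_angle(c(0, 0), c(1, 1)), "degenerate")
})

test_that("endmember extraction reduces to means and standard deviations", {
  g <- tiny_grid(2)
  vals <- array(0, c(2, 2, 2))
  vals[1, 1, ] <- c(1, 3)
  vals[2, 1, ] <- c(3, 1)
  vals[1, 2, ] <- c(9, 9)
  vals[2, 2, ] <- c(9, 9)
  rc <- reflectance_cube(vals, g)
  roi <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  em <- extract_endmember(rc, roi, "toy")
  expect_equal(em$mu, c(2, 2))
  expect_equal(em$n_pixels, 2L)

  # identical spectra give zero spread
  rc2 <- reflectance_cube(array(rep(c(1, 2), each = 4), c(2, 2, 2)), g)
  em2 <- extract_endmember(rc2, matrix(TRUE, 2, 2), "const")
  expect_equal(em2$spread, c(0, 0))

  # random ROI matches direct recomputation
  cube <- random_cube(10, 10, seed = 8)
  set.seed(9)
  mask <- matrix(runif(100) < 0.4, 10, 10)
  em3 <- extract_endmember(cube, mask, "rand")
  flat <- matrix(cube$values, nrow = 100)
  expect_equal(em3$mu, colMeans(flat[which(mask), ]), tolerance = 1e-12)
  expect_equal(em3$spread, apply(flat[which(mask), ], 2, sd),
               tolerance = 1e-12)
  expect_error(extract_endmember(cube, matrix(FALSE, 10, 10), "x"),
               "empty roi")
})

test_that("angle maps equal the elementwise brute-force loop", {
  cube <- random_cube(8, 8, seed = 13)
  mu <- runif(35, 0.2, 1)
  am <- angle_map(cube, mu)
  for (i in 1:8) for (j in 1:8)
    expect_equal(am$values[i, j], oracle_angle(cube$values[i, j, ], mu),
                 tolerance = 1e-12)
  # cube of endmember copies gives the zero map
  g <- wavelength_grid()
  rc <- reflectance_cube(array(rep(mu, each = 9), c(3, 3, 35)), g)
  expect_lt(max(angle_map(rc, mu)$values), 1e-6)
})

test_that("segmentation thresholds use strict inequality", {
  am <- structure(list(values = matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                       label = "t", n_degenerate = 0L),
                  class = "angle_map")
  expect_equal(sum(segment_type(am, 0.25)), 2)
  expect_equal(sum(segment_type(am, 0.1)), 0)    # boundary excluded
  expect_equal(sum(segment_type(am, pi / 2)), 4)
  expect_error(segment_type(am, 0), "threshold")
})

test_that("fill factor and coverage match brute-force counting", {
  am <- structure(list(values = matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                       label = "t", n_degenerate = 0L),
                  class = "angle_map")
  ffc <- fill_factor_curve(am, c(0.05, 0.25, 0.45, pi / 2))
  expect_equal(ffc$fractions, c(0, 0.5, 1, 1))

  set.seed(21)
  vals <- matrix(runif(144, 0, pi / 2), 12, 12)
  am2 <- structure(list(values = vals, label = "r", n_degenerate = 0L),
                   class = "angle_map")
  grid <- default_threshold_grid()
  ffc2 <- fill_factor_curve(am2, grid)
  cov2 <- coverage_vs_threshold(am2, grid)
  for (i in seq_along(grid)) {
    expect_equal(ffc2$fractions[i], sum(vals <= grid[i]) / 144)
    expect_equal(cov2$coverage[i], sum(vals < grid[i]) / 144)
  }
  # nondecreasing, terminal value one
  expect_true(all(diff(ffc2$fractions) >= 0))
  expect_equal(ffc2$fractions[length(grid)], 1)
})

test_that("OSCA is the largest grid threshold with zero sub-threshold pixels", {
  mk_am <- function(v) structure(list(values = matrix(v, 2, 2), label = "t",
                                      n_degenerate = 0L), class = "angle_map")
  grid <- default_threshold_grid(0.01)
  # minimum exactly on the grid
  ffc <- fill_factor_curve(mk_am(c(0.1, 0.2, 0.3, 0.4)), grid)
  attr(ffc, "min_angle") <- 0.1
  expect_equal(determine_osca(ffc), 0.1)
  # off-grid minimum rounds down so the reference stays clean
  ffc2 <- fill_factor_curve(mk_am(c(0.103, 0.2, 0.3, 0.4)), grid)
  attr(ffc2, "min_angle") <- 0.103
  osca2 <- determine_osca(ffc2)
  expect_equal(osca2, 0.1)
  expect_equal(sum(mk_am(c(0.103, 0.2, 0.3, 0.4))$values < osca2), 0)
  # endmember present in the reference: first grid point
  ffc3 <- fill_factor_curve(mk_am(c(0, 0.2, 0.3, 0.4)), grid)
  attr(ffc3, "min_angle") <- 0
  expect_equal(determine_osca(ffc3), 0)
})

test_that("library construction routes references, recomputes, and serializes", {
  tpl <- make_paper_templates()
  sp <- scene_spec(c(16, 16), noise_sd = 0.01, illumination = "none",
                   seed = 31)
  ref1 <- generate_reference_cube(tpl$fat, sp)
  sp2 <- sp; sp2$seed <- 32L
  ref2 <- generate_reference_cube(tpl$ICT1, sp2)
  refs <- list(`1` = normalize_cube(ref1$sample, ref1$dark, ref1$reference),
               `2` = normalize_cube(ref2$sample, ref2$dark, ref2$reference))
  cube <- random_cube(6, 6, seed = 33)
  ems <- list(extract_endmember(cube, matrix(TRUE, 6, 6), "blood"),
              structure(list(label = "fat", mu = tpl$fat$spectrum,
                             spread = rep(0, 35), n_pixels = 5,
                             color = "yellow", grid = tpl$fat$grid),
                        class = "endmember"))
  lib <- build_library(ems, refs)
  expect_equal(lib$entries$blood$reference_id, 1L)
  expect_equal(lib$entries$fat$reference_id, 2L)

  # stored OSCA equals an independent re-run of the fill-factor analysis
  for (e in lib$entries) {
    am <- angle_map(refs[[as.character(e$reference_id)]], e$endmember)
    ffc <- fill_factor_curve(am)
    attr(ffc, "min_angle") <- min(am$values)
    expect_equal(e$osca, determine_osca(ffc))
  }

  # threshold override
  lib2 <- build_library(ems, refs, threshold_overrides = c(blood = 0.08))
  expect_equal(lib2$entries$blood$threshold, 0.08)
  expect_equal(lib2$entries$blood$osca, lib$entries$blood$osca)

  # serialization round-trips values and re-serializes byte-identically
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_library(lib, p1)
  lib_back <- read_library(p1)
  expect_equal(lib_back$entries$blood$endmember$mu,
               lib$entries$blood$endmember$mu, tolerance = 0)
  expect_equal(lib_back$entries$fat$osca, lib$entries$fat$osca)
  write_library(lib_back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the OSCA threshold yields zero positives on its own reference cube", {
  tpl <- make_paper_templates()
  sp <- scene_spec(c(24, 24), noise_sd = 0.02, illumination = "none",
                   seed = 41)
  ref1 <- generate_reference_cube(tpl$fat, sp)
  sp2 <- sp; sp2$seed <- 42L
  ref2 <- generate_reference_cube(tpl$ICT1, sp2)
  refs <- list(`1` = normalize_cube(ref1$sample, ref1$dark, ref1$reference),
               `2` = normalize_cube(ref2$sample, ref2$dark, ref2$reference))
  ems <- lapply(tpl[c("blood", "fat", "IDC", "IMC", "epi")], function(t)
    structure(list(label = t$label, mu = t$spectrum,
                   spread = rep(0, 35), n_pixels = 1, color = "gray",
                   grid = t$grid), class = "endmember"))
  lib <- build_library(ems, refs)
  for (e in lib$entries) {
    if (e$osca == 0) next  # nothing can pass a zero threshold either
    am <- angle_map(refs[[as.character(e$reference_id)]], e$endmember)
    expect_equal(sum(segment_type(am, e$osca)), 0)
  }
})

test_that("integrated segmentation applies the minimum-angle rule", {
  g <- tiny_grid(2)
  # pixel equally passable by two types; angles decide
  mk_em <- function(label, mu, col = "gray")
    structure(list(label = label, mu = mu, spread = c(0, 0), n_pixels = 1,
                   color = col, grid = g), class = "endmember")
  emA <- mk_em("A", c(1, 0.1))
  emB <- mk_em("B", c(1, 0.3))
  vals <- array(0, c(1, 2, 2))
  vals[1, 1, ] <- c(1, 0.12)   # closer to A
  vals[1, 2, ] <- c(0.05, 1)   # far from both
  rc <- reflectance_cube(vals, g)
  lib <- structure(list(entries = list(
    A = list(endmember = emA, osca = 0.2, threshold = 0.2, reference_id = 1L),
    B = list(endmember = emB, osca = 0.2, threshold = 0.2, reference_id = 1L)),
    version = "hsdfm-library-1"), class = "endmember_library")
  seg <- integrate_segmentation(rc, lib)
  expect_equal(seg$labels[1, 1], 1L)   # type A wins by minimum angle
  expect_equal(seg$labels[1, 2], 0L)   # background: passes no threshold
})

test_that("segmented area grows with threshold and the min-rule only removes pixels", {
  tpl <- make_paper_templates()
  sp <- quadrant_scene(shape = c(16, 16), noise_sd = 0.02, seed = 55)
  gdat <- generate_cube(sp, tpl)
  rc <- normalize_cube(gdat$sample, gdat$dark, gdat$reference)
  em <- extract_endmember(rc, gdat$labels == 1, "blood")
  am <- angle_map(rc, em)
  areas <- vapply(c(0.05, 0.1, 0.2, 0.4, pi / 2),
                  function(th) sum(segment_type(am, th)), numeric(1))
  expect_true(all(diff(areas) >= 0))

  # integrated map per-type area bounded by the solo segmentation area
  ems <- lapply(which(apply(gdat$abundance == 1, 3, any)), function(t)
    extract_endmember(rc, gdat$abundance[, , t] == 1,
                      attr(gdat$labels, "labels")[t]))
  lib <- structure(list(entries = lapply(ems, function(e)
    list(endmember = e, osca = 0.3, threshold = 0.3, reference_id = 1L)),
    version = "hsdfm-library-1"), class = "endmember_library")
  names(lib$entries) <- vapply(ems, `[[`, character(1), "label")
  seg <- integrate_segmentation(rc, lib)
  for (i in seq_along(lib$entries)) {
    solo <- sum(segment_type(angle_map(rc, lib$entries[[i]]$endmember), 0.3))
    expect_lte(sum(seg$labels == i), solo)
  }
})

test_that("angle analysis is invariant to positive rescaling of pixels and endmembers", {
  cube <- random_cube(6, 6, seed = 61)
  mu <- runif(35, 0.2, 1)
  am1 <- angle_map(cube, mu)
  scaled <- reflectance_cube(cube$values * 4.2, cube$grid)
  am2 <- angle_map(scaled, 0.3 * mu)
  expect_equal(am1$values, am2$values, tolerance = 1e-12)
})
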