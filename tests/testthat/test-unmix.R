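test_that("stacking cubes preserves pixels and round-trips", {
  c1 <- random_cube(2, 2, seed = 1)
  pm <- stack_cubes(c1)
  expect_equal(dim(pm$X), c(4L, 35L))
  expect_equal(pm$X[1, ], c1$values[1, 1, ])
  c2 <- random_cube(3, 2, seed = 2)
  pm2 <- stack_cubes(list(c1, c2))
  expect_equal(nrow(pm2$X), 4L + 6L)
  # unstack(stack(x)) is the identity per band
  back <- unstack_vector(pm2$X[, 7], pm2)
  expect_equal(back[[1]], c1$values[, , 7])
  expect_equal(back[[2]], c2$values[, , 7])
})

test_that("Lloyd clustering recovers separated clouds and the restart minimum", {
  X <- rbind(matrix(rep(c(1, 0), each = 20), 20, 2),
             matrix(rep(c(0, 1), each = 20), 20, 2))
  cr <- kmeans_endmembers(X, k = 2, restarts = 3, seed = 1)
  expect_equal(cr$objective, 0)
  expect_equal(sort(cr$centroids[, 1]), c(0, 1))
  expect_error(kmeans_endmembers(X, k = 3, restarts = 1, seed = 1),
               "distinct")

  # objective trace is nonincreasing; stored objective matches recomputation
  set.seed(5)
  Y <- matrix(rnorm(600), 200, 3)
  cr2 <- kmeans_endmembers(Y, k = 4, restarts = 5, seed = 2)
  expect_true(all(diff(cr2$objective_trace) <= 1e-9))
  recomputed <- sum((Y - cr2$centroids[cr2$assignment, ])^2)
  expect_equal(cr2$objective, recomputed, tolerance = 1e-9)

  # agrees with stats::kmeans on well-separated data (independent check)
  set.seed(6)
  Z <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
             matrix(rnorm(100, 5, 0.05), 50, 2))
  cr3 <- kmeans_endmembers(Z, k = 2, restarts = 5, seed = 3)
  km <- stats::kmeans(Z, centers = 2, nstart = 5, algorithm = "Lloyd")
  expect_equal(unname(sort(rowMeans(cr3$centroids))),
               unname(sort(rowMeans(km$centers))), tolerance = 1e-9)

  # seeded rerun is identical
  cr4 <- kmeans_endmembers(Y, k = 4, restarts = 5, seed = 2)
  expect_identical(cr2$centroids, cr4$centroids)
  expect_identical(cr2$assignment, cr4$assignment)
})

test_that("centroids recover planted templates on a near-noiseless scene", {
  tpl <- make_paper_templates()
  sp <- scene_spec(c(20, 20), regions = list(
    list(type = "rect", r0 = 1, r1 = 7, c0 = 1, c1 = 20,
         weights = c(blood = 1)),
    list(type = "rect", r0 = 8, r1 = 14, c0 = 1, c1 = 20,
         weights = c(fat = 1))),
    background = c(IDC = 1), noise_sd = 0.02, illumination = "none",
    seed = 71)
  gdat <- generate_cube(sp, tpl)
  rc <- normalize_cube(gdat$sample, gdat$dark, gdat$reference)
  cr <- kmeans_endmembers(stack_cubes(rc), k = 3, restarts = 10, seed = 0)
  planted <- list(tpl$blood$spectrum, tpl$fat$spectrum, tpl$IDC$spectrum)
  for (i in 1:3) {
    angs <- vapply(planted, function(s)
      spectral_angle(cr$centroids[i, ], s), numeric(1))
    expect_lt(min(angs), 0.05)
  }
})

test_that("cluster ranking equals the between-cluster variance decomposition", {
  # two equal clusters symmetric about the mean share 50/50
  X <- rbind(matrix(rep(c(1, 0), each = 10), 10, 2),
             matrix(rep(c(-1, 0), each = 10), 10, 2))
  cr <- kmeans_endmembers(X, k = 2, restarts = 2, seed = 1)
  rk <- rank_clusters(cr, X)
  expect_equal(rk$share, c(0.5, 0.5))

  # k = 1 is degenerate with zero share
  cr1 <- kmeans_endmembers(X, k = 1, restarts = 1, seed = 1)
  rk1 <- rank_clusters(cr1, X)
  expect_equal(rk1$share, 0)
  expect_true(attr(rk1, "degenerate"))

  # random partition matches direct recomputation
  set.seed(8)
  Y <- matrix(runif(90), 30, 3)
  cr3 <- kmeans_endmembers(Y, k = 3, restarts = 4, seed = 9)
  rk3 <- rank_clusters(cr3, Y)
  xbar <- colMeans(Y)
  scores <- vapply(1:3, function(i)
    cr3$sizes[i] * sum((cr3$centroids[i, ] - xbar)^2), numeric(1))
  expect_equal(sort(rk3$share, decreasing = TRUE),
               sort(scores / sum(scores), decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("NNLS abundances honor the closed forms and KKT conditions", {
  U <- cbind(c(1, 0), c(0, 1))
  ab <- nnls_abundances(matrix(c(0.3, 0.7), 1, 2), U)
  expect_equal(as.vector(ab$M), c(0.3, 0.7), tolerance = 1e-12)

  # single endmember: projection (1 + 2)/2
  ab2 <- nnls_abundances(matrix(c(1, 2), 1, 2), cbind(c(1, 1)))
  expect_equal(as.vector(ab2$M), 1.5, tolerance = 1e-12)

  # active constraint: unconstrained optimum (-1, 1) clips to (0, 0.5)
  U3 <- cbind(c(1, 0), c(1, 1))
  ab3 <- suppressWarnings(nnls_abundances(matrix(c(0, 1), 1, 2), U3))
  expect_equal(as.vector(ab3$M), c(0, 0.5), tolerance = 1e-12)

  # random instances against brute-force active-set enumeration
  set.seed(10)
  for (rep in 1:20) {
    U4 <- matrix(runif(12, -0.2, 1), 4, 3)
    y <- runif(4, -0.5, 1)
    got <- suppressWarnings(nnls_abundances(matrix(y, 1, 4), U4))
    expect_equal(as.vector(got$M), oracle_nnls(U4, y), tolerance = 1e-8)
  }
})

test_that("NNLS residuals never exceed the zero-solution residual", {
  pm <- stack_cubes(random_cube(5, 5, seed = 77))
  U <- vapply(make_paper_templates()[1:4], `[[`, numeric(35), "spectrum")
  ab <- nnls_abundances(pm, U)
  expect_true(all(ab$M >= 0))
  expect_true(all(ab$residuals <= sqrt(rowSums(pm$X^2)) + 1e-12))
})

test_that("pure pixels are identified as unit abundance rows", {
  tpl <- make_paper_templates()
  U <- vapply(tpl[c("blood", "fat", "ICT1")], `[[`, numeric(35), "spectrum")
  X <- t(U)  # three pure pixels
  ab <- nnls_abundances(X, U)
  expect_equal(ab$M, diag(3), tolerance = 1e-8)
})

test_that("abundance maps reshape correctly and composites scale channels", {
  tpl <- make_paper_templates()
  g <- tpl$blood$grid
  vals <- array(0, c(1, 2, 35))
  vals[1, 1, ] <- tpl$blood$spectrum
  vals[1, 2, ] <- 0.5 * (tpl$blood$spectrum + tpl$fat$spectrum)
  pm <- stack_cubes(reflectance_cube(vals, g))
  U <- vapply(tpl[c("blood", "fat", "ICT1")], `[[`, numeric(35), "spectrum")
  ab <- nnls_abundances(pm, U)
  maps <- abundance_to_maps(ab, pm)
  # pure pixel: full first channel, nothing in the second
  expect_equal(maps$composite[[1]][1, 1, 1], 1, tolerance = 1e-6)
  expect_equal(maps$composite[[1]][1, 1, 2], 0, tolerance = 1e-6)
  # 50/50 pixel carries both channels at equal abundance
  expect_equal(ab$M[2, 1], ab$M[2, 2], tolerance = 1e-6)
  expect_equal(ab$M[2, 1], 0.5, tolerance = 1e-6)
  # reshape round trip
  expect_equal(maps$maps[[1]][[1]][1, 2], ab$M[2, 1])
})
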