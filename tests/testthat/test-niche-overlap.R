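test_that("make_grid partitions the pooled range into r bins", {
  pts <- matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE)
  g <- make_grid(pts, d = 2, r = 10, margin = 0)
  expect_equal(diff(g$edges[[1]])[1], 0.1, tolerance = 1e-12)
  expect_equal(g$bounds[1, ], c(0, 1))
  # every in-range point falls in exactly one cell
  set.seed(2)
  cells <- grid_cell(matrix(runif(200), ncol = 2), g)
  expect_false(anyNA(cells))
  expect_true(all(cells >= 1 & cells <= 10))
  # the extreme corner (closed last bin) is inside
  expect_equal(as.integer(grid_cell(matrix(c(1, 1), 1), g)), c(10L, 10L))
})

test_that("points on interior bin edges go to the higher bin", {
  g <- make_grid(matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE),
                 d = 2, r = 10, margin = 0)
  # direct interval arithmetic: edge k/10 starts bin k+1 ([low, high))
  for (k in 1:9) {
    edge <- g$edges[[1]][k + 1]
    cell <- grid_cell(matrix(c(edge, 0.05), 1), g)
    expect_equal(unname(cell[1, 1]), k + 1L)
  }
})

test_that("degenerate axes and bad bandwidths are errors", {
  expect_error(make_grid(matrix(c(1, 0, 1, 1), ncol = 2, byrow = TRUE),
                         d = 2, r = 10), "degenerate")
  g <- make_grid(matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE),
                 d = 2, r = 5, margin = 0)
  expect_error(kernel_density(matrix(c(0.5, 0.5), 1), g, c(0, 0.1)),
               "positive")
})

test_that("a single point with vanishing bandwidth is a delta in its cell", {
  g <- make_grid(matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE),
                 d = 2, r = 10, margin = 0)
  pt <- matrix(c(0.33, 0.74), 1)
  dens <- kernel_density(pt, g, c(0.01, 0.01))
  cell <- grid_cell(pt, g)
  expect_equal(dens[cell], 1, tolerance = 1e-8)
})

test_that("kernel density equals direct Gaussian-mixture evaluation", {
  set.seed(5)
  for (i in 1:5) {
    pts <- matrix(runif(2 * sample(2:20, 1)), ncol = 2)
    g <- make_grid(matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE),
                   d = 2, r = 10, margin = 0)
    bw <- runif(2, 0.05, 0.3)
    expect_equal(kernel_density(pts, g, bw),
                 direct_kernel_density(pts, g, bw), tolerance = 1e-10)
  }
  # three-dimensional case against the same naive oracle
  pts3 <- matrix(runif(15), ncol = 3)
  g3 <- make_grid(matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE),
                  d = 3, r = 6, margin = 0)
  bw3 <- c(0.2, 0.15, 0.25)
  expect_equal(kernel_density(pts3, g3, bw3),
               direct_kernel_density(pts3, g3, bw3), tolerance = 1e-10)
})

test_that("kernel densities are normalized for random inputs", {
  set.seed(6)
  for (i in 1:10) {
    pts <- matrix(rnorm(40), ncol = 2)
    g <- make_grid(pts, d = 2, r = 25, margin = 0.1)
    dens <- kernel_density(pts, g, silverman_bandwidths(pts, 2))
    expect_equal(sum(dens), 1, tolerance = 1e-12)
    expect_true(all(dens >= 0))
  }
})

test_that("occupancy correction behaves as o/e where available", {
  set.seed(7)
  o <- array(runif(25), dim = c(5, 5)); o <- o / sum(o)
  # uniform availability: correction is a no-op up to renormalization
  e_unif <- array(1 / 25, dim = c(5, 5))
  expect_equal(occupancy(o, e_unif), o, tolerance = 1e-12)
  # correction off passes o through exactly
  e <- array(runif(25), dim = c(5, 5)); e <- e / sum(e)
  expect_identical(occupancy(o, e, correct = FALSE), o)
  # cell-by-cell ratio against an elementwise oracle
  z <- occupancy(o, e)
  ratio <- o / e
  expect_equal(z, ratio / sum(ratio), tolerance = 1e-12)
  # occurrence mass where availability is scarce is promoted
  o2 <- array(0, dim = c(5, 5)); o2[1, 1] <- 0.6; o2[5, 5] <- 0.4
  e2 <- array(0.9 / 23, dim = c(5, 5)); e2[1, 1] <- 0.01; e2[5, 5] <- 0.09
  z2 <- occupancy(o2, e2)
  expect_gt(z2[1, 1] / z2[5, 5], o2[1, 1] / o2[5, 5])
  # availability below the floor everywhere is an error
  expect_error(occupancy(o, array(0, dim = c(5, 5))), "floor")
})

test_that("Schoener's D satisfies its defining identities", {
  z <- array(runif(16), dim = c(4, 4)); z <- z / sum(z)
  expect_equal(schoener_d(z, z), 1, tolerance = 1e-12)
  a <- array(0, dim = c(4, 4)); a[1:2, 1] <- 0.5
  b <- array(0, dim = c(4, 4)); b[3:4, 4] <- 0.5
  expect_equal(schoener_d(a, b), 0)
  # worked example of the formula
  expect_equal(schoener_d(c(0.5, 0.25, 0.25, 0),
                          c(0.25, 0.25, 0.25, 0.25)), 0.75)
  expect_error(schoener_d(z, array(0.25, dim = c(2, 2))), "same grid")
})

test_that("D matches an independent summation and is symmetric in [0,1]", {
  set.seed(8)
  for (i in 1:25) {
    d <- sample(2:3, 1)
    r <- sample(3:12, 1)
    z1 <- array(runif(r^d), dim = rep(r, d)); z1 <- z1 / sum(z1)
    z2 <- array(runif(r^d), dim = rep(r, d)); z2 <- z2 / sum(z2)
    D <- schoener_d(z1, z2)
    expect_equal(D, direct_schoener(z1, z2), tolerance = 1e-12)
    expect_equal(D, schoener_d(z2, z1), tolerance = 1e-15)
    expect_gte(D, 0); expect_lte(D, 1)
  }
})

test_that("empirical D converges to the generating-density oracle", {
  mu1 <- c(0, 0); mu2 <- c(1.349, 0); s <- c(1, 1)
  err_for_n <- function(n) {
    sapply(1:20, function(seed) {
      a <- simulate_niche_scores(mu1, s, n, seed = 100 + seed)
      b <- simulate_niche_scores(mu2, s, n, seed = 300 + seed)
      g <- make_grid(rbind(as.matrix(a), as.matrix(b)), d = 2, r = 60)
      Dhat <- schoener_d(niche_density(a, grid = g, correct = FALSE)$z,
                         niche_density(b, grid = g, correct = FALSE)$z)
      abs(Dhat - gaussian_overlap_d(mu1, s, mu2, s, g))
    })
  }
  expect_lte(median(err_for_n(5000)), median(err_for_n(500)))
})

test_that("equivalency test is maximal, reproducible and guards inputs", {
  pts <- simulate_niche_scores(c(0, 0), c(1, 1), 20, seed = 1)
  # identical occurrence sets: D = 1 and p = 1
  et <- equivalency_test(pts, pts, correct = FALSE, n_perm = 19, seed = 2)
  expect_equal(et$D, 1, tolerance = 1e-12)
  expect_equal(et$p_value, 1)
  # add-one p-value convention and bounds
  expect_equal(et$p_value, (1 + sum(et$null_D <= et$D)) / (et$n_perm + 1))
  # bit-reproducible for a fixed seed; null varies with the seed
  a <- simulate_niche_scores(c(0, 0), c(1, 1), 15, seed = 3)
  b <- simulate_niche_scores(c(0.5, 0), c(1, 1), 15, seed = 4)
  e1 <- equivalency_test(a, b, correct = FALSE, n_perm = 29, seed = 7)
  e2 <- equivalency_test(a, b, correct = FALSE, n_perm = 29, seed = 7)
  expect_identical(e1$null_D, e2$null_D)
  e3 <- equivalency_test(a, b, correct = FALSE, n_perm = 29, seed = 8)
  expect_false(identical(e1$null_D, e3$null_D))
  # too few occurrences names the offending species
  expect_error(equivalency_test(pts[1:3, ], pts, correct = FALSE,
                                species = c("sparse", "other")), "sparse")
  expect_error(equivalency_test(pts, pts, n_perm = 5, correct = FALSE),
               "19")
})

test_that("overlap_matrix composes pairs on a shared grid", {
  bgm <- matrix(c(-4, -4, 4, 4), ncol = 2, byrow = TRUE)
  g <- make_grid(bgm, d = 2, r = 40, margin = 0)
  a <- simulate_niche_scores(c(-2, -2), c(0.2, 0.2), 200, seed = 1)
  c_ <- simulate_niche_scores(c(2, 2), c(0.2, 0.2), 200, seed = 2)
  dens <- list(
    A = niche_density(a, grid = g, correct = FALSE, species = "A"),
    B = niche_density(a, grid = g, correct = FALSE, species = "B"),
    C = niche_density(c_, grid = g, correct = FALSE, species = "C"))
  tab <- overlap_matrix(dens)
  expect_equal(nrow(tab), 3)
  getD <- function(x, y) tab$D[tab$species_1 == x & tab$species_2 == y]
  # A and B are the same point set; C is far away
  expect_equal(getD("A", "B"), 1, tolerance = 1e-12)
  expect_lt(getD("A", "C"), 1e-6)
  expect_lt(getD("B", "C"), 1e-6)
  # mismatched grids refuse to compose
  g2 <- make_grid(bgm, d = 2, r = 30, margin = 0)
  dens$C <- niche_density(c_, grid = g2, correct = FALSE, species = "C")
  expect_error(overlap_matrix(dens), "share")
  # zero-occurrence entries are dropped with a warning
  fake <- dens$A; fake$n_occurrences <- 0L
  expect_warning(out <- overlap_matrix(list(A = dens$A, B = dens$B,
                                            Z = fake)), "Z")
  expect_equal(nrow(out), 1)
})

test_that("null permutation p-values are approximately uniform", {
  p <- null_calibration_pvalues(200)
  grid_p <- seq(0.01, 1, by = 0.01)
  ks <- max(abs(vapply(grid_p, function(t) mean(p <= t) - t, numeric(1))))
  expect_lt(ks, 0.15)
})
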