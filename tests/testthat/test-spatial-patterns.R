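test_that("ANN reproduces the hand-evaluated unit-square case", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- nearest_neighbor_stat(pts, area = 1)
  expect_equal(r$d_obs, 1)
  expect_equal(r$d_exp, 0.25)
  expect_equal(r$ann, 4)
  expect_equal(r$se, 0.06534)
  expect_equal(r$z, 0.75 / 0.06534, tolerance = 1e-6)
  expect_identical(r$area_source, "user")
})

test_that("ANN handles coincident points, defaults to the MER, and validates", {
  two <- rbind(c(0.3, 0.4), c(0.3, 0.4))
  r <- nearest_neighbor_stat(two, area = 1)
  expect_equal(r$d_obs, 0)
  expect_equal(r$ann, 0)
  # MER default: 3 points spanning a 2 x 5 rectangle
  r2 <- nearest_neighbor_stat(rbind(c(0, 0), c(2, 5), c(1, 3)))
  expect_equal(r2$area, 10)
  expect_identical(r2$area_source, "min_enclosing_rect")
  expect_error(nearest_neighbor_stat(rbind(c(0, 0))), "at least 2")
  # collinear points: degenerate MER demands a user area
  expect_error(nearest_neighbor_stat(rbind(c(0, 0), c(1, 0), c(2, 0))),
               "degenerate")
})

test_that("observed mean NN distance matches the brute-force scan", {
  set.seed(101)
  for (n in c(17, 301)) {
    pts <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    r <- nearest_neighbor_stat(pts, area = 500^2)
    expect_equal(r$d_obs, bf_mean_nn(pts), tolerance = 1e-9)
  }
})

test_that("rook weights on a 2x2 block grid give 2 neighbours each, s0 = 8", {
  blocks <- make_grid_blocks(2, 2, size = 100)
  w <- build_weights(blocks, "rook")
  expect_equal(w$n, 4)
  expect_equal(w$s0, 8)
  deg <- table(w$i)
  expect_true(all(deg == 2))
  # matches the lattice adjacency oracle
  expect_setequal(paste(w$i, w$j), paste(lattice_pairs(2, 2)[, 1],
                                         lattice_pairs(2, 2)[, 2]))
})

test_that("inverse-distance weights follow 1/d and row standardization sums rows to 1", {
  pts <- rbind(c(0, 0), c(10, 0))
  w <- build_weights(pts, "inverse_distance", cutoff = 20)
  expect_equal(sort(w$w), c(0.1, 0.1))
  blocks <- make_grid_blocks(3, 3, size = 50)
  for (scheme in c("rook", "knn", "distance_band")) {
    ws <- build_weights(blocks, scheme, k = 3, band = 60, row_standardize = TRUE)
    rows <- tapply(ws$w, ws$i, sum)
    expect_true(all(abs(rows - 1) < 1e-12))
  }
  # isolated feature under a narrow distance band errors with its id
  far <- rbind(c(0, 0), c(10, 0), c(500, 500))
  expect_error(build_weights(far, "distance_band", band = 50), "3")
})

test_that("Moran's I is -1 on the rook checkerboard and E[I] is exact", {
  blocks <- make_grid_blocks(2, 2, size = 1)
  w <- build_weights(blocks, "rook")
  vals <- c(1, -1, -1, 1)          # alternating by construction order
  m <- morans_i(vals, w)
  expect_equal(m$I, -1)
  expect_equal(m$e_i, -1 / 3)
  m5 <- morans_i(c(5, 1, 2, 8, 3),
                 build_weights(cbind(c(0, 1, 2, 0, 1), c(0, 0, 0, 1, 1)),
                               "knn", k = 2))
  expect_equal(m5$e_i, -0.25)
  expect_error(morans_i(rep(2, 4), w), "zero variance")
})

test_that("Moran's I matches the naive double loop on irregular weights", {
  set.seed(7)
  pts <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  vals <- rnorm(60) + pts[, 1] / 50
  for (scheme in c("inverse_distance", "knn")) {
    w <- build_weights(pts, scheme, k = 4)
    W <- weights_matrix(w)
    expect_equal(morans_i(vals, w)$I, bf_moran(vals, W), tolerance = 1e-12)
  }
})

test_that("Moran's I null distribution matches theory on a 10x10 rook grid", {
  blocks <- make_grid_blocks(10, 10, size = 1)
  w <- build_weights(blocks, "rook")
  set.seed(42)
  sims <- t(vapply(1:500, function(b) {
    m <- morans_i(rnorm(100), w)
    c(m$I, m$v_i)
  }, numeric(2)))
  e_i <- -1 / 99
  se_sim <- sd(sims[, 1]) / sqrt(500)
  expect_lt(abs(mean(sims[, 1]) - e_i), 3 * se_sim)
  # analytic variance agrees with the simulated variance (sampling error of a
  # variance over 500 draws is ~6%, so allow 15%)
  expect_equal(var(sims[, 1]) / mean(sims[, 2]), 1, tolerance = 0.15)
})

test_that("permutation inference flags a checkerboard as dispersed, reproducibly", {
  blocks <- make_grid_blocks(6, 6, size = 1)
  w <- build_weights(blocks, "rook")
  vals <- (-1)^(outer(1:6, 1:6, "+"))          # perfect checkerboard
  m1 <- morans_i(as.vector(vals), w, inference = "permutation",
                 n_perm = 999, seed = 9)
  expect_equal(m1$I, -1)
  expect_lt(m1$p_perm, 0.1)
  m2 <- morans_i(as.vector(vals), w, inference = "permutation",
                 n_perm = 999, seed = 9)
  expect_identical(m1$p_perm, m2$p_perm)
})

test_that("bandwidth rule evaluates the printed formula on constructed geometry", {
  # 100 points, mean centre at the origin: 50 at distance 50, 50 at the
  # distance that makes the standard distance exactly 100
  r2 <- sqrt((100^2 * 100 - 50 * 50^2) / 50)
  ang <- seq(0, 2 * pi, length.out = 26)[1:25]
  ring <- function(r) rbind(cbind(r * cos(ang), r * sin(ang)),
                            cbind(-r * cos(ang), -r * sin(ang)))
  pts <- rbind(ring(50), ring(r2))
  h <- kde_bandwidth(pts)
  expect_equal(h, 0.9 * min(100, sqrt(1 / log(2)) * 50) * 100^(-0.2),
               tolerance = 1e-9)
  expect_equal(h, 21.518, tolerance = 1e-3)
  # min structure: with a huge SD the median branch is taken
  expect_lt(h, 0.9 * 100 * 100^(-0.2))
})

test_that("bandwidth scales as n^-0.2 when points are duplicated", {
  set.seed(3)
  pts <- cbind(rnorm(40, 0, 120), rnorm(40, 0, 120))
  h1 <- kde_bandwidth(pts)
  h2 <- kde_bandwidth(rbind(pts, pts))
  expect_equal(h2 / h1, 2^(-0.2), tolerance = 1e-12)
  expect_error(kde_bandwidth(rbind(c(1, 1), c(1, 1))), "coincident")
})

test_that("the quartic KDE conserves mass, is linear in weight, and has compact support", {
  pt <- matrix(c(100, 100), 1)
  s <- kernel_density(pt, weights = 1, cell_size = 3, bandwidth = 40)
  expect_equal(kde_integral(s), 1, tolerance = 0.01)    # cell = h/13
  s2 <- kernel_density(pt, weights = 2, cell_size = 3, bandwidth = 40)
  expect_equal(s2$values, 2 * s$values)
  # two points 10h apart yield disjoint positive discs
  far <- rbind(c(0, 0), c(400, 0))
  s3 <- kernel_density(far, cell_size = 3, bandwidth = 40)
  xs <- s3$origin[1] + (seq_len(nrow(s3$values)) - 0.5) * s3$cell_size
  mid <- which(xs > 60 & xs < 340)
  expect_true(all(s3$values[mid, ] == 0))
  expect_true(any(s3$values > 0))
  expect_true(all(s3$values >= 0))
  expect_error(kernel_density(pt, weights = -1, cell_size = 1, bandwidth = 10),
               "positive")
})

test_that("KDE surfaces write as readable ASCII grids", {
  s <- kernel_density(matrix(c(10, 10), 1), cell_size = 5, bandwidth = 20)
  f <- withr::local_tempfile(fileext = ".asc")
  write_kde_asc(s, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_match(hdr[5], "^cellsize 5")
  body <- read.table(f, skip = 6)
  expect_equal(nrow(body), ncol(s$values))
})
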