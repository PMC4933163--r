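# random labelled coordinate set
rand_set <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(label = seq_len(n), x = rnorm(n, sd = 3),
                 y = rnorm(n, sd = 3), z = rnorm(n, sd = 3))
}

rotate_set <- function(s, axis, angle, shift = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- cbind(s$x, s$y, s$z) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

test_that("superposed RMSD vanishes under rigid motion", {
  a <- rand_set(10, 1)
  expect_equal(kabsch_rmsd(a, a), 0)
  b <- rotate_set(a, c(0, 1, 0), pi / 2, shift = c(5, -3, 2))
  expect_lt(kabsch_rmsd(a, b, superpose = TRUE), 1e-6)
  expect_gt(kabsch_rmsd(a, b, superpose = FALSE), 1)
  expect_error(kabsch_rmsd(a[1:2, ], b[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches a brute-force rotation-grid oracle", {
  a <- rand_set(4, 2)
  set.seed(3)
  b <- a
  b$x <- b$x + rnorm(4, sd = 0.3)
  b$y <- b$y + rnorm(4, sd = 0.3)
  b$z <- b$z + rnorm(4, sd = 0.3)
  b <- rotate_set(b, c(1, 2, 3), 0.7, shift = c(1, 1, -2))
  got <- kabsch_rmsd(a, b)
  # oracle: exhaustive search over Euler angles on a fine grid around the
  # best coarse cell, centered coordinates
  xa <- scale(cbind(a$x, a$y, a$z), scale = FALSE)
  xb <- scale(cbind(b$x, b$y, b$z), scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  rmsd_at <- function(ang) sqrt(mean(rowSums((xb %*% t(rot(ang)) - xa)^2)))
  search <- function(center, half, n) {
    g <- seq(-half, half, length.out = n)
    best <- c(Inf, 0, 0, 0)
    for (u in g) for (v in g) for (w in g) {
      ang <- center + c(u, v, w)
      r <- rmsd_at(ang)
      if (r < best[1]) best <- c(r, ang)
    }
    best
  }
  best <- search(c(0, 0, 0), pi, 17)
  half <- 0.4
  for (lev in 1:4) {
    best <- search(best[2:4], half, 9)
    half <- half / 4
  }
  expect_equal(got, best[1], tolerance = 1e-3)
  expect_lte(got, best[1] + 1e-9) # Kabsch is the true optimum
})

test_that("Kabsch RMSD agrees with an independent superposition routine", {
  a <- rand_set(12, 5)
  set.seed(6)
  b <- rotate_set(a, c(1, 0, 1), 1.1, shift = c(2, 0, -1))
  b$x <- b$x + rnorm(12, sd = 0.2)
  xa <- as.vector(t(cbind(a$x, a$y, a$z)))
  xb <- as.vector(t(cbind(b$x, b$y, b$z)))
  ref <- bio3d::rmsd(xa, xb, fit = TRUE)
  got <- kabsch_rmsd(a, b)
  expect_equal(got, ref, tolerance = 5e-3)
  expect_lte(got, ref + 1e-6) # SVD solution is the optimum
})

test_that("RMSD is symmetric and superposition never increases it", {
  for (seed in 1:5) {
    a <- rand_set(8, seed)
    b <- rand_set(8, seed + 100)
    expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
    expect_lte(
      kabsch_rmsd(a, b, superpose = TRUE),
      kabsch_rmsd(a, b, superpose = FALSE) + 1e-12
    )
  }
})

test_that("RMSF isolates a single oscillating atom and ignores tumbling", {
  base <- rand_set(30, 7)
  # rigid anchor, atom 1 oscillates +/- d along x
  d <- 0.8
  frames <- lapply(1:20, function(k) {
    f <- base
    f$x[1] <- f$x[1] + d * sign(k %% 2 - 0.5)
    f$frame <- k
    f
  })
  traj <- dplyr::bind_rows(frames)
  out <- rmsf(traj)
  expect_equal(out$rmsf[out$label == 1], d, tolerance = 0.05)
  expect_lt(max(out$rmsf[out$label != 1]), 0.1)

  # whole-body tumbling: all fluctuations vanish after superposition
  tumb <- dplyr::bind_rows(lapply(1:10, function(k) {
    f <- rotate_set(base, c(1, 1, 0), 0.3 * k, shift = c(k, 0, -k))
    f$frame <- k
    f
  }))
  out2 <- rmsf(tumb)
  expect_lt(max(out2$rmsf), 1e-6)

  static <- dplyr::bind_rows(lapply(1:3, function(k) {
    f <- base
    f$frame <- k
    f
  }))
  expect_equal(max(rmsf(static)$rmsf), 0, tolerance = 1e-12)
  expect_error(rmsf(base[integer(0), ]), "frame")
})

test_that("radius of gyration matches closed-form geometries", {
  two <- tibble::tibble(label = 1:2, x = c(0, 2), y = 0, z = 0)
  expect_equal(radius_of_gyration(two), 1.0)
  tri <- tibble::tibble(
    label = 1:3,
    x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2), z = 0
  )
  expect_equal(radius_of_gyration(tri), 1 / sqrt(3), tolerance = 1e-12)
  one <- tibble::tibble(label = 1, x = 4, y = 5, z = 6)
  expect_equal(radius_of_gyration(one), 0)
  # masses shift the center: heavy atom dominates
  w <- tibble::tibble(label = 1:2, x = c(0, 2), y = 0, z = 0, mass = c(1e9, 1))
  expect_lt(abs(radius_of_gyration(w) - 0), 1e-3)
})

test_that("grid molecular volume matches sphere formulas and unions", {
  a <- one_atom(r = 2)
  expect_equal(molecular_volume(a), 4 / 3 * pi * 8, tolerance = 0.02)
  apart <- dplyr::bind_rows(a, one_atom(x = 10, r = 2, serial = 2L, resseq = 2L))
  expect_equal(molecular_volume(apart), 2 * 4 / 3 * pi * 8, tolerance = 0.02)
  coincident <- dplyr::bind_rows(a, one_atom(r = 2, serial = 2L, resseq = 2L))
  expect_equal(molecular_volume(coincident), 4 / 3 * pi * 8, tolerance = 0.02)
  expect_error(molecular_volume(a, grid = 0), "positive")
})

test_that("volume is monotone in radii and converges under grid halving", {
  st <- dplyr::bind_rows(
    one_atom(r = 1.7),
    one_atom(x = 2.5, r = 1.5, serial = 2L, resseq = 2L),
    one_atom(y = 2.0, r = 1.2, serial = 3L, resseq = 3L)
  )
  v1 <- molecular_volume(st, grid = 0.25)
  inflated <- st
  inflated$vdw_radius <- inflated$vdw_radius * 1.2
  expect_gt(molecular_volume(inflated, grid = 0.25), v1)
  v2 <- molecular_volume(st, grid = 0.125)
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("RDF first peak finds lattice and chain spacings", {
  chain <- tibble::tibble(x = seq(0, 100, by = 5), y = 0)
  expect_equal(rdf_first_peak(chain, bin_width = 0.5, max_radius = 12), 5,
               tolerance = 0.5 / 5)
  lat3 <- tidyr::expand_grid(x = seq(0, 40, 8), y = seq(0, 40, 8), z = seq(0, 40, 8))
  expect_equal(rdf_first_peak(lat3, bin_width = 0.5, max_radius = 15, dimension = 3),
               8, tolerance = 0.5 / 8)
  expect_error(rdf_first_peak(chain[1:2, ], bin_width = 0.5, max_radius = 2),
               "pair|peak")
})
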