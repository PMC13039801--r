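test_that("connectivity follows the covalent-radius cutoff", {
  # H-H at 0.74 A: cutoff 1.2 * (0.31 + 0.31) = 0.744 -> bonded
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  expect_equal(nrow(infer_connectivity(g)), 1L)
  # water-like: two O-H bonds at 0.96 A, H atoms not bonded to each other
  w <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  b <- infer_connectivity(w)
  expect_equal(nrow(b), 2L)
  expect_true(all(b[, 1] == 1L))
  # far-apart atoms are isolated
  far <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_error(infer_connectivity(far), "isolated")
})

test_that("ALF choice is deterministic, mass-prioritized and rigid-motion invariant", {
  toy <- make_toy("chain5") # C C C C H
  alf <- build_alf(toy$geometry)
  # middle atom 2 has equal-mass C neighbours 1 and 3: tie -> lowest index
  expect_equal(alf$x_axis[2], 1L)
  # atom 4 bonds C3 and H5: carbon is heavier -> x axis, H -> plane
  expect_equal(alf$x_axis[4], 3L)
  expect_equal(alf$xy_plane[4], 5L)
  # terminal atom 1 has one neighbour (2); plane atom from 2's neighbours
  expect_equal(alf$x_axis[1], 2L)
  expect_equal(alf$xy_plane[1], 3L)
  # rigid motion leaves the definition unchanged
  set.seed(11)
  R <- random_rotation()
  g2 <- toy$geometry
  g2$coords <- g2$coords %*% R + matrix(rep(c(3, -2, 1), each = 5), 5, 3)
  expect_identical(build_alf(g2), alf)
})

test_that("feature layout matches its contract", {
  toy <- make_toy("chain4")
  expect_equal(n_features(4L), 6L)
  expect_equal(periodic_mask(6L), c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(which(periodic_mask(9L)), c(6L, 9L))
  # 3-atom molecule: exactly 3 features, none periodic
  w <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  f <- featurize(w, build_alf(w), 1L)
  expect_length(f$values, 3L)
  expect_false(any(f$periodic_mask))
  # diatomic: rejected without the degenerate mode, 1 feature with it
  di <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  expect_error(featurize(di, atom = 1L), "diatomic")
  expect_equal(featurize(di, atom = 1L, diatomic = TRUE)$values, 0.74)
})

test_that("spherical coordinates of an atom on the local +x axis are (r, pi/2, 0)", {
  # atom 1's frame: x axis toward atom 2, plane atom 3; atom 4 on the +x axis
  g <- geometry(c("C", "C", "C", "C"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.7, 1.2, 0), c(2, 0, 0)))
  alf <- list(x_axis = c(2L, 1L, 1L, 1L), xy_plane = c(3L, 3L, 2L, 2L))
  f <- featurize(g, alf, 1L)
  expect_equal(f$values[4:6], c(2, pi / 2, 0), tolerance = 1e-12)
})

test_that("features are invariant under random rigid motions", {
  toy <- make_toy("chain5")
  alf <- build_alf(toy$geometry)
  f0 <- lapply(1:5, function(a) featurize(toy$geometry, alf, a)$values)
  set.seed(21)
  worst <- 0
  for (k in 1:100) {
    R <- random_rotation()
    g2 <- toy$geometry
    g2$coords <- g2$coords %*% R +
      matrix(rep(stats::rnorm(3, sd = 5), each = 5), 5, 3)
    for (a in 1:5) {
      dev <- max(abs(featurize(g2, alf, a)$values - f0[[a]]))
      worst <- max(worst, dev)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate collinear frames are rejected", {
  g <- geometry(c("C", "C", "C"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)))
  alf <- list(x_axis = c(2L, 1L, 2L), xy_plane = c(3L, 3L, 1L))
  expect_error(featurize(g, alf, 1L), "degenerate")
})

test_that("the B-matrix matches central finite differences and is exact for d1", {
  set.seed(31)
  toy <- make_toy("chain5")
  g <- toy$geometry
  g$coords <- g$coords + matrix(rnorm(15, sd = 0.05), 5, 3)
  alf <- build_alf(toy$geometry)
  h <- 1e-6
  for (a in c(1L, 3L)) {
    B <- feature_jacobian(g, alf, a)
    fd <- matrix(0, nrow(B), ncol(B))
    for (i in 1:5) for (k in 1:3) {
      gp <- g; gp$coords[i, k] <- gp$coords[i, k] + h
      gm <- g; gm$coords[i, k] <- gm$coords[i, k] - h
      fd[, 3 * (i - 1) + k] <-
        (featurize(gp, alf, a)$values - featurize(gm, alf, a)$values) / (2 * h)
    }
    expect_lt(max(abs(B - fd)), 1e-7)
    # d1 row: unit bond vector on the x-axis atom, opposite sign on the centre
    u <- g$coords[alf$x_axis[a], ] - g$coords[a, ]
    u <- u / sqrt(sum(u^2))
    expect_equal(B[1, 3 * (alf$x_axis[a] - 1) + 1:3], u, tolerance = 1e-12)
    expect_equal(B[1, 3 * (a - 1) + 1:3], -u, tolerance = 1e-12)
    # translation invariance: every row dotted with a uniform shift is zero
    shift <- rep(1, 5)
    for (k in 1:3) {
      cols <- 3 * (0:4) + k
      expect_lt(max(abs(B[, cols] %*% shift)), 1e-10)
    }
  }
})
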