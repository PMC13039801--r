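test_that("toy topologies match their declared term counts", {
  c4 <- make_toy("chain4")
  expect_length(c4$elements, 4L)
  expect_equal(nrow(c4$bonds), 3L)
  expect_equal(nrow(c4$angles), 2L)
  expect_equal(nrow(c4$torsions), 1L)
  expect_equal(n_features(4L), 6L)
  expect_equal(sum(periodic_mask(6L)), 1L)
  gl <- make_toy("glycine_like")
  expect_gte(nrow(gl$torsions), 2L)
  expect_error(make_toy("nope"))
  # connectivity inferred from the built coordinates matches the term table
  expect_equal(nrow(infer_connectivity(gl$geometry)), nrow(gl$bonds))
})

test_that("the torsion scan of chain4 is periodic with minima at the staggered angles", {
  toy <- make_toy("chain4")
  # rotate atom 4 about the 2-3 bond to scan the dihedral
  scan <- function(phi_deg) {
    g <- toy$geometry
    axis <- g$coords[3, ] - g$coords[2, ]
    axis <- axis / sqrt(sum(axis^2))
    v <- g$coords[4, ] - g$coords[3, ]
    th <- (phi_deg - 180) * pi / 180 # reference geometry is anti (180 deg)
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    g$coords[4, ] <- g$coords[3, ] + drop(R %*% v)
    toy_energy(toy, g$coords)
  }
  phis <- seq(-180, 180, by = 5)
  e <- vapply(phis, scan, 0)
  # periodicity in the dihedral: endpoints coincide
  expect_equal(e[1], e[length(e)], tolerance = 1e-10)
  # V (1 + cos 3 phi) has minima at +-60 and 180 and maxima at 0 and +-120
  expect_equal(e[phis == 60], min(e), tolerance = 1e-10)
  expect_equal(e[phis == -60], min(e), tolerance = 1e-10)
  expect_equal(e[phis == 180], min(e), tolerance = 1e-10)
  expect_equal(e[phis == 0], max(e), tolerance = 1e-10)
})

test_that("the atomic partition reconstructs the total energy exactly", {
  set.seed(151)
  for (kind in c("diatomic", "chain4", "chain5", "glycine_like")) {
    toy <- make_toy(kind)
    n <- length(toy$elements)
    for (i in 1:20) {
      x <- toy$geometry$coords + matrix(rnorm(3 * n, sd = 0.1), n, 3)
      expect_lt(abs(sum(toy_atomic_energies(toy, x)) - toy_energy(toy, x)),
                1e-12)
    }
  }
})

test_that("analytic toy gradients match finite differences", {
  set.seed(161)
  for (kind in c("chain4", "chain5", "glycine_like")) {
    toy <- make_toy(kind)
    n <- length(toy$elements)
    x <- toy$geometry$coords + matrix(rnorm(3 * n, sd = 0.08), n, 3)
    g <- toy_gradient(toy, x)
    # drop the constant element baselines for the FD oracle: they cancel in
    # the difference but cost ~1e-8 of cancellation roundoff at |E| ~ 300 Ha
    toy0 <- toy
    toy0$baselines <- 0 * toy0$baselines
    h <- 1e-6
    fd <- matrix(0, n, 3)
    for (i in seq_len(n)) for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd[i, k] <- (toy_energy(toy0, xp) - toy_energy(toy0, xm)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)), 1e-8)
  }
})

test_that("labels carry the injected noise structure and conserve after correction", {
  toy <- make_toy("chain5")
  geoms <- sample_configs(toy, n = 40, t_eff = 600, seed = 171)
  # zero noise: recovery error vanishes and the correction is the identity
  cfg0 <- label_configs(toy, geoms[1:5], noise_sd = 0)
  for (c in cfg0) {
    out <- correct_energies(c)
    expect_equal(out$recovery_error, 0)
    expect_equal(out$corrected_atomic_energies, c$raw_atomic_energies)
  }
  # noisy labels: sum of corrected energies returns the exact total
  cfgs <- label_configs(toy, geoms, noise_sd = 1e-4, seed = 181)
  for (c in cfgs[1:10]) {
    out <- correct_energies(c)
    expect_lt(abs(sum(out$corrected_atomic_energies) - c$ref_molecular_energy),
              1e-12)
    expect_equal(out$recovery_error,
                 c$ref_molecular_energy - sum(c$raw_atomic_energies))
  }
  # reproducible under a fixed seed
  again <- label_configs(toy, geoms, noise_sd = 1e-4, seed = 181)
  expect_identical(cfgs[[3]]$raw_atomic_energies,
                   again[[3]]$raw_atomic_energies)
  # heavy atoms get five times the hydrogen noise scale
  resid <- vapply(cfgs, function(c) {
    c$raw_atomic_energies - toy_atomic_energies(toy, c$geometry$coords)
  }, numeric(5))
  sd_heavy <- stats::sd(resid[1:4, ])
  sd_h <- stats::sd(resid[5, ])
  expect_equal(sd_heavy / sd_h, 5, tolerance = 0.5)
})

test_that("sampling covers torsions at high temperature and stays tight at low", {
  toy <- make_toy("chain5")
  expect_length(sample_configs(toy, n = 1, t_eff = 300, seed = 1), 1L)
  hot <- sample_configs(toy, n = 250, t_eff = 1500, seed = 191)
  phis <- vapply(hot, function(g) dihedral_angle(g, 1:4), 0)
  bins <- table(cut(phis, seq(-180, 180, by = 30)))
  expect_gte(sum(bins > 0), 8L)
  cold <- sample_configs(toy, n = 100, t_eff = 20, seed = 201)
  for (b in seq_len(nrow(toy$bonds))) {
    r <- vapply(cold, function(g)
      sqrt(sum((g$coords[toy$bonds[b, 1], ] - g$coords[toy$bonds[b, 2], ])^2)),
      0)
    # 95th percentile: individual draws carry Maxwell-Boltzmann tails
    expect_lt(stats::quantile(abs(r - toy$r0[b]) / toy$r0[b], 0.95), 0.02)
  }
})
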