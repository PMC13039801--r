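test_that("Maxwell-Boltzmann velocities hit the target temperature with zero drift", {
  g <- make_toy("chain5")$geometry
  mass <- element_data(g$elements)$mass
  set.seed(131)
  ke <- replicate(400, {
    v <- init_velocities(g, 500)
    0.5 * sum(mass * rowSums(v^2))
  })
  # 3N - 3 momentum-free degrees of freedom at kT/2 each
  expect_equal(mean(ke), 0.5 * 12 * alfgpr_units$kb_mdu * 500, tolerance = 0.05)
  v <- init_velocities(g, 500, seed = 7)
  expect_lt(max(abs(colSums(v * mass))), 1e-12)
  expect_identical(init_velocities(g, 500, seed = 7), v)
})

test_that("a zero-step run reports zero stability time and no crash", {
  m <- chain5_model("MF5")
  res <- run_md(m, chain5_data()$toy$geometry, 300, steps = 0)
  expect_identical(res$stability$crash_step, NA_integer_)
  expect_identical(res$stability$stability_time_ps, 0)
})

test_that("crash detection is exact against a per-step scan of bond ratios", {
  d <- chain5_data()
  m1 <- chain5_model("MF1")
  res <- run_md(m1, d$toy$geometry, 1600, steps = 60000, dt = 0.25,
                reference = d$toy$geometry, seed = 3)
  st <- res$stability
  expect_identical(st$crash_kind, "bond")
  # max_ratio holds every step: the crash step is the first above 1.65 and
  # no earlier step violates the criterion
  expect_gt(st$max_ratio[st$crash_step + 1L], 1.65)
  expect_true(all(st$max_ratio[seq_len(st$crash_step)] <= 1.65))
  expect_equal(st$stability_time_ps, st$crash_step * 0.25 / 1000)
})

test_that("NVE conserves energy and Nose-Hoover holds the temperature", {
  d <- chain5_data()
  m <- chain5_model("MF5")
  res <- run_md(m, d$toy$geometry, 300, steps = 8000, dt = 0.25,
                thermostat = "none", seed = 3, sample_every = 20)
  etot <- res$trajectory$scalars$epot + res$trajectory$scalars$ekin
  expect_lt(diff(range(etot)), 1e-4)
  res2 <- run_md(m, d$toy$geometry, 400, steps = 40000, dt = 0.25,
                 thermostat = "nose_hoover", seed = 4, sample_every = 50)
  temps <- res2$trajectory$scalars$temp
  expect_equal(mean(temps[-(1:100)]), 400, tolerance = 0.1)
  # langevin thermostats to the same target
  res3 <- run_md(m, d$toy$geometry, 400, steps = 40000, dt = 0.25,
                 thermostat = "langevin", seed = 5, sample_every = 50)
  expect_equal(mean(res3$trajectory$scalars$temp[-(1:100)]), 400,
               tolerance = 0.1)
})

test_that("robustness averages per-run stability times", {
  d <- chain5_data()
  m1 <- chain5_model("MF1")
  rb <- robustness(m1, rep(list(d$toy$geometry), 3), 1600, cap_ps = 3,
                   seeds = 1:3, reference = d$toy$geometry)
  expect_equal(rb$score_ps, mean(rb$stabilities_ps))
  expect_equal(rb$n_sim, 3L)
  expect_true(all(rb$stabilities_ps <= 3))
  # a single stable run returns its own stability time (the cap)
  m5 <- chain5_model("MF5")
  rb1 <- robustness(m5, list(d$toy$geometry), 300, cap_ps = 0.25, seeds = 9,
                    reference = d$toy$geometry)
  expect_equal(rb1$score_ps, 0.25)
})

test_that("BFGS terminates below fmax and is a no-op on converged starts", {
  d <- chain5_data()
  m <- chain5_model("MF5")
  opt <- bfgs_optimize(m, perturb_geometry(d$toy$geometry, 0.2, seed = 17))
  expect_true(opt$converged)
  expect_lte(tail(opt$trace$max_force, 1), 0.00045)
  expect_lt(rmsd(opt$geometry, d$toy$geometry), 0.05)
  # restarting from the optimum does nothing
  opt2 <- bfgs_optimize(m, opt$geometry)
  expect_identical(opt2$steps, 0L)
  expect_identical(opt2$geometry$coords, opt$geometry$coords)
})

test_that("perturbations are bounded, seedable and vanish at zero amplitude", {
  g <- make_toy("chain4")$geometry
  expect_identical(perturb_geometry(g, 0, seed = 1)$coords, g$coords)
  p1 <- perturb_geometry(g, 0.25, seed = 2)
  expect_true(all(abs(p1$coords - g$coords) <= 0.25))
  expect_identical(perturb_geometry(g, 0.25, seed = 2)$coords, p1$coords)
})

test_that("superposition RMSD matches independent oracles", {
  set.seed(141)
  g1 <- make_toy("chain5")$geometry
  expect_equal(rmsd(g1, g1), 0)
  R <- random_rotation()
  g2 <- g1
  g2$coords <- g1$coords %*% R + matrix(rep(c(1, -4, 2), each = 5), 5, 3)
  expect_lt(rmsd(g1, g2), 1e-10)
  # displaced copy against a dense rotation-grid oracle
  g3 <- g1
  g3$coords[2, ] <- g3$coords[2, ] + c(0.3, -0.1, 0.2)
  grid <- seq(0, 2 * pi, length.out = 60)
  P <- scale(g1$coords, scale = FALSE)
  Q <- scale(g3$coords, scale = FALSE)
  best <- Inf
  for (a in grid) for (b in seq(0, pi, length.out = 30)) for (c in grid) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    v <- sqrt(mean(rowSums((Q - P %*% t(Rz2 %*% Ry %*% Rz1))^2)))
    if (v < best) best <- v
  }
  expect_equal(rmsd(g1, g3), best, tolerance = 0.05)
  expect_lte(rmsd(g1, g3), best + 1e-12) # optimal beats any grid rotation
  # cross-check against bio3d's fitted RMSD
  skip_if_not_installed("bio3d")
  xyz1 <- matrix(t(g1$coords), nrow = 1)
  xyz3 <- matrix(t(g3$coords), nrow = 1)
  # bio3d rounds its RMSD to three decimals
  expect_equal(rmsd(g1, g3),
               as.numeric(bio3d::rmsd(xyz1, xyz3, fit = TRUE)),
               tolerance = 0.01)
})

test_that("dihedral angles are signed and hit the cis/trans references", {
  cis <- geometry(rep("C", 4),
                  rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0)))
  trans <- geometry(rep("C", 4),
                    rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0)))
  expect_equal(dihedral_angle(cis, 1:4), 0, tolerance = 1e-10)
  expect_equal(abs(dihedral_angle(trans, 1:4)), 180, tolerance = 1e-10)
  sm <- structural_metrics(cis, trans, dihedrals = list(1:4))
  expect_equal(sm$dihedrals$a_deg, 0, tolerance = 1e-10)
  expect_true(sm$rmsd > 0)
})
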