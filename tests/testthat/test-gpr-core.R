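test_that("mean functions match direct arithmetic and collapse correctly", {
  y <- c(-1, 0, 1)
  expect_equal(compute_mean("MF1", y)$value, 0)
  expect_equal(compute_mean("MF2", y)$value, sqrt(2 / 3)) # population sd
  expect_equal(compute_mean("MF3", y)$value, 1)
  expect_equal(compute_mean("MF4", y)$value, 3)
  expect_equal(compute_mean("MF5", y)$value, 11)
  expect_equal(compute_mean("MIN", y)$value, -1)
  for (k in c("MF1", "MF2", "MF3", "MF4", "MF5", "MIN")) {
    expect_equal(compute_mean(k, c(2.5, 2.5, 2.5))$value, 2.5)
    expect_equal(compute_mean(k, 2.5)$value, 2.5)
  }
  expect_error(compute_mean("MF1", numeric(0)), "nonempty")
})

test_that("mean ordering MIN <= MF1 <= MF3 <= MF4 <= MF5 holds on random sets", {
  set.seed(51)
  for (i in 1:50) {
    y <- rnorm(sample(2:30, 1), sd = runif(1, 0.01, 2))
    v <- vapply(c("MIN", "MF1", "MF2", "MF3", "MF4", "MF5"),
                function(k) compute_mean(k, y)$value, 0)
    expect_true(v["MIN"] <= v["MF1"])
    expect_true(v["MF1"] <= v["MF2"])
    expect_true(v["MF3"] <= v["MF4"])
    expect_true(v["MF4"] <= v["MF5"])
    # sigma <= max - mu always holds for finite samples
    expect_true(v["MF2"] <= v["MF3"] + 1e-12)
  }
})

test_that("composite kernel matches hand arithmetic, symmetry and periodicity", {
  r <- c(1.2, 1.4, 1.9, 2.2, 1.1, 0.3)
  th <- rep(0.5, 6)
  expect_equal(gp_kernel(r, r, th, sigma_f = 3), 3)
  # vectors differing only in the periodic feature d = 6 by pi
  r2 <- r; r2[6] <- r[6] + pi
  expect_equal(gp_kernel(r, r2, th, sigma_f = 1), exp(-0.5), tolerance = 1e-12)
  # periodic feature shifted by a full turn is identical
  r3 <- r; r3[6] <- r[6] + 2 * pi
  expect_equal(gp_kernel(r, r3, th, sigma_f = 2), 2, tolerance = 1e-12)
  expect_error(gp_kernel(r, r[-1], th), "length")
  set.seed(61)
  for (i in 1:20) {
    a <- rnorm(9); b <- rnorm(9); tht <- runif(9)
    expect_equal(gp_kernel(a, b, tht), gp_kernel(b, a, tht), tolerance = 1e-15)
  }
  # kernel_matrix agrees with the scalar kernel
  X <- matrix(rnorm(27), 3, 9); Y <- matrix(rnorm(18), 2, 9)
  tht <- runif(9)
  K <- kernel_matrix(X, Y, tht, sigma_f = 1.7)
  for (i in 1:3) for (j in 1:2)
    expect_equal(K[i, j], gp_kernel(X[i, ], Y[j, ], tht, 1.7), tolerance = 1e-14)
})

test_that("weight fitting reproduces a dense-solver oracle and the 2x2 closed form", {
  # hand-built 1-feature, 2-point case solved symbolically:
  # K = sf * [[1, e], [e, 1]], e = exp(-th (x1-x2)^2)
  x <- c(0, 1); y <- c(0.3, -0.2); th <- 0.8; sf <- 2; sn <- 1e-6
  m <- fit_atomic_model(matrix(x), y, th, sigma_n2 = sn, mean_kind = "MF1",
                        sigma_f = sf, periodic = FALSE)
  e <- exp(-th)
  mu <- mean(y)
  a <- sf + sn; b <- sf * e
  det2 <- a^2 - b^2
  w_exact <- c(a * (y[1] - mu) - b * (y[2] - mu),
               -b * (y[1] - mu) + a * (y[2] - mu)) / det2
  expect_equal(m$weights, w_exact, tolerance = 1e-12)
  # y identically equal to the mean -> zero weights
  m0 <- fit_atomic_model(matrix(x), c(0.4, 0.4), th, mean_kind = "MF1",
                         periodic = FALSE)
  expect_equal(m0$weights, c(0, 0))
  # dense solve() oracle on a bigger random case
  set.seed(71)
  X <- matrix(runif(60, 0, 3), 20, 3)
  yy <- rowSums(sin(X))
  tht <- c(0.4, 0.9, 0.2)
  mm <- fit_atomic_model(X, yy, tht, sigma_n2 = 1e-8, mean_kind = "MF2",
                         periodic = rep(FALSE, 3))
  K <- kernel_matrix(X, X, tht, mm$sigma_f, rep(FALSE, 3))
  w_oracle <- solve(K + diag(1e-8, 20), yy - mm$mean$value)
  expect_equal(mm$weights, w_oracle, tolerance = 1e-9)
  # residual of the linear system is tiny
  expect_lt(max(abs((K + diag(1e-8, 20)) %*% mm$weights - (yy - mm$mean$value))),
            1e-10)
})

test_that("the posterior mean interpolates training data at vanishing noise", {
  d <- chain5_data()
  sub <- d$train[1:50]
  m <- train_model(sub, mean_kind = "MF1", sigma_n2 = 1e-10)
  for (a in c(1L, 5L)) {
    am <- m$atoms[[a]]
    pred <- vapply(seq_len(nrow(am$X)),
                   function(i) predict_atomic(am, am$X[i, ]), 0)
    expect_lt(max(abs(pred - am$y)), 1e-6)
  }
})

test_that("predictions revert to the prior mean far from training data", {
  d <- chain5_data()
  m <- chain5_model("MF5")
  am <- m$atoms[[2]]
  far <- am$X[1, ]
  far[!am$periodic] <- far[!am$periodic] + 10
  expect_lt(abs(predict_atomic(am, far) - am$mean$value), 1e-8)
  # zero weights -> prior mean for any input
  am0 <- am
  am0$weights <- rep(0, length(am0$weights))
  expect_identical(predict_atomic(am0, am$X[3, ]), am0$mean$value)
})

test_that("molecular prediction is the sum of atomic predictions plus nothing", {
  d <- chain5_data()
  m <- chain5_model("MF5")
  g <- d$heldout[[5]]$geometry
  atomic <- vapply(1:5, function(a)
    predict_atomic(m$atoms[[a]], featurize(g, m$alf, a)), 0)
  expect_equal(predict_molecular(m, g), sum(atomic), tolerance = 1e-12)
  expect_error(predict_molecular(m, geometry(c("O", "H"),
                                             rbind(c(0, 0, 0), c(1, 0, 0)))),
               "element")
  # all-zero weights -> M
  m0 <- m
  for (a in 1:5) m0$atoms[[a]]$weights <- rep(0, nrow(m0$atoms[[a]]$X))
  expect_equal(predict_molecular(m0, g), m0$M, tolerance = 1e-12)
})

test_that("trained chain5 models reach sub-kcal/mol molecular accuracy", {
  d <- chain5_data()
  m <- chain5_model("MF5")
  test <- d$heldout[1:150]
  pred <- vapply(test, function(c) predict_molecular(m, c$geometry), 0)
  truth <- vapply(test, function(c) c$ref_molecular_energy, 0)
  mae <- mean(abs(pred - truth)) * alfgpr_units$kcalmol_per_hartree
  expect_lt(mae, 1)
})
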