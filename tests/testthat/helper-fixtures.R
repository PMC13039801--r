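# Shared fixtures, built lazily once per test session. The chain5 pipeline
# (Langevin pool -> DAS selection -> noisy labels -> per-atom GP fit) is the
# workhorse system for the force, MD and deployment tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

chain5_data <- function() fixture("chain5_data", function() {
  toy <- make_toy("chain5")
  pool <- sample_configs(toy, n = 600, t_eff = 900, seed = 42)
  sel <- das_select(pool, toy$geometry, 300)
  cfgs <- label_configs(toy, pool, noise_sd = 1e-4, seed = 7)
  held <- setdiff(seq_along(pool), sel$indices)
  list(toy = toy, pool = pool, cfgs = cfgs,
       train = cfgs[sel$indices], heldout = cfgs[held])
})

# noise-matched regularization: heavy-atom label noise is 5e-4 Ha
chain5_model <- function(mean_kind = "MF5") {
  fixture(paste0("chain5_", mean_kind), function() {
    train_model(chain5_data()$train, mean_kind = mean_kind, sigma_n2 = 2.5e-7)
  })
}

# diatomic degenerate-mode fixture: 50 bond lengths spanning 0.8-1.2 A
diatomic_data <- function() fixture("diatomic_data", function() {
  toy <- make_toy("diatomic")
  rs <- seq(0.8, 1.2, length.out = 50)
  geoms <- lapply(rs, function(r)
    geometry(toy$elements, rbind(c(0, 0, 0), c(r, 0, 0))))
  list(toy = toy, rs = rs, geoms = geoms,
       cfgs = label_configs(toy, geoms, noise_sd = 1e-4, seed = 5))
})

diatomic_model <- function(mean_kind = "MF5", sigma_n2 = 2.5e-7) {
  fixture(paste0("diatomic_", mean_kind, "_", sigma_n2), function() {
    train_model(diatomic_data()$cfgs, mean_kind = mean_kind,
                sigma_n2 = sigma_n2)
  })
}

# radial slope dE/dr of a diatomic model by central differences
diatomic_slope <- function(model, r, h = 1e-5) {
  el <- c("O", "H")
  ep <- predict_molecular(model, geometry(el, rbind(c(0, 0, 0), c(r + h, 0, 0))))
  em <- predict_molecular(model, geometry(el, rbind(c(0, 0, 0), c(r - h, 0, 0))))
  (ep - em) / (2 * h)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# independent greedy farthest-point oracle over a precomputed distance matrix
das_greedy_oracle <- function(dmat, seed_dist, k) {
  n <- nrow(dmat)
  mind <- seed_dist
  sel <- integer(k)
  for (s in seq_len(k)) {
    cand <- if (s == 1L) which.min(mind) else which.max(mind)
    sel[s] <- cand
    mind[cand] <- -Inf
    upd <- dmat[, cand]
    upd[is.infinite(mind)] <- -Inf
    mind <- pmin(mind, upd)
  }
  sel
}
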