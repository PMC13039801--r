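# One grey-wolf position update: average over the three leaders l of
# leader_d - A_{l,d} * |C_{l,d} leader_d - self_d|, with A = 2 a r1 - a and
# C = 2 a r2. lead_pos is 3 x d; r1, r2 are 3 x d matrices of U(0,1) draws.
gwo_move <- function(lead_pos, self, a, r1, r2) {
  A <- 2 * a * r1 - a
  C <- 2 * a * r2
  D <- abs(C * lead_pos - matrix(self, 3, length(self), byrow = TRUE))
  colMeans(lead_pos - A * D)
}

# Lucky-agent promotion target: (1 + eps) times the leader centroid.
gwo_promote_target <- function(lead_pos, eps) {
  (1 + eps) * colMeans(lead_pos)
}

#' Grey-wolf optimizer with lucky-agent promotion and elitism
#'
#' Minimizes `fn` over a box. A pack of agents moves under the guidance of
#' its three best members (alpha, beta, delta): each non-leader position is
#' updated per dimension as the average of `leader - A * |C * leader - self|`
#' over the three leaders, with A = 2 a r1 - a, C = 2 a r2, r1 and r2 fresh
#' uniform draws per leader and dimension, and the control scalar a decaying
#' linearly from 2 at the first iteration to 0 at the last. Every
#' `lucky_period` iterations `lucky_count` random non-leaders are promoted to
#' (1 + eps) times the leader centroid with eps ~ U(0, 0.25). An elitism
#' check reverts any move that worsens an agent's loss, so the best-so-far
#' loss is non-increasing. Positions are clamped to the bounds after every
#' move.
#'
#' @param fn loss function of a position vector; non-finite values are
#'   treated as +Inf.
#' @param lower,upper numeric bound vectors (equal length = dimension).
#' @param agents pack size (default 50).
#' @param iterations number of iterations (default 200).
#' @param lucky_period,lucky_count promotion schedule (defaults 5 and 5).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return list with `best` (position), `best_loss`, `trace` (best-so-far
#'   loss per iteration, non-increasing) and `evals`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gwo_optimize(sphere, rep(0, 5), rep(1, 5),
#'                     agents = 20, iterations = 50, seed = 1)
#' res$best_loss
#' @export
gwo_optimize <- function(fn, lower, upper, agents = 50L, iterations = 200L,
                         lucky_period = 5L, lucky_count = 5L, seed = 0L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), agents >= 3L)
  safe_fn <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) Inf else v
  }
  clamp <- function(x) pmin(pmax(x, lower), upper)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pos <- matrix(stats::runif(agents * d, rep(lower, each = agents),
                             rep(upper, each = agents)), nrow = agents)
  loss <- apply(pos, 1L, safe_fn)
  evals <- agents
  trace <- numeric(iterations)
  for (t in seq_len(iterations) - 1L) {
    a <- if (iterations > 1L) 2 * (1 - t / (iterations - 1L)) else 0
    ord <- order(loss)
    leaders <- ord[1:3]
    followers <- ord[-(1:3)]
    lead_pos <- pos[leaders, , drop = FALSE]
    for (i in followers) {
      new <- clamp(gwo_move(lead_pos, pos[i, ], a,
                            matrix(stats::runif(3 * d), 3, d),
                            matrix(stats::runif(3 * d), 3, d)))
      new_loss <- safe_fn(new)
      evals <- evals + 1L
      if (new_loss <= loss[i]) { # elitism: keep the better position
        pos[i, ] <- new
        loss[i] <- new_loss
      }
    }
    if (lucky_period > 0L && (t + 1L) %% lucky_period == 0L &&
        length(followers) > 0L) {
      ord2 <- order(loss)
      cands <- ord2[-(1:3)]
      lucky <- cands[sample.int(length(cands),
                                min(lucky_count, length(cands)))]
      for (i in lucky) {
        eps <- stats::runif(1, 0, 0.25)
        new <- clamp(gwo_promote_target(pos[ord2[1:3], , drop = FALSE], eps))
        new_loss <- safe_fn(new)
        evals <- evals + 1L
        if (new_loss <= loss[i]) {
          pos[i, ] <- new
          loss[i] <- new_loss
        }
      }
    }
    trace[t + 1L] <- min(loss)
  }
  best <- which.min(loss)
  list(best = pos[best, ], best_loss = loss[best],
       trace = cummin(trace), evals = evals)
}

#' Validation loss of one atomic model under candidate hyperparameters
#'
#' Mean squared error (Hartree^2) over a validation block, refitting the
#' regression weights for the candidate kernel parameters before predicting.
#'
#' @param X_train,y_train training feature matrix and energies.
#' @param X_val,y_val validation feature matrix and energies (disjoint from
#'   the training block).
#' @param theta kernel weights; `sigma_n2` regularization noise.
#' @inheritParams fit_atomic_model
#' @return mean squared validation error (Ha^2); +Inf if the fit fails.
#' @export
validation_loss <- function(theta, sigma_n2, X_train, y_train, X_val, y_val,
                            mean_kind = "MF1", sigma_f = NULL,
                            periodic = periodic_mask(ncol(X_train))) {
  m <- tryCatch(
    fit_atomic_model(X_train, y_train, theta, sigma_n2, mean_kind,
                     sigma_f = sigma_f, periodic = periodic),
    error = function(e) NULL)
  if (is.null(m)) return(Inf)
  kv <- kernel_matrix(m$X, X_val, m$theta, m$sigma_f, m$periodic)
  pred <- m$mean$value + drop(crossprod(kv, m$weights))
  mean((y_val - pred)^2)
}

#' Grey-wolf hyperparameter search for one atomic model
#'
#' Searches the kernel weights theta (bounds \[0, 1\] per dimension) and the
#' regularization noise sigma_n^2 (bounds \[1e-10, 1e-4\], searched in log10
#' space because the range spans six decades) by minimizing
#' [validation_loss()]. The pre-factor sigma_f stays fixed at
#' sqrt(N_train * N_feats).
#'
#' @inheritParams validation_loss
#' @inheritParams gwo_optimize
#' @return list with `theta`, `sigma_n2`, `loss` and the optimizer `trace`.
#' @export
tune_hyperparameters <- function(X_train, y_train, X_val, y_val,
                                 mean_kind = "MF1",
                                 periodic = periodic_mask(ncol(X_train)),
                                 agents = 50L, iterations = 200L,
                                 lucky_period = 5L, lucky_count = 5L,
                                 seed = 0L) {
  nf <- ncol(X_train)
  lower <- c(rep(0, nf), -10)
  upper <- c(rep(1, nf), -4)
  fn <- function(x)
    validation_loss(x[seq_len(nf)], 10^x[nf + 1L], X_train, y_train,
                    X_val, y_val, mean_kind = mean_kind, periodic = periodic)
  res <- gwo_optimize(fn, lower, upper, agents = agents,
                      iterations = iterations, lucky_period = lucky_period,
                      lucky_count = lucky_count, seed = seed)
  list(theta = res$best[seq_len(nf)], sigma_n2 = 10^res$best[nf + 1L],
       loss = res$best_loss, trace = res$trace)
}

#' Refine a trained molecular model's hyperparameters per atom
#'
#' Runs an independent grey-wolf search for every atomic model against a
#' shared validation block, then refits the weights at the best
#' hyperparameters.
#'
#' @param model a `molecular_gpr` from [train_model()].
#' @param train_configs,val_configs disjoint lists of [labeled_config()]
#'   objects (the training block must be the one the model was built from).
#' @inheritParams gwo_optimize
#' @return the retrained `molecular_gpr`.
#' @export
tune_model <- function(model, train_configs, val_configs, agents = 50L,
                       iterations = 200L, lucky_period = 5L, lucky_count = 5L,
                       seed = 0L) {
  stopifnot(inherits(model, "molecular_gpr"))
  val_feats <- featurize_dataset(lapply(val_configs, `[[`, "geometry"),
                                 model$alf, model$diatomic)
  val_e <- vapply(val_configs,
                  function(c) correct_energies(c)$corrected_atomic_energies,
                  numeric(model$n_atoms))
  for (a in seq_len(model$n_atoms)) {
    m <- model$atoms[[a]]
    tuned <- tune_hyperparameters(m$X, m$y, val_feats[[a]], val_e[a, ],
                                  mean_kind = model$mean_kind,
                                  periodic = m$periodic, agents = agents,
                                  iterations = iterations,
                                  lucky_period = lucky_period,
                                  lucky_count = lucky_count, seed = seed + a)
    model$atoms[[a]] <- fit_atomic_model(
      m$X, m$y, tuned$theta, tuned$sigma_n2, model$mean_kind,
      periodic = m$periodic, atom = a, alf_slice = m$alf_slice)
  }
  model$M <- sum(vapply(model$atoms, function(m) m$mean$value, 0))
  model
}
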