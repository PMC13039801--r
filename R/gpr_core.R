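#' Prior mean functions
#'
#' The value a GP prediction reverts to far from the training data. Six
#' definitions over an atom's training energies are supported, shifted from
#' low- to high-energy states (mu, sigma, max, min and H are the mean,
#' population standard deviation, maximum, minimum and range):
#'
#' * `MF1`: mu
#' * `MF2`: mu + sigma
#' * `MF3`: max
#' * `MF4`: max + 1 H
#' * `MF5`: max + 5 H
#' * `MIN`: min
#'
#' @param kind one of `"MF1"`, ..., `"MF5"`, `"MIN"`.
#' @param training_energies numeric vector of the atom's training energies
#'   (Hartree), nonempty.
#' @return list of class `mean_function` with fields `kind` and `value`.
#' @examples
#' compute_mean("MF5", c(-1, 0, 1))$value  # 1 + 5 * 2 = 11
#' @export
compute_mean <- function(kind, training_energies) {
  kind <- match.arg(kind, c("MF1", "MF2", "MF3", "MF4", "MF5", "MIN"))
  y <- as.numeric(training_energies)
  if (length(y) == 0L) stop("training energies must be nonempty")
  mu <- mean(y)
  sigma <- sqrt(mean((y - mu)^2))  # population sd
  h <- max(y) - min(y)
  value <- switch(kind,
    MF1 = mu,
    MF2 = mu + sigma,
    MF3 = max(y),
    MF4 = max(y) + h,
    MF5 = max(y) + 5 * h,
    MIN = min(y))
  structure(list(kind = kind, value = value), class = "mean_function")
}

#' Composite kernel
#'
#' Similarity between two feature vectors,
#' k = sigma_f * exp(-sum_d theta_d Phi_d), where Phi_d = sin^2(0.5 (R_i - R_j))
#' on periodic (azimuthal-angle) features and (R_i - R_j)^2 otherwise.
#'
#' @param r_i,r_j numeric feature vectors of equal length.
#' @param theta per-feature positive weights in \[0, 1\].
#' @param sigma_f kernel pre-factor.
#' @param periodic logical mask of periodic features (default from
#'   [periodic_mask()]).
#' @return scalar similarity; `gp_kernel(r, r, ...)` equals `sigma_f`.
#' @export
gp_kernel <- function(r_i, r_j, theta, sigma_f = 1,
                      periodic = periodic_mask(length(r_i))) {
  if (length(r_i) != length(r_j) || length(theta) != length(r_i) ||
      length(periodic) != length(r_i))
    stop("feature vectors, theta and periodic mask must share one length")
  delta <- r_i - r_j
  phi <- ifelse(periodic, sin(0.5 * delta)^2, delta^2)
  sigma_f * exp(-sum(theta * phi))
}

#' Kernel matrix between two feature sets
#'
#' @param X,Y feature matrices (rows are configurations).
#' @inheritParams gp_kernel
#' @export
kernel_matrix <- function(X, Y, theta, sigma_f = 1,
                          periodic = periodic_mask(ncol(X))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature dimension mismatch")
  cpp_kernel_matrix(X, Y, as.numeric(theta), sigma_f, as.integer(periodic))
}

#' Default pre-factor sigma_f = sqrt(N_train * N_feats)
#' @param n_train,n_feats training-set size and feature count.
#' @export
default_sigma_f <- function(n_train, n_feats) sqrt(n_train * n_feats)

#' Fit one atomic GP model
#'
#' Solves (K + sigma_n^2 I) w = y - m by Cholesky factorization. If the
#' factorization fails, the jitter escalates tenfold (up to 1e-6) before the
#' fit errors out with a condition-number estimate.
#'
#' @param X N_train x N_feats training feature matrix.
#' @param y training energies (Hartree).
#' @param theta kernel weights (length N_feats, in \[0, 1\]).
#' @param sigma_n2 regularization noise, in \[1e-10, 1e-4\].
#' @param mean_kind prior mean kind (see [compute_mean()]) or a
#'   `mean_function` object.
#' @param sigma_f kernel pre-factor; default sqrt(N_train * N_feats).
#' @param periodic periodic-feature mask.
#' @param atom 1-based atom index this model belongs to (bookkeeping).
#' @param alf_slice list with `x_axis` and `xy_plane` indices for the atom.
#' @return object of class `atomic_gpr`.
#' @export
fit_atomic_model <- function(X, y, theta, sigma_n2 = 1e-8, mean_kind = "MF1",
                             sigma_f = NULL, periodic = periodic_mask(ncol(X)),
                             atom = NA_integer_, alf_slice = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 training configurations")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  theta <- as.numeric(theta)
  if (length(theta) != ncol(X)) stop("length(theta) must equal ncol(X)")
  if (is.null(sigma_f)) sigma_f <- default_sigma_f(nrow(X), ncol(X))
  mf <- if (inherits(mean_kind, "mean_function")) mean_kind
        else compute_mean(mean_kind, y)
  K <- kernel_matrix(X, X, theta, sigma_f, periodic)
  if (!all(is.finite(K))) stop("non-finite kernel matrix")
  jitter <- sigma_n2
  repeat {
    ch <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) break
    if (jitter >= 1e-6)
      stop("kernel matrix not positive definite even at jitter 1e-6 ",
           "(condition estimate ", format(kappa(K), digits = 3), ")")
    jitter <- jitter * 10
  }
  w <- backsolve(ch, forwardsolve(t(ch), y - mf$value))
  structure(list(atom = atom, alf_slice = alf_slice, theta = theta,
                 sigma_f = sigma_f, sigma_n2 = jitter, mean = mf,
                 X = X, y = y, weights = as.numeric(w), periodic = periodic),
            class = "atomic_gpr")
}

#' Predict one atom's energy
#'
#' Posterior mean m_A + sum_i w_i k(R_i, R_j) at a feature vector.
#'
#' @param model an `atomic_gpr`.
#' @param r_j feature vector (or a `featurize()` result).
#' @return predicted energy, Hartree.
#' @export
predict_atomic <- function(model, r_j) {
  stopifnot(inherits(model, "atomic_gpr"))
  if (is.list(r_j)) r_j <- r_j$values
  if (length(r_j) != ncol(model$X)) stop("feature length mismatch")
  k <- kernel_matrix(model$X, matrix(r_j, nrow = 1), model$theta,
                     model$sigma_f, model$periodic)
  model$mean$value + sum(model$weights * k)
}

#' @export
print.atomic_gpr <- function(x, ...) {
  cat(sprintf("<atomic_gpr> atom %s, %d train pts, %d feats, mean %s = %.6f Ha\n",
              x$atom, nrow(x$X), ncol(x$X), x$mean$kind, x$mean$value))
  invisible(x)
}

# internal: featurize every configuration for every atom
# returns list (per atom) of n_config x n_feats matrices
featurize_dataset <- function(geometries, alf, diatomic = FALSE) {
  n <- n_atoms(geometries[[1]])
  if (diatomic || n == 2L) {
    r <- vapply(geometries, function(g)
      sqrt(sum((g$coords[1, ] - g$coords[2, ])^2)), 0)
    return(lapply(1:2, function(a) matrix(r, ncol = 1)))
  }
  f <- 3L * n - 6L
  per_cfg <- lapply(geometries, function(g)
    cpp_features_all(g$coords, alf$x_axis, alf$xy_plane))
  lapply(seq_len(n), function(a)
    do.call(rbind, lapply(per_cfg, function(m) m[a, , drop = FALSE])))
}

# internal: heuristic kernel weights from training feature spread,
# theta_d = 1 / (2 var_d), with a circular variance on periodic features and
# a floor of 1e-3 so far-field kernels still decay. For ALF feature vectors
# the weights are capped at 1 (the hyperparameter window the multi-feature
# kernel sum is calibrated for); the single-feature degenerate mode keeps the
# raw length-scale heuristic, since there is no summation over dimensions to
# absorb a wide per-feature kernel.
heuristic_theta <- function(X, periodic, cap = 1) {
  vapply(seq_len(ncol(X)), function(d) {
    x <- X[, d]
    v <- if (periodic[d]) {
      mu <- atan2(mean(sin(x)), mean(cos(x)))
      mean(sin(0.5 * (x - mu))^2) * 4  # small-angle-consistent spread
    } else stats::var(x)
    min(cap, max(1e-3, 1 / (2 * max(v, 1e-12))))
  }, 0)
}

#' Train a molecular model
#'
#' Applies the recovery-error correction to the labeled configurations,
#' builds the ALF from the first geometry, featurizes every atom, and fits
#' one independent atomic GP per atom. Kernel weights default to a
#' spread-based heuristic (theta_d = 1/(2 var_d), floored at 1e-3 and capped
#' at 1 for ALF models; the cap is dropped in the single-feature diatomic
#' mode) and can optionally be refined per atom with the grey-wolf optimizer
#' (see [tune_hyperparameters()]).
#'
#' @param configs list of [labeled_config()] objects sharing one element list.
#' @param mean_kind prior mean kind, one of MF1..MF5, MIN.
#' @param theta `"heuristic"`, or a list of per-atom weight vectors, or a
#'   single vector recycled over atoms.
#' @param sigma_n2 regularization noise (default 1e-8).
#' @param correct apply the recovery-error correction to the labels
#'   (default TRUE).
#' @param diatomic use the distance-only degenerate feature mode (N = 2).
#' @return object of class `molecular_gpr`.
#' @export
train_model <- function(configs, mean_kind = "MF5", theta = "heuristic",
                        sigma_n2 = 1e-8, correct = TRUE, diatomic = FALSE) {
  stopifnot(length(configs) >= 2L)
  g0 <- configs[[1]]$geometry
  n <- n_atoms(g0)
  if (n == 2L) diatomic <- TRUE
  alf <- if (diatomic) NULL else build_alf(g0)
  feats <- featurize_dataset(lapply(configs, `[[`, "geometry"), alf, diatomic)
  nf <- ncol(feats[[1]])
  pmask <- if (diatomic) FALSE else periodic_mask(nf)
  energies <- if (correct) {
    em <- vapply(configs, function(c) correct_energies(c)$corrected_atomic_energies,
                 numeric(n))
    if (n == 1L) matrix(em, nrow = 1) else em
  } else {
    vapply(configs, `[[`, numeric(n), "raw_atomic_energies")
  }
  atoms <- lapply(seq_len(n), function(a) {
    th <- if (identical(theta, "heuristic"))
      heuristic_theta(feats[[a]], pmask, cap = if (diatomic) Inf else 1)
          else if (is.list(theta)) theta[[a]] else theta
    fit_atomic_model(feats[[a]], energies[a, ], th, sigma_n2 = sigma_n2,
                     mean_kind = mean_kind, periodic = pmask, atom = a,
                     alf_slice = if (diatomic) NULL else
                       list(x_axis = alf$x_axis[a], xy_plane = alf$xy_plane[a]))
  })
  structure(list(elements = g0$elements, n_atoms = n, n_feats = nf,
                 alf = alf, atoms = atoms, diatomic = diatomic,
                 M = sum(vapply(atoms, function(m) m$mean$value, 0)),
                 mean_kind = mean_kind),
            class = "molecular_gpr")
}

#' @export
print.molecular_gpr <- function(x, ...) {
  cat(sprintf(
    "<molecular_gpr> %d atoms [%s], %d train pts, mean %s (M = %.6f Ha)\n",
    x$n_atoms, paste(x$elements, collapse = " "), nrow(x$atoms[[1]]$X),
    x$mean_kind, x$M))
  invisible(x)
}

# internal: flat representation consumed by the C++ core
model_for_cpp <- function(model) {
  stopifnot(inherits(model, "molecular_gpr"), !model$diatomic)
  list(n_atoms = model$n_atoms, n_feats = model$n_feats,
       alfx = model$alf$x_axis, alfy = model$alf$xy_plane,
       periodic = as.integer(periodic_mask(model$n_feats)),
       mean = vapply(model$atoms, function(m) m$mean$value, 0),
       sigma_f = vapply(model$atoms, function(m) m$sigma_f, 0),
       theta = lapply(model$atoms, `[[`, "theta"),
       X = lapply(model$atoms, `[[`, "X"),
       w = lapply(model$atoms, `[[`, "weights"))
}

#' Predict the molecular energy
#'
#' Sum of the atomic predictions, M + sum_A sum_i w_i k_ij.
#'
#' @param model a `molecular_gpr`.
#' @param geometry a [geometry()] with the model's element list.
#' @return molecular energy, Hartree.
#' @export
predict_molecular <- function(model, geometry) {
  stopifnot(inherits(model, "molecular_gpr"))
  if (!identical(geometry$elements, model$elements))
    stop("geometry element list does not match the model")
  if (model$diatomic) {
    r <- featurize(geometry, atom = 1L, diatomic = TRUE)$values
    return(sum(vapply(model$atoms, predict_atomic, 0, r_j = r)))
  }
  cpp_energy_gradient(geometry$coords, model_for_cpp(model),
                      gradient = FALSE)$energy
}
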