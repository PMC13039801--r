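#' Gradient of the composite kernel with respect to the test features
#'
#' For non-periodic features d, dk/dR_d^j = 2 theta_d (R_d^i - R_d^j) k; for
#' periodic features, differentiating -theta_d sin^2(0.5 (R_d^i - R_d^j))
#' with respect to R_d^j gives dk/dR_d^j = 0.5 theta_d sin(R_d^i - R_d^j) k.
#'
#' @inheritParams gp_kernel
#' @return numeric vector, length of the feature layout.
#' @export
kernel_gradient <- function(r_i, r_j, theta, sigma_f = 1,
                            periodic = periodic_mask(length(r_i))) {
  k <- gp_kernel(r_i, r_j, theta, sigma_f, periodic)
  delta <- r_i - r_j
  k * ifelse(periodic, 0.5 * theta * sin(delta), 2 * theta * delta)
}

#' Analytic Cartesian forces of a molecular model
#'
#' Assembles F_A = -dE/dx_A by the chain rule: for every atomic model, the
#' kernel gradient with respect to its test features is pushed through that
#' atom's B-matrix, accumulated over models, and converted from Ha/Angstrom
#' to Ha/Bohr. Because the features are rotation- and translation-invariant,
#' the net force and net torque vanish.
#'
#' @param model a `molecular_gpr` (see [train_model()]).
#' @param geometry a [geometry()] matching the model's element list.
#' @return list of class `force_field`: `forces` (N x 3, Ha/Bohr),
#'   `energy` (Ha), `max_force` (largest absolute component, Ha/Bohr).
#' @export
molecular_forces <- function(model, geometry) {
  stopifnot(inherits(model, "molecular_gpr"))
  if (!identical(geometry$elements, model$elements))
    stop("geometry element list does not match the model")
  if (model$diatomic) {
    r <- featurize(geometry, atom = 1L, diatomic = TRUE)$values
    B <- feature_jacobian(geometry, atom = 1L, diatomic = TRUE)
    dE_dr <- sum(vapply(model$atoms, function(m) {
      k <- drop(kernel_matrix(m$X, matrix(r, 1), m$theta, m$sigma_f, m$periodic))
      delta <- m$X[, 1] - r
      sum(m$weights * k * 2 * m$theta * delta)
    }, 0))
    grad <- matrix(drop(dE_dr * B), ncol = 3, byrow = TRUE)
    energy <- predict_molecular(model, geometry)
  } else {
    res <- cpp_energy_gradient(geometry$coords, model_for_cpp(model),
                               gradient = TRUE)
    grad <- res$gradient
    energy <- res$energy
  }
  forces <- -grad / alfgpr_units$bohr_per_angstrom
  structure(list(forces = forces, energy = energy,
                 max_force = max(abs(forces))),
            class = "force_field")
}

#' Compare analytic forces against central finite differences
#'
#' Displaces every Cartesian coordinate by +/- h, differences the predicted
#' energies, and reports the worst deviation from the analytic forces.
#'
#' @param model a `molecular_gpr`.
#' @param geometry a [geometry()].
#' @param h central-difference step in Angstrom (1e-7 to 1e-4).
#' @return list with `max_abs_dev` (Ha/Bohr), `max_rel_dev` (relative to the
#'   force scale) and the finite-difference force matrix.
#' @export
validate_forces <- function(model, geometry, h = 1e-5) {
  stopifnot(h >= 1e-7, h <= 1e-4)
  ff <- molecular_forces(model, geometry)
  n <- n_atoms(geometry)
  fd <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    gp <- geometry; gp$coords[i, k] <- gp$coords[i, k] + h
    gm <- geometry; gm$coords[i, k] <- gm$coords[i, k] - h
    dEdA <- (predict_molecular(model, gp) - predict_molecular(model, gm)) / (2 * h)
    fd[i, k] <- -dEdA / alfgpr_units$bohr_per_angstrom
  }
  dev <- abs(fd - ff$forces)
  scale <- max(abs(fd), 1e-12)
  list(max_abs_dev = max(dev), max_rel_dev = max(dev) / scale, fd_forces = fd,
       analytic_forces = ff$forces)
}
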