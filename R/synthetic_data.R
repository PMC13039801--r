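#' Analytic toy potential-energy surfaces with an exact atomic partition
#'
#' The toy PES is a classical valence force field — harmonic bonds and
#' angles, cosine torsions, plus a fixed per-element baseline energy — with
#' an analytic gradient. Its energy is partitioned exactly over atoms (each
#' bond term split half/half between its atoms, each angle term assigned to
#' the apex atom, each torsion split half/half between the two central
#' atoms, baselines to their own atom), so the per-atom energies sum to the
#' total by construction. This emulates the structure of topological
#' atomic-energy labels: element-dependent baselines and ranges, several
#' metastable conformers, periodic dihedral dependence.
#'
#' Available systems:
#' * `"diatomic"`: O-H oscillator (engages the 1-feature degenerate mode),
#' * `"chain4"`: C4 chain, 3 bonds / 2 angles / 1 torsion,
#' * `"chain5"`: C4H chain, 4 bonds / 3 angles / 2 torsions,
#' * `"glycine_like"`: 7-atom N/C/O/H fragment with 2 backbone torsions.
#'
#' @param kind toy system name.
#' @return list of class `toy_pes` with the reference `geometry` (built at
#'   the equilibrium internal coordinates, torsions anti) and the term
#'   tables `bonds`, `angles`, `torsions`, `baselines`.
#' @examples
#' toy <- make_toy("chain4")
#' toy_energy(toy, toy$geometry$coords)
#' @export
make_toy <- function(kind = c("diatomic", "chain4", "chain5",
                              "glycine_like")) {
  kind <- match.arg(kind)
  baseline_of <- c(H = -0.5, C = -37.8, N = -54.4, O = -75.0)
  deg <- pi / 180
  spec <- switch(kind,
    diatomic = list(
      elements = c("O", "H"),
      zmat = list(NULL, list(1L, NA, NA, 0.96, NA, NA)),
      bonds = cbind(1L, 2L), kb = 0.60, r0 = 0.96,
      angles = NULL, torsions = NULL),
    chain4 = list(
      elements = rep("C", 4),
      zmat = list(NULL,
                  list(1L, NA, NA, 1.50, NA, NA),
                  list(2L, 1L, NA, 1.50, 109.47 * deg, NA),
                  list(3L, 2L, 1L, 1.50, 109.47 * deg, 180 * deg)),
      bonds = cbind(1:3, 2:4), kb = rep(0.60, 3), r0 = rep(1.50, 3),
      angles = rbind(c(1, 2, 3), c(2, 3, 4)), ka = rep(0.15, 2),
      th0 = rep(109.47 * deg, 2),
      torsions = rbind(c(1, 2, 3, 4)), v = 0.0046, n_per = 3, phase = 0),
    chain5 = list(
      elements = c("C", "C", "C", "C", "H"),
      zmat = list(NULL,
                  list(1L, NA, NA, 1.50, NA, NA),
                  list(2L, 1L, NA, 1.50, 109.47 * deg, NA),
                  list(3L, 2L, 1L, 1.50, 109.47 * deg, 180 * deg),
                  list(4L, 3L, 2L, 1.09, 109.47 * deg, 180 * deg)),
      bonds = cbind(1:4, 2:5), kb = c(0.60, 0.60, 0.60, 0.70),
      r0 = c(1.50, 1.50, 1.50, 1.09),
      angles = rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)),
      ka = rep(0.15, 3), th0 = rep(109.47 * deg, 3),
      torsions = rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)),
      v = c(0.0046, 0.0046), n_per = c(3, 3), phase = c(0, 0)),
    glycine_like = list(
      # N1-C2-C3(=O4) backbone, H5/H6 on N1, H7 on C2
      elements = c("N", "C", "C", "O", "H", "H", "H"),
      zmat = list(NULL,
                  list(1L, NA, NA, 1.45, NA, NA),
                  list(2L, 1L, NA, 1.52, 110 * deg, NA),
                  list(3L, 2L, 1L, 1.23, 120 * deg, 180 * deg),
                  list(1L, 2L, 3L, 1.01, 110 * deg, 60 * deg),
                  list(1L, 2L, 3L, 1.01, 110 * deg, 300 * deg),
                  list(2L, 1L, 5L, 1.09, 109 * deg, 120 * deg)),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(1, 6), c(2, 7)),
      kb = c(0.55, 0.60, 0.90, 0.70, 0.70, 0.70),
      r0 = c(1.45, 1.52, 1.23, 1.01, 1.01, 1.09),
      angles = rbind(c(1, 2, 3), c(2, 3, 4), c(5, 1, 2), c(6, 1, 2),
                     c(5, 1, 6), c(1, 2, 7), c(7, 2, 3)),
      ka = rep(0.15, 7),
      th0 = c(110, 120, 110, 110, 107, 109, 109) * deg,
      torsions = rbind(c(5, 1, 2, 3), c(1, 2, 3, 4)),
      v = c(0.0046, 0.0080), n_per = c(3, 2), phase = c(0, pi)))
  coords <- build_zmatrix(spec$zmat)
  pes <- structure(
    list(kind = kind, elements = spec$elements,
         geometry = geometry(spec$elements, coords, tag = kind),
         bonds = spec$bonds, kb = spec$kb, r0 = spec$r0,
         angles = spec$angles, ka = spec$ka, th0 = spec$th0,
         torsions = spec$torsions, v = spec$v, n_per = spec$n_per,
         phase = spec$phase,
         baselines = unname(baseline_of[spec$elements])),
    class = "toy_pes")
  pes
}

# tiny z-matrix (NeRF) builder: each entry (ref_bond, ref_angle, ref_dih,
# r, angle, dihedral); first three atoms use the obvious reduced forms
build_zmatrix <- function(zmat) {
  n <- length(zmat)
  x <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    z <- zmat[[i]]
    if (i == 1L) next
    if (i == 2L) { x[2, ] <- x[z[[1]], ] + c(z[[4]], 0, 0); next }
    if (is.na(z[[3]]) || is.null(z[[3]])) {
      a <- x[z[[1]], ]; b <- x[z[[2]], ]
      u <- (b - a); u <- u / sqrt(sum(u^2))
      # place in the xy-plane at the requested angle from the a->b direction
      perp <- c(-u[2], u[1], 0)
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      x[i, ] <- a + z[[4]] * (cos(z[[5]]) * u + sin(z[[5]]) * perp)
      next
    }
    a <- x[z[[1]], ]; b <- x[z[[2]], ]; c0 <- x[z[[3]], ]
    bc <- a - b; bc <- bc / sqrt(sum(bc^2))
    nv <- cross3(b - c0, bc); nv <- nv / sqrt(sum(nv^2))
    mv <- cross3(nv, bc)
    d2 <- z[[4]] * c(-cos(z[[5]]), sin(z[[5]]) * cos(z[[6]]),
                     sin(z[[5]]) * sin(z[[6]]))
    x[i, ] <- a + d2[1] * bc + d2[2] * mv + d2[3] * nv
  }
  x
}

#' @export
print.toy_pes <- function(x, ...) {
  cat(sprintf("<toy_pes> %s: %d atoms, %d bonds, %d angles, %d torsions\n",
              x$kind, length(x$elements), nrow(x$bonds),
              if (is.null(x$angles)) 0L else nrow(x$angles),
              if (is.null(x$torsions)) 0L else nrow(x$torsions)))
  invisible(x)
}

# per-term energies; used by both the total and the partition
toy_terms <- function(pes, coords) {
  bonds_e <- {
    d <- sqrt(rowSums((coords[pes$bonds[, 1], , drop = FALSE] -
                       coords[pes$bonds[, 2], , drop = FALSE])^2))
    0.5 * pes$kb * (d - pes$r0)^2
  }
  angles_e <- if (is.null(pes$angles)) numeric(0) else
    vapply(seq_len(nrow(pes$angles)), function(t) {
      a <- pes$angles[t, ]
      u <- coords[a[1], ] - coords[a[2], ]
      w <- coords[a[3], ] - coords[a[2], ]
      th <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
      0.5 * pes$ka[t] * (th - pes$th0[t])^2
    }, 0)
  torsions_e <- if (is.null(pes$torsions)) numeric(0) else
    vapply(seq_len(nrow(pes$torsions)), function(t) {
      phi <- torsion_angle(coords, pes$torsions[t, ])
      pes$v[t] * (1 + cos(pes$n_per[t] * phi - pes$phase[t]))
    }, 0)
  list(bonds = bonds_e, angles = angles_e, torsions = torsions_e)
}

torsion_angle <- function(coords, idx) {
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Toy PES energy, gradient, and exact atomic partition
#'
#' @param pes a `toy_pes`.
#' @param coords N x 3 coordinate matrix (Angstrom); a [geometry()] is also
#'   accepted.
#' @return `toy_energy`: total energy (Hartree, baselines included);
#'   `toy_gradient`: N x 3 gradient (Ha/Angstrom); `toy_atomic_energies`:
#'   per-atom energies summing exactly to the total.
#' @export
toy_energy <- function(pes, coords) {
  if (inherits(coords, "geometry")) coords <- coords$coords
  te <- toy_terms(pes, coords)
  sum(te$bonds) + sum(te$angles) + sum(te$torsions) + sum(pes$baselines)
}

#' @rdname toy_energy
#' @export
toy_atomic_energies <- function(pes, coords) {
  if (inherits(coords, "geometry")) coords <- coords$coords
  te <- toy_terms(pes, coords)
  e <- pes$baselines
  for (b in seq_along(te$bonds)) {
    e[pes$bonds[b, 1]] <- e[pes$bonds[b, 1]] + 0.5 * te$bonds[b]
    e[pes$bonds[b, 2]] <- e[pes$bonds[b, 2]] + 0.5 * te$bonds[b]
  }
  for (a in seq_along(te$angles))
    e[pes$angles[a, 2]] <- e[pes$angles[a, 2]] + te$angles[a]
  for (t in seq_along(te$torsions)) {
    e[pes$torsions[t, 2]] <- e[pes$torsions[t, 2]] + 0.5 * te$torsions[t]
    e[pes$torsions[t, 3]] <- e[pes$torsions[t, 3]] + 0.5 * te$torsions[t]
  }
  e
}

#' @rdname toy_energy
#' @export
toy_gradient <- function(pes, coords) {
  if (inherits(coords, "geometry")) coords <- coords$coords
  n <- nrow(coords)
  g <- matrix(0, n, 3)
  for (b in seq_len(nrow(pes$bonds))) {
    i <- pes$bonds[b, 1]; j <- pes$bonds[b, 2]
    dv <- coords[i, ] - coords[j, ]
    d <- sqrt(sum(dv^2))
    f <- pes$kb[b] * (d - pes$r0[b]) * dv / d
    g[i, ] <- g[i, ] + f; g[j, ] <- g[j, ] - f
  }
  if (!is.null(pes$angles)) for (t in seq_len(nrow(pes$angles))) {
    a <- pes$angles[t, ]
    u <- coords[a[1], ] - coords[a[2], ]
    w <- coords[a[3], ] - coords[a[2], ]
    du <- sqrt(sum(u^2)); dw <- sqrt(sum(w^2))
    uh <- u / du; wh <- w / dw
    cth <- max(-1, min(1, sum(uh * wh)))
    sth <- sqrt(max(1 - cth^2, 1e-14))
    pref <- pes$ka[t] * (acos(cth) - pes$th0[t])
    dth_di <- -(wh - cth * uh) / (sth * du)
    dth_dk <- -(uh - cth * wh) / (sth * dw)
    g[a[1], ] <- g[a[1], ] + pref * dth_di
    g[a[3], ] <- g[a[3], ] + pref * dth_dk
    g[a[2], ] <- g[a[2], ] - pref * (dth_di + dth_dk)
  }
  if (!is.null(pes$torsions)) for (t in seq_len(nrow(pes$torsions))) {
    idx <- pes$torsions[t, ]
    b1 <- coords[idx[2], ] - coords[idx[1], ]
    b2 <- coords[idx[3], ] - coords[idx[2], ]
    b3 <- coords[idx[4], ] - coords[idx[3], ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
    dEdphi <- -pes$v[t] * pes$n_per[t] * sin(pes$n_per[t] * phi - pes$phase[t])
    dphi_d1 <- -nb2 / sum(n1^2) * n1
    dphi_d4 <- nb2 / sum(n2^2) * n2
    c12 <- sum(b1 * b2) / sum(b2^2)
    c32 <- sum(b3 * b2) / sum(b2^2)
    dphi_d2 <- -(1 + c12) * dphi_d1 + c32 * dphi_d4
    dphi_d3 <- c12 * dphi_d1 - (1 + c32) * dphi_d4
    g[idx[1], ] <- g[idx[1], ] + dEdphi * dphi_d1
    g[idx[2], ] <- g[idx[2], ] + dEdphi * dphi_d2
    g[idx[3], ] <- g[idx[3], ] + dEdphi * dphi_d3
    g[idx[4], ] <- g[idx[4], ] + dEdphi * dphi_d4
  }
  g
}

#' Label configurations with noisy partitioned energies
#'
#' Raw per-atom energies are the exact partition plus Gaussian integration
#' noise; heavy (non-hydrogen) atoms get 5x the hydrogen noise scale,
#' mirroring the larger integration errors of heavy atoms. The absolute
#' integration error |L_A| is the absolute value of the injected noise, and
#' the reference molecular energy is the exact total, so the recovery error
#' equals minus the summed noise and [correct_energies()] restores exact
#' conservation.
#'
#' @param pes a `toy_pes`.
#' @param geometries list of geometries.
#' @param noise_sd hydrogen-atom noise standard deviation (Ha, default 1e-4).
#' @param seed integer seed.
#' @return list of [labeled_config()] objects.
#' @export
label_configs <- function(pes, geometries, noise_sd = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd >= 0)
  scale <- ifelse(pes$elements == "H", noise_sd, 5 * noise_sd)
  lapply(geometries, function(g) {
    exact <- toy_atomic_energies(pes, g$coords)
    noise <- stats::rnorm(length(exact), 0, scale)
    if (noise_sd == 0) noise <- rep(0, length(exact))
    labeled_config(g, exact + noise, abs(noise), sum(exact))
  })
}

#' Sample configurations from the toy PES
#'
#' Langevin dynamics directly on the analytic surface at an effective
#' temperature, thinned uniformly after a burn-in.
#'
#' @param pes a `toy_pes`.
#' @param start starting [geometry()] (default: the toy's reference).
#' @param n number of configurations to return.
#' @param t_eff effective temperature (K).
#' @param seed integer seed.
#' @param dt timestep (fs); `thin` steps between kept frames;
#'   `burn_in` discarded leading steps; `friction` in fs^-1.
#' @return list of geometries.
#' @export
sample_configs <- function(pes, start = pes$geometry, n, t_eff, seed = 0L,
                           dt = 0.5, thin = 25L, burn_in = 500L,
                           friction = 0.02) {
  stopifnot(n >= 1L)
  set.seed(seed)
  mass <- element_data(pes$elements)$mass
  natom <- length(mass)
  kT <- alfgpr_units$kb_mdu * t_eff
  x <- start$coords
  v <- init_velocities(start, t_eff, seed = NULL)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  acc <- -toy_gradient(pes, x) * alfgpr_units$mdu_per_hartree / mass
  out <- vector("list", n)
  kept <- 0L
  total_steps <- burn_in + n * thin
  for (s in seq_len(total_steps)) {
    v <- v + 0.5 * dt * acc
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * sqrt(kT / mass) * matrix(stats::rnorm(3 * natom),
                                                natom, 3)
    x <- x + 0.5 * dt * v
    acc <- -toy_gradient(pes, x) * alfgpr_units$mdu_per_hartree / mass
    v <- v + 0.5 * dt * acc
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[[kept]] <- geometry(pes$elements, x)
      if (kept == n) break
    }
  }
  out
}
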