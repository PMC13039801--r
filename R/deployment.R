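#' Maxwell-Boltzmann initial velocities
#'
#' Draws velocities at the target temperature and removes the centre-of-mass
#' drift.
#'
#' @param geometry a [geometry()].
#' @param temperature target temperature (K).
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return N x 3 matrix of velocities (Angstrom/fs).
#' @export
init_velocities <- function(geometry, temperature, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mass <- element_data(geometry$elements)$mass
  n <- length(mass)
  sd <- sqrt(alfgpr_units$kb_mdu * temperature / mass)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  p <- colSums(v * mass)
  sweep(v, 2, p / sum(mass)) # zero total linear momentum
}

#' Run molecular dynamics on a trained model
#'
#' Velocity-Verlet integration with an optional thermostat: `"none"` (NVE),
#' `"nose_hoover"` (single Nose-Hoover thermostat, coupling time 100 dt by
#' default) or `"langevin"` (BAOAB splitting). Every step the bond-length
#' ratio criterion is checked against the reference bond set: the run is
#' declared unstable at the first step where any bond exceeds `ratio_limit`
#' times its equilibrium length or drops below 1/`ratio_limit` of it. A
#' non-finite energy or force also counts as a crash (tagged distinctly).
#'
#' @param model a `molecular_gpr`.
#' @param start starting [geometry()].
#' @param temperature target temperature (K); also used for velocity
#'   initialization when `velocities` is NULL.
#' @param steps number of timesteps.
#' @param dt timestep (fs), default 0.25.
#' @param thermostat `"none"`, `"nose_hoover"` or `"langevin"`.
#' @param tau Nose-Hoover coupling time (fs); default 100 * dt.
#' @param friction Langevin friction (fs^-1), default 0.01.
#' @param reference geometry supplying the bond set and equilibrium lengths
#'   b0 (default: the start geometry).
#' @param ratio_limit stability threshold on bond ratios (default 1.65).
#' @param seed integer seed for velocity draw and Langevin noise.
#' @param velocities optional N x 3 starting velocities (Angstrom/fs).
#' @param sample_every record scalars/frames every this many steps.
#' @param record_frames store sampled coordinates in the trajectory.
#' @return list with `trajectory` (class `md_trajectory`: `frames`, `forces`,
#'   `scalars` data.frame with step/time_fs/epot/ekin/temp) and `stability`
#'   (class `stability_report`: `crash_step`, `crash_kind` ("none", "bond",
#'   "nonfinite"), `stability_time_ps`, `max_ratio` per step, `bonds`, `b0`),
#'   plus the final `state` (coords, velocities, thermostat variable).
#' @export
run_md <- function(model, start, temperature, steps, dt = 0.25,
                   thermostat = c("nose_hoover", "langevin", "none"),
                   tau = 100 * dt, friction = 0.01, reference = start,
                   ratio_limit = 1.65, seed = 0L, velocities = NULL,
                   sample_every = 20L, record_frames = FALSE) {
  stopifnot(inherits(model, "molecular_gpr"), dt > 0, temperature >= 0)
  thermostat <- match.arg(thermostat)
  mode <- switch(thermostat, none = 0L, nose_hoover = 1L, langevin = 2L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocities))
    velocities <- init_velocities(start, max(temperature, 1e-12), seed = NULL)
  mass <- element_data(start$elements)$mass
  bonds <- infer_connectivity(reference)
  b0 <- sqrt(rowSums((reference$coords[bonds[, 1], , drop = FALSE] -
                      reference$coords[bonds[, 2], , drop = FALSE])^2))
  if (steps == 0L) {
    scal <- data.frame(step = 0L, time_fs = 0,
                       epot = predict_molecular(model, start), ekin = NA_real_,
                       temp = NA_real_)
    stab <- structure(list(crash_step = NA_integer_, crash_kind = "none",
                           stability_time_ps = 0, max_ratio = numeric(0),
                           bonds = bonds, b0 = b0),
                      class = "stability_report")
    return(list(trajectory = structure(list(frames = list(start),
                                            forces = list(NULL),
                                            scalars = scal),
                                       class = "md_trajectory"),
                stability = stab,
                state = list(coords = start$coords, velocities = velocities,
                             xi = 0)))
  }
  res <- cpp_run_md(start$coords, velocities, mass, model_for_cpp(model),
                    dt, as.integer(steps), mode, temperature, tau, friction,
                    alfgpr_units$kb_mdu, alfgpr_units$mdu_per_hartree,
                    bonds, b0, ratio_limit, as.integer(sample_every),
                    record_frames)
  crash_step <- if (res$crash_step > 0) res$crash_step else NA_integer_
  crash_kind <- c("none", "bond", "nonfinite")[res$crash_kind + 1L]
  stability_time_ps <- (if (is.na(crash_step)) steps else crash_step) * dt / 1000
  scal <- data.frame(step = as.integer(res$sample_step),
                     time_fs = res$sample_step * dt,
                     epot = res$epot, ekin = res$ekin, temp = res$temp)
  frames <- if (record_frames)
    lapply(seq_len(dim(res$frames)[3]), function(k)
      geometry(start$elements, res$frames[, , k]))
  else list()
  traj <- structure(list(frames = frames,
                         forces = vector("list", length(frames)),
                         scalars = scal),
                    class = "md_trajectory")
  stab <- structure(list(crash_step = crash_step, crash_kind = crash_kind,
                         stability_time_ps = stability_time_ps,
                         max_ratio = as.numeric(res$max_ratio),
                         bonds = bonds, b0 = b0),
                    class = "stability_report")
  list(trajectory = traj, stability = stab,
       state = list(coords = res$coords, velocities = res$vel, xi = res$xi))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s; stability time %.4f ps\n",
              if (is.na(x$crash_step)) "no crash"
              else sprintf("crash (%s) at step %d", x$crash_kind, x$crash_step),
              x$stability_time_ps))
  invisible(x)
}

#' Robustness score: mean stability time over repeated runs
#'
#' Runs one NVT simulation per start (independent Maxwell-Boltzmann velocity
#' draws) capped at `cap_ps`, and averages the per-run stability times.
#'
#' @param model a `molecular_gpr`.
#' @param starts list of starting geometries.
#' @param temperature target temperature (K).
#' @param cap_ps per-run simulation-time cap (ps).
#' @param seeds integer vector, one per start.
#' @param ... further arguments passed to [run_md()].
#' @return list of class `robustness_score`: `score_ps` (mean), per-run
#'   `stabilities_ps` and `n_sim`.
#' @export
robustness <- function(model, starts, temperature, cap_ps = 1000,
                       seeds = seq_along(starts), dt = 0.25, ...) {
  stopifnot(length(starts) >= 1L, length(seeds) == length(starts))
  steps <- round(cap_ps * 1000 / dt)
  s <- vapply(seq_along(starts), function(i) {
    run_md(model, starts[[i]], temperature, steps = steps, dt = dt,
           seed = seeds[i], ...)$stability$stability_time_ps
  }, 0)
  structure(list(score_ps = mean(s), stabilities_ps = s,
                 n_sim = length(starts), temperature = temperature),
            class = "robustness_score")
}

#' @export
print.robustness_score <- function(x, ...) {
  cat(sprintf("<robustness_score> R = %.3f ps over %d runs at %g K\n",
              x$score_ps, x$n_sim, x$temperature))
  invisible(x)
}

#' BFGS geometry optimization on a trained model
#'
#' Quasi-Newton minimization of the predicted energy, terminating when the
#' maximum absolute force component drops to `fmax` (Ha/Bohr) or after
#' `max_steps` gradient evaluations. A start already below `fmax` is
#' returned unchanged.
#'
#' @param model a `molecular_gpr`.
#' @param start starting [geometry()].
#' @param fmax force-convergence threshold, Ha/Bohr (default 0.00045).
#' @param max_steps cap on optimizer iterations (default 500).
#' @return list with `geometry` (optimized), `converged`, `steps`, and
#'   `trace` (data.frame of energy (Ha) and max force (Ha/Bohr) at each
#'   check).
#' @export
bfgs_optimize <- function(model, start, fmax = 0.00045, max_steps = 500L) {
  stopifnot(inherits(model, "molecular_gpr"))
  n <- n_atoms(start)
  cur <- start$coords
  geom_of <- function(x) geometry(start$elements, matrix(x, n, 3))
  fn <- function(x) {
    e <- predict_molecular(model, geom_of(x))
    if (!is.finite(e)) stop("non-finite energy during optimization")
    e
  }
  gr <- function(x) { # gradient in Ha/Angstrom
    ff <- molecular_forces(model, geom_of(x))
    as.numeric(-ff$forces * alfgpr_units$bohr_per_angstrom)
  }
  maxf <- function(x) molecular_forces(model, geom_of(x))$max_force
  trace <- data.frame(step = 0L, energy = fn(as.numeric(cur)),
                      max_force = maxf(as.numeric(cur)))
  if (trace$max_force[1] <= fmax)
    return(list(geometry = start, converged = TRUE, steps = 0L, trace = trace))
  x <- as.numeric(cur)
  done <- 0L
  chunk <- 25L
  repeat {
    res <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = chunk, reltol = 1e-14))
    x <- res$par
    done <- done + chunk
    mf <- maxf(x)
    trace <- rbind(trace, data.frame(step = done, energy = res$value,
                                     max_force = mf))
    if (mf <= fmax || done >= max_steps) break
  }
  list(geometry = geom_of(x), converged = maxf(x) <= fmax, steps = done,
       trace = trace)
}

#' Random Cartesian perturbation of a geometry
#'
#' Displaces every coordinate by an independent uniform draw in
#' (-max_disp, +max_disp).
#'
#' @param g a [geometry()].
#' @param max_disp maximum per-coordinate displacement (Angstrom).
#' @param seed integer seed.
#' @export
perturb_geometry <- function(g, max_disp = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_atoms(g)
  g$coords <- g$coords + matrix(stats::runif(3 * n, -max_disp, max_disp), n, 3)
  g
}

#' Superposition RMSD between two geometries
#'
#' Root-mean-square deviation after optimal rigid alignment (Kabsch
#' rotation on centred coordinates).
#'
#' @param a,b geometries with the same element list.
#' @param heavy_only drop hydrogen atoms before aligning.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, heavy_only = FALSE) {
  if (!identical(a$elements, b$elements)) stop("element lists differ")
  keep <- if (heavy_only) a$elements != "H" else rep(TRUE, n_atoms(a))
  if (sum(keep) < 2L) stop("not enough atoms after filtering")
  cpp_rmsd(a$coords[keep, , drop = FALSE], b$coords[keep, , drop = FALSE])
}

#' Signed dihedral angle
#'
#' @param g a [geometry()].
#' @param atoms length-4 vector of 1-based atom indices.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(g, atoms) {
  stopifnot(length(atoms) == 4L)
  p <- g$coords[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Structural comparison of two geometries
#'
#' @param a,b geometries with the same element list.
#' @param dihedrals optional list of length-4 index vectors; the named
#'   angles are reported for both geometries.
#' @return list with `rmsd` (Angstrom, after superposition) and a
#'   data.frame `dihedrals` (degrees in (-180, 180]) when requested.
#' @export
structural_metrics <- function(a, b, dihedrals = NULL) {
  out <- list(rmsd = rmsd(a, b))
  if (!is.null(dihedrals)) {
    out$dihedrals <- data.frame(
      index = seq_along(dihedrals),
      a_deg = vapply(dihedrals, function(d) dihedral_angle(a, d), 0),
      b_deg = vapply(dihedrals, function(d) dihedral_angle(b, d), 0))
  }
  out
}
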