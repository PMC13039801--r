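#' Infer molecular connectivity from covalent radii
#'
#' Atoms i and j are bonded iff their distance is below 1.2 times the sum of
#' their covalent radii.
#'
#' @param geometry a [geometry()].
#' @return integer matrix with two columns (i, j), i < j, one row per bond.
#' @export
infer_connectivity <- function(geometry) {
  stopifnot(inherits(geometry, "geometry"))
  n <- n_atoms(geometry)
  rad <- element_data(geometry$elements)$covalent_radius
  d <- as.matrix(stats::dist(geometry$coords))
  cutoff <- outer(rad, rad, "+") * 1.2
  bonded <- d < cutoff & upper.tri(d)
  idx <- which(bonded, arr.ind = TRUE)
  bonds <- cbind(i = idx[, 1], j = idx[, 2])
  deg <- tabulate(bonds, nbins = n)
  if (any(deg == 0L))
    stop("isolated atom(s) with no bond: ",
         paste(which(deg == 0L), collapse = ", "))
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' Build the atomic local frame definition
#'
#' For each atom A the x-axis atom is its bonded neighbour of highest atomic
#' mass (ties broken by lowest index) and the xy-plane atom is the
#' next-highest-mass bonded neighbour. If A has a single neighbour X, the
#' xy-plane atom is the heaviest neighbour of X other than A. The choice is
#' deterministic and depends only on masses and connectivity, so it is
#' invariant under rigid motions of the coordinates.
#'
#' @param geometry a [geometry()].
#' @param bonds bond matrix from [infer_connectivity()]; computed if missing.
#' @return An `alf_definition`: list with integer vectors `x_axis` and
#'   `xy_plane` (1-based atom indices, per atom).
#' @export
build_alf <- function(geometry, bonds = infer_connectivity(geometry)) {
  n <- n_atoms(geometry)
  mass <- element_data(geometry$elements)$mass
  nbrs <- lapply(seq_len(n), function(a)
    sort(unique(c(bonds[bonds[, 1] == a, 2], bonds[bonds[, 2] == a, 1]))))
  pick_heaviest <- function(cand, exclude = integer(0)) {
    cand <- setdiff(cand, exclude)
    if (length(cand) == 0L) return(NA_integer_)
    cand[order(-mass[cand], cand)][1L]
  }
  x_axis <- integer(n)
  xy_plane <- integer(n)
  for (a in seq_len(n)) {
    nb <- nbrs[[a]]
    x_axis[a] <- pick_heaviest(nb)
    if (length(nb) >= 2L) {
      xy_plane[a] <- pick_heaviest(nb, exclude = x_axis[a])
    } else {
      xy_plane[a] <- pick_heaviest(nbrs[[x_axis[a]]], exclude = a)
      if (is.na(xy_plane[a]))
        stop("cannot define an ALF for atom ", a,
             ": its only neighbour has no other neighbour")
    }
  }
  structure(list(x_axis = x_axis, xy_plane = xy_plane),
            class = "alf_definition")
}

#' Number of ALF features per atom
#'
#' @param n number of atoms (>= 3); the diatomic degenerate mode has 1
#'   distance feature.
#' @export
n_features <- function(n) if (n == 2L) 1L else 3L * n - 6L

#' Periodic-feature mask
#'
#' Feature d (1-based) is an azimuthal angle, hence periodic, exactly when
#' d > 3 and d mod 3 == 0.
#'
#' @param n_feats number of features.
#' @return logical vector.
#' @export
periodic_mask <- function(n_feats) {
  d <- seq_len(n_feats)
  d > 3L & d %% 3L == 0L
}

#' ALF feature vector of one atom
#'
#' Layout: d1 = distance to the x-axis atom, d2 = distance to the xy-plane
#' atom, d3 = valence angle between them (radians), then for every other atom
#' in ascending index its spherical coordinates (r, theta, phi) in the atom's
#' right-handed local frame. Polar angles lie in \[0, pi\], azimuthal angles in
#' (-pi, pi\]. Features are invariant under rigid rotation and translation.
#'
#' For N = 2 the ALF does not exist; when `diatomic = TRUE` a degenerate
#' 1-feature (interatomic distance) mode is used instead.
#'
#' @param geometry a [geometry()].
#' @param alf an `alf_definition` (ignored in diatomic mode).
#' @param atom 1-based atom index.
#' @param diatomic enable the distance-only degenerate mode for N = 2.
#' @return list with `values` (numeric) and `periodic_mask` (logical).
#' @export
featurize <- function(geometry, alf = NULL, atom, diatomic = FALSE) {
  n <- n_atoms(geometry)
  if (n == 2L) {
    if (!diatomic)
      stop("N = 2 has no ALF (3N-6 = 0); use diatomic = TRUE for the ",
           "distance-only degenerate mode")
    r <- sqrt(sum((geometry$coords[1, ] - geometry$coords[2, ])^2))
    return(list(values = r, periodic_mask = FALSE))
  }
  if (is.null(alf)) alf <- build_alf(geometry)
  vals <- cpp_features(geometry$coords, atom,
                       alf$x_axis[atom], alf$xy_plane[atom])
  list(values = as.numeric(vals), periodic_mask = periodic_mask(3L * n - 6L))
}

#' B-matrix: Jacobian of one atom's ALF features
#'
#' Exact analytic derivatives of the feature vector with respect to all 3N
#' Cartesian coordinates (column order x1, y1, z1, x2, ...), in feature units
#' per Angstrom.
#'
#' @inheritParams featurize
#' @return (3N-6) x 3N numeric matrix (1 x 6 in diatomic mode).
#' @export
feature_jacobian <- function(geometry, alf = NULL, atom, diatomic = FALSE) {
  n <- n_atoms(geometry)
  if (n == 2L) {
    if (!diatomic) stop("N = 2 has no ALF; use diatomic = TRUE")
    d <- geometry$coords[2, ] - geometry$coords[1, ]
    u <- d / sqrt(sum(d^2))
    return(matrix(c(-u, u), nrow = 1L))
  }
  if (is.null(alf)) alf <- build_alf(geometry)
  cpp_feature_jacobian(geometry$coords, atom,
                       alf$x_axis[atom], alf$xy_plane[atom])
}
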