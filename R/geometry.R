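#' Molecular geometry
#'
#' A geometry is a set of atoms with element symbols and Cartesian
#' coordinates in Angstrom. Every symbol must map to a known atomic mass and
#' covalent radius (see [element_data()]).
#'
#' @param elements character vector of element symbols (length N >= 2).
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param tag optional identifier string.
#' @return An object of class `geometry`: a list with fields `elements`,
#'   `coords` and `tag`.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(g)
#' @export
geometry <- function(elements, coords, tag = NULL) {
  elements <- normalize_symbols(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 2L)
    stop("a geometry needs at least 2 atoms")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching length(elements)")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  element_data(elements) # errors on unknown symbols
  dimnames(coords) <- NULL
  structure(list(elements = elements, coords = coords, tag = tag),
            class = "geometry")
}

#' @rdname geometry
#' @param x,g a `geometry`.
#' @export
n_atoms <- function(g) length(g$elements)

#' @rdname geometry
#' @param ... ignored.
#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atoms [%s]%s\n", n_atoms(x),
              paste(x$elements, collapse = " "),
              if (is.null(x$tag)) "" else paste0(" tag=", x$tag)))
  invisible(x)
}

#' Labeled configuration
#'
#' Bundles a geometry with its per-atom raw energies (Hartree), per-atom
#' absolute integration errors (Hartree) and the reference molecular energy
#' (Hartree) used by the recovery-error correction.
#'
#' @param geometry a [geometry()].
#' @param raw_atomic_energies numeric length-N vector, Hartree.
#' @param abs_integration_errors numeric length-N non-negative vector, Hartree.
#' @param ref_molecular_energy scalar, Hartree.
#' @return An object of class `labeled_config`.
#' @export
labeled_config <- function(geometry, raw_atomic_energies,
                           abs_integration_errors, ref_molecular_energy) {
  stopifnot(inherits(geometry, "geometry"))
  n <- n_atoms(geometry)
  raw_atomic_energies <- as.numeric(raw_atomic_energies)
  abs_integration_errors <- as.numeric(abs_integration_errors)
  if (length(raw_atomic_energies) != n || length(abs_integration_errors) != n)
    stop("per-atom arrays must have length ", n)
  if (any(abs_integration_errors < 0))
    stop("abs_integration_errors must be non-negative")
  stopifnot(is.finite(ref_molecular_energy), length(ref_molecular_energy) == 1L)
  structure(list(geometry = geometry,
                 raw_atomic_energies = raw_atomic_energies,
                 abs_integration_errors = abs_integration_errors,
                 ref_molecular_energy = as.numeric(ref_molecular_energy)),
            class = "labeled_config")
}

#' @export
print.labeled_config <- function(x, ...) {
  cat(sprintf("<labeled_config> %d atoms, E_ref = %.8f Ha\n",
              n_atoms(x$geometry), x$ref_molecular_energy))
  invisible(x)
}
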