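#' Recovery-error correction of raw atomic energies
#'
#' The sum of raw per-atom energies misses the reference molecular energy by
#' the recovery error dE = E_ref - sum(E_raw). The correction redistributes
#' this deficit over atoms in proportion to each atom's share of the raw
#' molecular energy, with an additional shift for atoms whose absolute
#' integration error deviates from the mean:
#'
#' E_corr_A = E_raw_A + dE * ( E_raw_A / sum(E_raw)
#'                             + (L_A - mean(L)) )
#'
#' The corrected energies sum to E_ref exactly (algebraic identity), and when
#' dE = 0 the correction is the identity regardless of the integration
#' errors.
#'
#' @param cfg a [labeled_config()].
#' @return list of class `corrected_labels` with fields
#'   `corrected_atomic_energies` (Hartree), `recovery_error` (Hartree) and
#'   `n_atoms`.
#' @examples
#' g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' cfg <- labeled_config(g, c(-0.6, -0.5), c(0.01, 0.03), -1.0)
#' correct_energies(cfg)$corrected_atomic_energies
#' @export
correct_energies <- function(cfg) {
  stopifnot(inherits(cfg, "labeled_config"))
  raw <- cfg$raw_atomic_energies
  labs <- cfg$abs_integration_errors
  e_mol_raw <- sum(raw)
  if (e_mol_raw == 0)
    stop("raw molecular energy is zero: the fractional redistribution ",
         "term is undefined")
  de <- cfg$ref_molecular_energy - e_mol_raw
  corr <- raw + de * (raw / e_mol_raw + (labs - mean(labs)))
  structure(list(corrected_atomic_energies = corr,
                 recovery_error = de,
                 n_atoms = length(raw)),
            class = "corrected_labels")
}
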