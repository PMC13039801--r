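#' Physical constants and element tables
#'
#' All geometry handled by the package is in Angstrom, energies in Hartree.
#' Molecular dynamics uses the Angstrom / femtosecond / atomic-mass-unit
#' system, in which 1 amu A^2/fs^2 = 1e4 kJ/mol. The constants below are the
#' single source of truth for every conversion in the package.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{1.8897259886 (CODATA)}
#'   \item{kcalmol_per_hartree}{627.509474}
#'   \item{mdu_per_kcalmol}{4.184e-4 amu A^2/fs^2 per kcal/mol}
#'   \item{mdu_per_hartree}{product of the two above}
#'   \item{kb_mdu}{Boltzmann constant, amu A^2/fs^2 per K (8.31446e-7)}
#' }
#' @export
alfgpr_units <- local({
  kcal <- 627.509474
  mdu_kcal <- 4.184e-4
  list(
    bohr_per_angstrom = 1.8897259886,
    kcalmol_per_hartree = kcal,
    mdu_per_kcalmol = mdu_kcal,
    mdu_per_hartree = kcal * mdu_kcal,
    kb_mdu = 8.31446261815324e-7
  )
})

# Masses (amu) and single-bond covalent radii (Angstrom, Cordero et al. 2008)
# for the elements the toy systems and typical small organics use.
.element_table <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Na", "Mg", "P", "S", "Cl"),
  mass = c(1.008, 4.0026, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990,
           24.305, 30.974, 32.06, 35.45),
  covalent_radius = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41,
                      1.07, 1.05, 1.02),
  stringsAsFactors = FALSE
)

#' Look up element properties
#'
#' @param symbols character vector of element symbols (case-insensitive).
#' @return data.frame with columns `symbol`, `mass` (amu) and
#'   `covalent_radius` (Angstrom), one row per input symbol.
#' @export
element_data <- function(symbols) {
  symbols <- normalize_symbols(symbols)
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  .element_table[idx, , drop = FALSE]
}

normalize_symbols <- function(symbols) {
  s <- tolower(as.character(symbols))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}
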