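# Stoichiometry inference from light-scattering masses and duplex mass
# computation from sequence composition.

# Average monoisotopic-free (average) masses of 2'-deoxynucleoside
# monophosphate residues within a DNA chain (Da).
NT_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
# Per-strand correction for a 5'-hydroxyl oligo: removal of one HPO3 (79.98)
# plus addition of water at the chain end leaves the standard -61.96 Da.
STRAND_END_CORRECTION <- -61.96

#' Mass of a DNA duplex from its sequence
#'
#' Sums average nucleotide-monophosphate residue masses over both strands
#' (the complement is generated internally) with the standard 5'-hydroxyl
#' end correction of -61.96 Da per strand. Deterministic; symmetric under
#' reverse complement.
#'
#' @param seq A [dna_sequence()] or character scalar (no `N`).
#' @return Duplex mass in kDa.
#' @examples
#' duplex_mass("AAATATTTATTATCGA") # ~9.76 kDa
#' @export
duplex_mass <- function(seq) {
  seq <- as_dna(seq)
  if (grepl("N", seq$bases, fixed = TRUE)) {
    abort("Cannot compute the mass of a sequence containing N.")
  }
  strand_mass <- function(bases) {
    chars <- strsplit(bases, "", fixed = TRUE)[[1]]
    sum(NT_MASS[chars]) + STRAND_END_CORRECTION
  }
  (strand_mass(seq$bases) + strand_mass(reverse_complement(seq$bases))) / 1000
}

#' Infer protein:DNA stoichiometry from a measured complex mass
#'
#' Given the solution mass of a protein-DNA complex (e.g. from SEC-MALS),
#' the protein monomer mass and the duplex mass, returns the nearest integer
#' number of protomers `n = round((complex - dna) / protein)` together with
#' the residual mass after rounding.
#'
#' @param complex_mass Measured complex mass, kDa.
#' @param protein_mass Protein monomer mass, kDa.
#' @param dna_mass DNA duplex mass, kDa (e.g. from [duplex_mass()]).
#' @return Tibble with `n_protein` and `residual_mass` (kDa).
#' @examples
#' infer_stoichiometry(32.7, 12.4, duplex_mass("AAATATTTATTATCGA")) # n = 2
#' infer_stoichiometry(20.1, 12.4, duplex_mass("AAATATTTATTATCGA")) # n = 1
#' @export
infer_stoichiometry <- function(complex_mass, protein_mass, dna_mass) {
  if (any(c(complex_mass, protein_mass, dna_mass) <= 0)) {
    abort("All masses must be positive.")
  }
  n <- round((complex_mass - dna_mass) / protein_mass)
  if (n < 0) {
    abort(paste(
      "Complex mass is below the DNA mass by more than half a protomer:",
      "cannot assign a non-negative stoichiometry."
    ))
  }
  residual <- complex_mass - dna_mass - n * protein_mass
  if (abs(residual) >= protein_mass / 2 + 1e-9) {
    abort("Residual mass after rounding exceeds half a protomer; inputs inconsistent.")
  }
  tibble(n_protein = as.integer(n), residual_mass = residual)
}
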