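# Shared alphabets and scales.

#' @keywords internal
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
HEPTADS <- letters[1:7]

#' @keywords internal
OLIGOMER_CLASSES <- c("NONCOIL", "DIMER", "TRIMER")

#' @keywords internal
COIL_CLASSES <- c("DIMER", "TRIMER")

# Eisenberg consensus hydrophobicity (Eisenberg et al. 1982); also shipped
# as inst/extdata/eisenberg_hydrophobicity.tsv for external use.
#' @keywords internal
EISENBERG_SCALE <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26
)

#' Eisenberg consensus hydrophobicity scale
#'
#' Per-residue hydrophobicity values on the Eisenberg consensus scale,
#' used for the a- and d-position core features.  The ambiguity code
#' `X` maps to 0.
#'
#' @return Named numeric vector over the 20 standard residues plus `X`.
#' @export
#' @examples
#' hydropathy_scale()[["L"]]
hydropathy_scale <- function() {
  c(EISENBERG_SCALE, X = 0)
}

# Map residues to 1..20, NA for X (handled as column average at lookup).
#' @keywords internal
aa_index <- function(residues) {
  match(residues, AMINO_ACIDS)
}

#' @keywords internal
heptad_index <- function(h) {
  match(h, HEPTADS)
}

# Cyclic successor of a heptad letter (g wraps to a); n may be negative.
#' @keywords internal
heptad_shift <- function(h, n) {
  HEPTADS[((heptad_index(h) - 1L + n) %% 7L) + 1L]
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
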