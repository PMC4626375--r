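# Residue alphabets and the Kyte-Doolittle hydropathy scale.

#' Standard amino-acid alphabet in hydropathy order
#'
#' The 20 standard one-letter codes ordered by decreasing Kyte-Doolittle
#' hydropathy index (I, +4.5 first; R, -4.5 last). This is the canonical
#' residue order of every table the package emits, so that composition and
#' difference profiles read left-to-right from most hydrophobic to most
#' hydrophilic, as in standard family-composition figures.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  names(kyte_doolittle())
}

# Ambiguity / non-standard letters tolerated on input but excluded from all
# composition counting.
aa_ambiguous <- function() c("X", "B", "Z", "U", "J", "O")

#' Kyte-Doolittle hydropathy index
#'
#' Per-residue hydropathy values on the dimensionless -4.5 (Arg) to +4.5 (Ile)
#' scale. Positive values favour membrane burial; the seven residues with
#' positive index (I, V, L, F, C, M, A) form the hydrophobic class used by
#' [hi_class_fractions()].
#'
#' @return Named numeric vector of length 20, names are one-letter codes,
#'   ordered by decreasing index.
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
kyte_doolittle <- function() {
  c(I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
    E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

# Residues with positive / negative hydropathy index (sign-based grouping).
hi_positive_residues <- function() names(which(kyte_doolittle() > 0))
hi_negative_residues <- function() names(which(kyte_doolittle() < 0))
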