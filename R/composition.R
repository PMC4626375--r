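# Family amino-acid composition, difference profiles and hydropathy scoring.

#' Amino-acid composition of a family
#'
#' Counts residues pooled over all sequences of a family (total residues
#' across the family, not the mean of per-sequence percentages; a
#' `per_sequence` mode is available for sensitivity analysis). Ambiguity
#' letters (X, B, Z, U, J, O) are excluded from both numerator and
#' denominator. Percentages are on the 0-100 scale and sum to 100.
#'
#' @param x A `core_regions` data.frame (only accepted cores are used; the
#'   core is the analysis unit), a [family_set()] (full-length mode), or a
#'   plain character vector of sequences.
#' @param family Family label; defaults to the label carried by `x`.
#' @param mode `"pooled"` (default) or `"per_sequence"`.
#' @return A `composition_profile`: data.frame with columns `residue`
#'   (hydropathy order, see [aa_alphabet()]), `count`, `percent`; attributes
#'   `family`, `n_sequences`, `n_residues`, `mode`.
#' @export
composition_profile <- function(x, family = NULL, mode = c("pooled", "per_sequence")) {
  mode <- match.arg(mode)
  if (inherits(x, "core_regions")) {
    x <- accepted_cores(x)
    if (is.null(family) && nrow(x)) family <- x$family[1]
    seqs <- x$core
  } else if (inherits(x, "family_set")) {
    if (is.null(family) && nrow(x)) family <- x$family[1]
    seqs <- x$residues
  } else {
    seqs <- as.character(x)
  }
  if (!length(seqs)) stop("empty family: no accepted sequences to profile")
  counts <- Biostrings::letterFrequency(Biostrings::AAStringSet(seqs),
                                        letters = aa_alphabet())
  total <- colSums(counts)
  percent <- if (mode == "pooled") {
    100 * total / sum(total)
  } else {
    colMeans(100 * counts / rowSums(counts))
  }
  out <- data.frame(residue = aa_alphabet(), count = as.integer(total),
                    percent = unname(percent), stringsAsFactors = FALSE)
  attr(out, "family") <- if (is.null(family)) NA_character_ else family
  attr(out, "n_sequences") <- length(seqs)
  attr(out, "n_residues") <- sum(total)
  attr(out, "mode") <- mode
  class(out) <- c("composition_profile", class(out))
  out
}

comp_percent <- function(profile) {
  stats::setNames(profile$percent, profile$residue)[aa_alphabet()]
}

#' Build a composition profile from a plain percentage (or probability) vector
#'
#' Wraps an externally supplied 20-residue composition -- e.g. a row of a
#' precomputed per-family composition table, or one of the built-in synthetic
#' stand-ins -- as a `composition_profile` so it can flow through
#' [percent_difference()], [hydropathy_weight()] and [hi_class_fractions()].
#' Vectors summing to ~1 are interpreted as probabilities and rescaled to
#' percent.
#'
#' @param percent Named numeric vector over the 20 standard residues.
#' @param family Family label.
#' @param n_sequences,n_residues Optional provenance counts.
#' @return A `composition_profile`.
#' @export
as_composition_profile <- function(percent, family,
                                   n_sequences = NA_integer_,
                                   n_residues = NA_integer_) {
  stopifnot(setequal(names(percent), aa_alphabet()), all(percent >= 0))
  percent <- percent[aa_alphabet()]
  if (abs(sum(percent) - 1) < 1e-6) percent <- percent * 100
  if (abs(sum(percent) - 100) > 1e-6) {
    stop("composition must sum to 1 or 100, got ", sum(percent))
  }
  out <- data.frame(residue = aa_alphabet(), count = NA_integer_,
                    percent = unname(percent), stringsAsFactors = FALSE)
  attr(out, "family") <- family
  attr(out, "n_sequences") <- n_sequences
  attr(out, "n_residues") <- n_residues
  attr(out, "mode") <- "external"
  class(out) <- c("composition_profile", class(out))
  out
}

#' Per-residue percent difference between two composition profiles
#'
#' The family-comparison statistic: `100 * (p_family - p_reference) /
#' p_reference` per residue. A residue at exactly 0% in the reference yields
#' an undefined (NA) difference, flagged in the `undefined` column rather than
#' raised as an error.
#'
#' @param profile,reference `composition_profile` objects.
#' @return A `difference_profile`: data.frame with `residue`, `percent`,
#'   `percent_ref`, `percent_diff`, `undefined`; attributes `family`,
#'   `reference`.
#' @export
percent_difference <- function(profile, reference) {
  p <- comp_percent(profile)
  r <- comp_percent(reference)
  diff <- ifelse(r == 0, NA_real_, 100 * (p - r) / r)
  out <- data.frame(residue = aa_alphabet(), percent = unname(p),
                    percent_ref = unname(r), percent_diff = unname(diff),
                    undefined = unname(r == 0), stringsAsFactors = FALSE)
  attr(out, "family") <- attr(profile, "family")
  attr(out, "reference") <- attr(reference, "family")
  class(out) <- c("difference_profile", class(out))
  out
}

#' Hydropathy-weight a difference profile
#'
#' Multiplies each residue's percent difference by its Kyte-Doolittle index.
#' A positive product marks a composition change that promotes overall
#' hydropathy: enrichment of a hydrophobic residue (+diff x +HI) or depletion
#' of a hydrophilic one (-diff x -HI).
#'
#' @param diff A `difference_profile`.
#' @param table Hydropathy table, default [kyte_doolittle()].
#' @return The input with `hydropathy` and `weighted` columns added.
#' @export
hydropathy_weight <- function(diff, table = kyte_doolittle()) {
  hi <- table[diff$residue]
  diff$hydropathy <- unname(hi)
  diff$weighted <- diff$percent_diff * unname(hi)
  diff
}

# Printed 7 + 11 hydropathy class lists (lysine and arginine unassigned).
printed_hi_groups <- function() {
  list(positive = c("I", "V", "L", "F", "C", "M", "A"),
       negative = c("G", "T", "S", "W", "Y", "P", "H", "D", "E", "N", "Q"))
}

#' Hydropathy-class fractions of a composition profile
#'
#' Sums composition percentages over the hydrophobic (positive
#' Kyte-Doolittle index: I, V, L, F, C, M, A) and hydrophilic (negative
#' index) residue classes. The default `sign_based` grouping assigns all 20
#' residues by the sign of their index, so the two fractions sum to 100. The
#' `printed` grouping uses a commonly printed 7 + 11 split that leaves lysine
#' and arginine unassigned; its fractions need not sum to 100.
#'
#' @param profile A `composition_profile`.
#' @param grouping `"sign_based"` (default) or `"printed"`.
#' @param table Hydropathy table for the sign-based split.
#' @return One-row data.frame: `family`, `grouping`, `positive_fraction`,
#'   `negative_fraction` (percent).
#' @export
hi_class_fractions <- function(profile, grouping = c("sign_based", "printed"),
                               table = kyte_doolittle()) {
  grouping <- match.arg(grouping)
  p <- comp_percent(profile)
  grp <- if (grouping == "sign_based") {
    list(positive = names(which(table > 0)), negative = names(which(table < 0)))
  } else {
    printed_hi_groups()
  }
  data.frame(
    family = attr(profile, "family"),
    grouping = grouping,
    positive_fraction = sum(p[grp$positive]),
    negative_fraction = sum(p[grp$negative]),
    stringsAsFactors = FALSE
  )
}

#' Net residue change implied by a class-fraction shift
#'
#' Converts a hydropathy-class shift in percentage points into the implied
#' number of residues for a receptor of typical length: `shift/100 *
#' typical_length`, rounded half away from zero. A 4-point hydrophobic gain at
#' length 300 is 12 residues; a 2-point gain is 6.
#'
#' @param fraction_shift Shift in percentage points.
#' @param typical_length Receptor length in residues (default 300).
#' @return Integer residue count (signed).
#' @export
net_residue_change <- function(fraction_shift, typical_length = 300) {
  stopifnot(typical_length > 0)
  x <- fraction_shift / 100 * typical_length
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
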