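# Seeded generator of GPCR-like synthetic families.
#
# Sequences are i.i.d. residue draws from a target composition, wrapped in
# the two anchor motifs (sequon ... NPxxY) plus scrubbed flanks, so that the
# whole pipeline -- filtering, composition, difference scoring, positional
# profiling -- is testable without any external download. Built-in
# compositions are synthetic stand-ins whose summary statistics encode the
# study conditions of the receptor families they mimic; they are not measured
# database profiles.

#' Built-in amine-like base composition (synthetic stand-in)
#'
#' A fixed, documented 20-residue composition resembling a class-A amine
#' receptor family: hydrophobic-class residues (I, V, L, F, C, M, A) carry
#' 43.8% of the mass, leucine is the most common residue, and tryptophan is
#' rare. Used as the default reference profile in tests and simulations.
#'
#' @return Named numeric probability vector (hydropathy order, sums to 1).
#' @export
amine_like_base <- function() {
  p <- c(I = 6.5, V = 6.1, L = 12.0, F = 6.0, C = 2.8, M = 2.6, A = 7.8,
         G = 6.2, T = 5.6, S = 7.4, W = 2.2, Y = 4.3, P = 4.6, H = 2.5,
         E = 3.9, Q = 3.5, D = 3.6, N = 4.0, K = 4.2, R = 4.7)
  p / sum(p)
}

#' Shift a composition toward a target hydropathy-class split
#'
#' Applies fixed per-residue enrichment factors, then rescales the remaining
#' members of the hydrophobic (positive Kyte-Doolittle) and hydrophilic
#' classes so that the hydrophobic class gains exactly `positive_shift`
#' percentage points while the whole vector still sums to 1. This is how the
#' built-in odorant-receptor-like and TAAR-like stand-ins are constructed:
#' the enrichments and the class shift are the conditions the pipeline is
#' later asked to recover.
#'
#' @param base Named probability vector over the 20 residues.
#' @param enrich Named multiplicative factors (e.g. `c(H = 1.6)`).
#' @param positive_shift Percentage-point gain of the hydrophobic class.
#' @return Named probability vector summing to 1.
#' @export
shifted_composition <- function(base, enrich = numeric(0), positive_shift = 0) {
  p <- base[aa_alphabet()]
  fixed <- names(enrich)
  p[fixed] <- base[fixed] * enrich
  pos <- hi_positive_residues()
  neg <- hi_negative_residues()
  pos_target <- sum(base[pos]) + positive_shift / 100
  free_pos <- setdiff(pos, fixed)
  p[free_pos] <- p[free_pos] * (pos_target - sum(p[intersect(pos, fixed)])) /
    sum(p[free_pos])
  free_neg <- setdiff(neg, fixed)
  p[free_neg] <- p[free_neg] * ((1 - pos_target) - sum(p[intersect(neg, fixed)])) /
    sum(p[free_neg])
  if (any(p < 0)) stop("infeasible shift: negative composition entry")
  p
}

#' OR-like and TAAR-like built-in compositions (synthetic stand-ins)
#'
#' Derived from [amine_like_base()] by [shifted_composition()]:
#' * `or_like_composition()`: histidine and methionine x1.6 (+60% each),
#'   tryptophan x0.4 (-60%), hydrophobic class +4 percentage points;
#' * `taar_like_composition()`: histidine and methionine x1.2 (+20%),
#'   tryptophan x1.1, hydrophobic class +2 points;
#' * `adrenergic_like_composition()`: identical to the amine base (the two
#'   families are compositionally near-indistinguishable).
#'
#' @return Named probability vector summing to 1.
#' @export
or_like_composition <- function() {
  shifted_composition(amine_like_base(),
                      c(H = 1.6, M = 1.6, W = 0.4), positive_shift = 4)
}

#' @rdname or_like_composition
#' @export
taar_like_composition <- function() {
  shifted_composition(amine_like_base(),
                      c(H = 1.2, M = 1.2, W = 1.1), positive_shift = 2)
}

#' @rdname or_like_composition
#' @export
adrenergic_like_composition <- function() amine_like_base()

#' Specify a synthetic family
#'
#' @param family Family label.
#' @param n_sequences Number of sequences.
#' @param composition Named probability vector over the 20 residues.
#' @param core_length Either a single integer (fixed core length, sequon N
#'   through NPxxY Y inclusive) or a list with `range = c(min, max)` and
#'   optionally `modal` and `modal_mass`: with probability `modal_mass` the
#'   core length is `modal`, otherwise uniform over the rest of the range.
#' @param nt_flank,ct_flank `c(min, max)` flank-length ranges. Flanks are
#'   scrubbed so they can never create a spurious anchor: the N-terminal
#'   flank contains no N, the C-terminal flank no P.
#' @param enrichments Named multiplicative factors applied to `composition`
#'   and renormalized (convenience for recovery experiments).
#' @param positional_inserts List of `list(motif =, offset =)` planted
#'   deterministically in every sequence; `offset` is the motif's first
#'   residue relative to the NPxxY Y at 0. Inserts must fit strictly between
#'   the sequon and the NPxxY at the smallest possible core length.
#' @param sequon_text Fixed 3-mer sequon (default: `N`, one draw from the
#'   composition, then S or T).
#' @param npxxy_text Fixed 5-mer NPxxY realization (default: `NP` + two
#'   draws + `Y`).
#' @param seed Master seed; per-sequence streams are derived from it so that
#'   changing `n_sequences` never reshuffles earlier sequences.
#' @return A `family_spec` object.
#' @export
family_spec <- function(family, n_sequences,
                        composition = amine_like_base(),
                        core_length = list(modal = 286, modal_mass = 0.95,
                                           range = c(270, 401)),
                        nt_flank = c(5, 40), ct_flank = c(5, 40),
                        enrichments = NULL,
                        positional_inserts = list(),
                        sequon_text = NULL, npxxy_text = NULL,
                        seed = 1L) {
  stopifnot(n_sequences >= 0, setequal(names(composition), aa_alphabet()),
            all(composition >= 0))
  composition <- composition[aa_alphabet()] / sum(composition)
  if (!is.null(enrichments)) {
    composition[names(enrichments)] <- composition[names(enrichments)] * enrichments
    composition <- composition / sum(composition)
  }
  if (is.numeric(core_length) && length(core_length) == 1L) {
    core_length <- list(modal = as.integer(core_length), modal_mass = 1,
                        range = c(as.integer(core_length), as.integer(core_length)))
  }
  stopifnot(is.list(core_length), !is.null(core_length$range),
            core_length$range[1] >= 10)
  if (is.null(core_length$modal_mass)) core_length$modal_mass <- 0
  min_len <- core_length$range[1]
  for (ins in positional_inserts) {
    m <- nchar(ins$motif)
    if (ins$offset + m - 1L > -5L || min_len + ins$offset < 4L) {
      stop("positional insert '", ins$motif, "' at offset ", ins$offset,
           " does not fit between the anchors at core length ", min_len)
    }
  }
  if (!is.null(sequon_text)) stopifnot(grepl("^N.[STC]$", sequon_text))
  if (!is.null(npxxy_text)) stopifnot(grepl("^NP..Y$", npxxy_text))
  structure(list(family = family, n_sequences = as.integer(n_sequences),
                 composition = composition, core_length = core_length,
                 nt_flank = as.integer(nt_flank), ct_flank = as.integer(ct_flank),
                 positional_inserts = positional_inserts,
                 sequon_text = sequon_text, npxxy_text = npxxy_text,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Deterministic per-sequence stream seed (Knuth multiplicative hash).
stream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 2654435761 + i) %% 2147483647)
}

draw_len <- function(cl) {
  if (cl$modal_mass > 0 && stats::runif(1) < cl$modal_mass) return(cl$modal)
  pool <- setdiff(seq(cl$range[1], cl$range[2]),
                  if (cl$modal_mass > 0) cl$modal else integer(0))
  if (!length(pool)) return(cl$range[1])
  pool[sample.int(length(pool), 1L)]
}

draw_res <- function(n, comp) {
  if (n <= 0) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

#' Generate a synthetic family
#'
#' Each sequence is: scrubbed N-flank + sequon + core interior drawn
#' residue-by-residue from the spec composition (with positional inserts
#' overwritten at their offsets) + NPxxY + scrubbed C-flank. By construction
#' the planted sequon is the most N-terminal sequon and the planted NPxxY is
#' the most C-terminal in-window NPxxY, so the inter-anchor length follows
#' the spec's core-length distribution exactly. Fully reproducible from the
#' spec seed.
#'
#' @param spec A [family_spec()].
#' @return A [family_set()] with ids `<family>_<i>`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  comp <- spec$composition
  nt_comp <- comp; nt_comp["N"] <- 0; nt_comp <- nt_comp / sum(nt_comp)
  ct_comp <- comp; ct_comp["P"] <- 0; ct_comp <- ct_comp / sum(ct_comp)
  n <- spec$n_sequences
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(stream_seed(spec$seed, i))
    L <- draw_len(spec$core_length)
    nt_len <- sample(spec$nt_flank[1]:spec$nt_flank[2], 1L)
    ct_len <- sample(spec$ct_flank[1]:spec$ct_flank[2], 1L)
    sequon <- if (is.null(spec$sequon_text)) {
      c("N", draw_res(1L, comp), sample(c("S", "T"), 1L))
    } else strsplit(spec$sequon_text, "")[[1]]
    npxxy <- if (is.null(spec$npxxy_text)) {
      # middle positions avoid P so the realized motif can never seed a more
      # C-terminal NPxxY spanning into the flank
      c("N", "P", draw_res(2L, ct_comp), "Y")
    } else strsplit(spec$npxxy_text, "")[[1]]
    core <- c(sequon, draw_res(L - 8L, comp), npxxy)
    for (ins in spec$positional_inserts) {
      idx <- L + ins$offset  # first residue of motif, 1-based within core
      core[idx:(idx + nchar(ins$motif) - 1L)] <- strsplit(ins$motif, "")[[1]]
    }
    seqs[i] <- paste(c(draw_res(nt_len, nt_comp), core,
                       draw_res(ct_len, ct_comp)), collapse = "")
  }
  family_set(sprintf("%s_%05d", spec$family, seq_len(n)), seqs, spec$family,
             provenance = sprintf("synthetic(seed=%d)", spec$seed))
}

#' Remove tryptophan except a single planted position
#'
#' Returns a modified spec whose composition carries no tryptophan mass and
#' whose every sequence instead receives exactly one planted W at a fixed
#' core offset -- the near-absent, single-conserved-position tryptophan
#' pattern characteristic of odorant receptors.
#'
#' @param spec A [family_spec()].
#' @param offset Offset of the planted W from the NPxxY Y (default -140,
#'   mid-core).
#' @return A modified `family_spec`.
#' @export
plant_no_trp <- function(spec, offset = -140L) {
  comp <- spec$composition
  comp["W"] <- 0
  spec$composition <- comp / sum(comp)
  spec$positional_inserts <- c(spec$positional_inserts,
                               list(list(motif = "W", offset = as.integer(offset))))
  validate <- family_spec(spec$family, spec$n_sequences, spec$composition,
                          spec$core_length, spec$nt_flank, spec$ct_flank,
                          positional_inserts = spec$positional_inserts,
                          sequon_text = spec$sequon_text,
                          npxxy_text = spec$npxxy_text, seed = spec$seed)
  validate
}

# Conserved-motif inserts characteristic of odorant receptors: three
# histidines and five methionines at discrete positions (one lone methionine
# outside any named motif), for a 286-residue core. Offsets are of each
# motif's first residue relative to the NPxxY Y.
or_conserved_inserts <- function() {
  list(
    list(motif = "LHTPMY",     offset = -230L),  # IC1
    list(motif = "PKML",       offset = -202L),  # EC1
    list(motif = "MAYDRYVAIC", offset = -176L),  # end of TM3
    list(motif = "M",          offset = -136L),  # lone conserved Met
    list(motif = "HFFCD",      offset = -120L),  # EC2
    list(motif = "CSSH",       offset = -60L),   # IC3
    list(motif = "PML",        offset = -7L)     # runs into NPLIY (end of TM7)
  )
}

#' Ready-made family specs at study scale
#'
#' Default specs for the four receptor families the pipeline compares. Sizes
#' are the filtered family tallies (289 adrenergic, 525 TAAR, 1803 amine,
#' 12007 OR). The OR spec puts 95% of its core-length mass at 286 residues
#' within the admissible 270-401 window, fixes the NPxxY realization to
#' NPLIY, and plants the conserved OR motifs (three His / five Met positions
#' plus a single mid-core Trp); see `or_like_composition()` for the
#' composition stand-ins. Amine and adrenergic families draw broader core
#' lengths, TAARs intermediate.
#'
#' @param n_sequences Family size (defaults above).
#' @param seed Master seed.
#' @param conserved_motifs Plant the OR conserved motifs (default TRUE).
#' @return A [family_spec()].
#' @export
or_like_spec <- function(n_sequences = 12007, seed = 1L, conserved_motifs = TRUE) {
  spec <- family_spec(
    "or", n_sequences, or_like_composition(),
    core_length = list(modal = 286, modal_mass = 0.95, range = c(270, 401)),
    positional_inserts = if (conserved_motifs) or_conserved_inserts() else list(),
    npxxy_text = "NPLIY", seed = seed
  )
  if (conserved_motifs) {
    comp <- spec$composition
    comp["W"] <- 0  # single conserved W only, planted below
    spec$composition <- comp / sum(comp)
    spec$positional_inserts <- c(spec$positional_inserts,
                                 list(list(motif = "W", offset = -146L)))
  }
  spec
}

#' @rdname or_like_spec
#' @export
amine_like_spec <- function(n_sequences = 1803, seed = 2L) {
  family_spec("amine", n_sequences, amine_like_base(),
              core_length = list(range = c(270, 401)), seed = seed)
}

#' @rdname or_like_spec
#' @export
adrenergic_like_spec <- function(n_sequences = 289, seed = 3L) {
  family_spec("adrenergic", n_sequences, adrenergic_like_composition(),
              core_length = list(range = c(270, 401)), seed = seed)
}

#' @rdname or_like_spec
#' @export
taar_like_spec <- function(n_sequences = 525, seed = 4L) {
  family_spec("taar", n_sequences, taar_like_composition(),
              core_length = list(modal = 291, modal_mass = 0.6,
                                 range = c(275, 330)), seed = seed)
}
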