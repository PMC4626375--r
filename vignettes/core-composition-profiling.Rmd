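---
title: "Core-region composition profiling of GPCR superfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-region composition profiling of GPCR superfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrcore)
```

## The analysis unit: the anchored core region

Class-A GPCRs share two near-universal landmarks: an N-linked glycosylation
sequon (N-x-S/T, extended here to N-x-S/T/C to admit non-consensus sites such
as NHC) near the N-terminus, and the NPxxY pentapeptide at the cytoplasmic
end of transmembrane helix 7. N- and C-terminal tails vary enormously in
length across families, so raw sequence coordinates are not comparable
between, say, a 320-residue odorant receptor and a 470-residue adrenergic
receptor. The package therefore reduces every receptor to its *core region*:
the sub-sequence from the most N-terminal sequon through the NPxxY motif.

Numerical conventions, fixed once:

* **Inclusive counting.** Core length runs from the sequon's N through the
  NPxxY's Y, both ends included. Odorant-receptor cores cluster tightly
  around 286 residues under this convention, which is what makes the
  anchored comparison meaningful.
* **Anchor multiplicity.** The sequon is the left-most match (ties cannot
  occur). NPxxY can match several times; the *most C-terminal* match whose
  implied core length falls inside the admissible window is taken, because
  the motif sits anatomically at the end of TM7. Without a window constraint
  the most C-terminal match overall is used.
* **Length filter.** Cores outside 270–401 residues are rejected; bounds are
  inclusive. Every rejection carries one reason (`no_sequon`, `no_npxxy`,
  `too_short`, `too_long`) and filter reports always satisfy
  `n_input = n_accepted + n_rejected`.
* **Ambiguity letters.** X/B/Z/U/J/O are retained at load and through
  filtering (cores containing them are accepted but flagged), and excluded
  from all composition counting — an explicit policy rather than a silent
  one, since exclusion changes denominators.
* **The sequon x position** admits any residue, including proline, by
  default; a strict mode (`strict_x = TRUE`) is available for sensitivity
  checks because glycosylation-prediction conventions differ on P.

## Composition statistics

Family composition is **pooled**: total counts over all core residues of all
accepted sequences, converted to percentages on the 0–100 scale. Pooling
weights longer cores proportionally, which is the natural estimator for "the
composition of this family's core residues"; a `per_sequence` mode (mean of
per-sequence percentages) is available for sensitivity analysis. Composition
is computed on core regions, the filtered analysis unit, not on full-length
sequences (full-length mode exists via `family_set` input).

The family-comparison statistic is the per-residue percent difference versus
a reference family,

$$\Delta_r = 100\,\frac{p_r^{\text{fam}} - p_r^{\text{ref}}}{p_r^{\text{ref}}},$$

with a reference residue at exactly 0% flagged undefined rather than raised
as an error. Hydropathy weighting multiplies $\Delta_r$ by the residue's
Kyte–Doolittle index ($-4.5$ for Arg to $+4.5$ for Ile): a positive product —
gaining a hydrophobic residue or shedding a hydrophilic one — promotes
overall hydropathy.

Class fractions sum composition over the hydrophobic (positive-index:
I, V, L, F, C, M, A) and hydrophilic (negative-index) classes. The default
`sign_based` grouping covers all 20 residues, so the two fractions sum
to 100. A second, `printed` grouping reproduces a commonly printed 7 + 11
split that leaves lysine and arginine unassigned; we treat the sign-based
grouping as primary because it is the only self-consistent reading (K and R
have strongly negative indices and belong in the hydrophilic class), and
expose the printed lists for exact replication attempts.
`net_residue_change()` converts a class shift in percentage points into
residues at a typical receptor length, rounding half away from zero. The
default `typical_length = 300` sits between the ~286-residue core and the
~320-residue full OR, and is the length at which a 4-point shift corresponds
to twelve residues and a 2-point shift to six.

## Positional profiles

Distribution curves of a residue along the core are anchored at the NPxxY
tyrosine (offset 0, negative offsets upstream), because C-terminal topology
is shared while N-terminal lengths vary. The default normalization divides
per-offset counts by *coverage* — the number of cores long enough to reach
that offset — rather than by family size; family-size normalization would
deflate upstream frequencies in families with variable core lengths, and is
provided only as an option. No smoothing is applied by default.

Peak calling reports local maxima with frequency ≥ `min_height` (default
0.5) and coverage ≥ `min_coverage` (default half the family size), collapsing
adjacent qualifying offsets to their maximum. The thresholds are our own
choice — the published figures name no cutoff — and are deliberately strict:
a peak must occur in the majority of sequences that reach its position.

## Conservation and identity

Alignment-column statistics are computed on *consumed* alignments (aligned
FASTA or Clustal, built externally, e.g. with Clustal Omega); the package
never constructs multiple alignments. Per column we report non-gap residue
frequencies, the gap fraction, the majority residue, and information content
$IC = \log_2 20 - H$ (Shannon entropy of the non-gap frequency vector, no
small-sample correction) — the bit scale of a sequence logo. Conserved
columns are called by majority-residue frequency (> 0.5 by default, > 0.9
for a strict "most highly conserved" call); frequency thresholding is the
reproducible operationalization of "more than 50% conservation", and both
the frequency and IC are emitted so either reading can be tested. Columns
with gap fraction > 0.5 are excluded from calls.

Pairwise identity uses Needleman–Wunsch global alignment through
`Biostrings::pairwiseAlignment` with EMBOSS-needle-like defaults: BLOSUM62,
gap open 10, gap extend 0.5 (a gap of length $L$ costs $10 + 0.5L$). The
default identity denominator is the full alignment length including gap
columns, with a `no_terminal_gaps` option; for tail-heavy receptor pairs the
intended comparison is between pre-extracted cores. The test suite verifies
the alignment score against an exhaustive, memoized search over all
alignment paths on short peptides.

## The synthetic-family generator

Every pipeline stage is validated on generated families, so the generator's
defaults *are* the study conditions:

* **Family sizes** default to the filtered tallies of the four receptor
  groups: 289 adrenergic, 525 TAAR, 1803 amine, 12007 OR.
* **Core lengths.** The OR spec puts 95% of its mass at 286 residues, the
  remainder uniform over the rest of the 270–401 window. Amine and
  adrenergic lengths are uniform over 270–401 and TAARs concentrate near 291
  within 275–330 — those two distributions are our own realistic choices
  (the families are known to vary in length where ORs do not; no published
  distribution is available to copy).
* **Compositions.** `amine_like_base()` is a fixed, documented stand-in for
  an amine-receptor core composition (43.8% hydrophobic-class mass, leucine
  most frequent). The OR-like profile is *constructed* from it by
  `shifted_composition()`: His ×1.6 and Met ×1.6 (+60% each), Trp ×0.4
  (−60%), and the remaining class members rescaled so the hydrophobic class
  gains exactly 4 percentage points; the TAAR-like profile uses ×1.2 factors
  and a 2-point shift. The ×1.6 vs ×1.2 and ×0.4 vs ×1.1 contrasts encode
  the reported ~3-fold OR/TAAR differences for Met, His and Trp. These are
  synthetic stand-ins that encode published summary statistics — the
  recovery tests demonstrate that the pipeline measures such differences
  correctly, not that these are the true database profiles.
* **Sequence model.** Residues are i.i.d. draws from the target composition
  (no Markov structure): composition-level analyses are the object under
  test, so independence is the minimal sufficient model. Each sequence is
  `N-flank + sequon + interior + NPxxY + C-flank`; the N-flank is drawn
  without asparagine and the C-flank (and the NPxxY middle positions)
  without proline, so a generated sequence can never contain a spurious
  anchor that displaces the planted ones — acceptance and core length are
  exact by construction, not approximately.
* **Planted motifs.** The OR spec plants the conserved OR motifs (LHTPMY,
  PKML, MAYDRYVAIC, a lone Met, HFFCD, CSSH, PML·NPLIY) at fixed anchored
  offsets consistent with a 286-residue core's topology, plus a single
  mid-core Trp, producing the characteristic 3-His/5-Met/1-Trp positional
  peaks. Planted motifs overwrite sampled positions, keeping lengths exact.
  Consequently the *sequence-level* OR family is slightly His/Met-richer
  than the OR-like composition vector; composition-delta checks therefore
  use the profile vectors directly (deterministic arithmetic), while
  enrichment-recovery checks use insert-free families.
* **Seeding.** One master seed per spec; per-sequence streams are derived by
  a multiplicative hash, so growing a family never reshuffles earlier
  sequences, and everything is bit-reproducible from `(spec, seed)`.

With enrichment factors renormalized to a probability vector, a ×1.6
histidine enrichment corresponds to an expected percent difference of
$100(1.6/1.015 - 1) \approx 57.6$, recovered within the ±5-point band at
1000 sequences × ~286 residues (sampling SD ≈ 2.4 points).

### What the generator does not emulate

No evolutionary covariation, no alignment structure, no per-species
redundancy, no pseudogene contamination, and no real motif degeneracy
(planted motifs are exact in every sequence, whereas real conserved
positions are merely frequent). Passing tests therefore demonstrate the
*correctness of the measurements* under known truth, not properties of real
receptor databases. Analyses of real families require their FASTA sets via
`read_family_fasta()`/`read_manifest()`; published family-level numbers are
recoverable only from the corresponding published sequence sets, which this
package does not redistribute. For the same reason the pairwise-identity
worked examples (an OR core versus the β2-adrenergic receptor at ~18%
identity) ship as machinery plus tests on constructed pairs, not as bundled
receptor sequences.

## Problem sizes and determinism

The test suite runs the full pipeline at study scale (14,624 sequences,
~4.4 M residues; a few seconds) and uses 100–2000-sequence families for
statistical checks — sizes at which multinomial sampling error is well below
the asserted tolerances. All stochastic tests fix their seeds;
`scripts/acceptance.R` derives every stream from its `--seed` argument and
is byte-reproducible for a fixed seed.

## Known limitations

* Transmembrane topology is never predicted; motif positions are reported
  as anchored offsets only.
* The identity statistic depends on aligner parameters; published identity
  counts computed with unknown parameters can be matched only to within a
  couple of identities.
* The built-in compositions are stand-ins; conclusions about real families
  must be drawn from real sequence sets run through the same pipeline.
* `shifted_composition()` requires feasible targets (no negative entries);
  extreme enrichments combined with large class shifts will error rather
  than silently clip.
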