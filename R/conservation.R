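# Alignment-column conservation statistics and pairwise global identity.
#
# Multiple alignments are consumed, never built: they arrive as aligned FASTA
# or Clustal files (or in-memory rows of equal length) produced by an external
# aligner.

align_gap_chars <- "[-.]"

as_alignment_rows <- function(alignment) {
  if (inherits(alignment, "AAMultipleAlignment")) {
    return(as.character(Biostrings::unmasked(alignment)))
  }
  if (inherits(alignment, "XStringSet")) return(as.character(alignment))
  if (length(alignment) == 1L && file.exists(alignment)) {
    first <- readLines(alignment, n = 1L, warn = FALSE)
    fmt <- if (startsWith(first, ">")) "fasta" else "clustal"
    return(as.character(Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(alignment, format = fmt))))
  }
  toupper(as.character(alignment))
}

#' Per-column conservation statistics of a multiple alignment
#'
#' Computes, for every alignment column, residue frequencies over non-gap
#' symbols, the gap fraction, the majority residue with its frequency, and
#' the information content in bits: `log2(20)` minus the Shannon entropy of
#' the non-gap frequency vector (no small-sample correction) -- the height
#' scale of a sequence logo. Ambiguity letters are excluded from the
#' frequency denominator; gap characters are `-` and `.`.
#'
#' @param alignment Aligned FASTA/Clustal file path, an `AAMultipleAlignment`
#'   or `AAStringSet`, or a character vector of equal-length aligned rows.
#' @return data.frame with `column`, `majority`, `majority_freq`,
#'   `gap_fraction`, `ic`; the full 20 x ncol residue-frequency matrix is
#'   attached as attribute `frequencies`.
#' @export
column_stats <- function(alignment) {
  rows <- as_alignment_rows(alignment)
  if (!length(rows)) stop("empty alignment")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged alignment: row ", bad, " has width ", widths[bad],
         " (expected ", widths[1], ")")
  }
  mat <- do.call(rbind, strsplit(rows, ""))
  ncol_aln <- ncol(mat)
  freqs <- matrix(0, nrow = 20, ncol = ncol_aln,
                  dimnames = list(aa_alphabet(), NULL))
  gap_fraction <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(grepl(align_gap_chars, col))
    counts <- table(factor(col[col %in% aa_alphabet()], levels = aa_alphabet()))
    tot <- sum(counts)
    if (tot > 0) freqs[, j] <- as.numeric(counts) / tot
  }
  ent <- apply(freqs, 2, function(f) {
    f <- f[f > 0]
    if (!length(f)) return(log2(20))  # all-gap column: zero information
    -sum(f * log2(f))
  })
  maj_idx <- apply(freqs, 2, which.max)
  out <- data.frame(
    column = seq_len(ncol_aln),
    majority = aa_alphabet()[maj_idx],
    majority_freq = freqs[cbind(maj_idx, seq_len(ncol_aln))],
    gap_fraction = gap_fraction,
    ic = pmax(0, log2(20) - ent),
    stringsAsFactors = FALSE
  )
  out$majority[colSums(freqs) == 0] <- NA_character_
  out$majority_freq[colSums(freqs) == 0] <- 0
  attr(out, "frequencies") <- freqs
  out
}

#' Conserved alignment columns
#'
#' Columns whose majority-residue frequency exceeds `threshold` (default 0.5;
#' use 0.9 for a strict "most highly conserved" call). Columns with a gap
#' fraction above `max_gap_fraction` are excluded from the call.
#'
#' @param stats Output of [column_stats()].
#' @param threshold Majority-frequency cutoff (exceeded strictly), default 0.5.
#' @param max_gap_fraction Columns gappier than this are skipped, default 0.5.
#' @return Integer vector of 1-based column indices.
#' @export
conserved_columns <- function(stats, threshold = 0.5, max_gap_fraction = 0.5) {
  which(stats$majority_freq > threshold & stats$gap_fraction <= max_gap_fraction)
}

#' Pairwise global-alignment percent identity
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with EMBOSS-needle-like defaults (BLOSUM62, gap open 10, gap extend 0.5).
#' Identity is the count of identical aligned columns; the default
#' denominator is the full alignment length including gap columns, with an
#' option to exclude terminal-gap columns.
#'
#' @param seq_a,seq_b Residue strings (non-empty).
#' @param id_a,id_b Identifiers carried into the result.
#' @param substitution_matrix Name of a matrix shipped with Biostrings.
#' @param gap_opening,gap_extension Affine gap costs (positive).
#' @param denominator `"full"` (default) or `"no_terminal_gaps"`.
#' @return One-row data.frame: `id_a`, `id_b`, `aligned_length`, `identities`,
#'   `percent_identity`, `score`.
#' @export
global_align_identity <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                                  substitution_matrix = "BLOSUM62",
                                  gap_opening = 10, gap_extension = 0.5,
                                  denominator = c("full", "no_terminal_gaps")) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- rep(TRUE, length(pa))
  if (denominator == "no_terminal_gaps") {
    res <- pa != "-" & sa != "-"
    keep <- seq_along(pa) >= min(which(res)) & seq_along(pa) <= max(which(res))
  }
  ident <- sum(pa[keep] == sa[keep] & pa[keep] != "-")
  alen <- sum(keep)
  data.frame(
    id_a = id_a, id_b = id_b,
    aligned_length = alen, identities = ident,
    percent_identity = 100 * ident / alen,
    score = Biostrings::score(aln),
    stringsAsFactors = FALSE
  )
}

#' Locate conserved motifs in a sequence
#'
#' Finds all occurrences of each pattern; `x` (either case) in a pattern is a
#' single-position wildcard. With `max_mismatch = 1`, near-matches at exactly
#' one non-wildcard mismatch are also reported and flagged in the
#' `mismatches` column.
#'
#' @param residues A single residue string.
#' @param motifs Character vector of patterns (e.g. `"NPxxY"`,
#'   `"MAYDRYVAIC"`).
#' @param max_mismatch 0 (default) or 1.
#' @return data.frame with `pattern`, `start`, `matched_text`, `mismatches`;
#'   zero rows when nothing matches.
#' @export
motif_map <- function(residues, motifs, max_mismatch = 0) {
  stopifnot(length(residues) == 1L, max_mismatch %in% c(0, 1))
  chars <- strsplit(residues, "")[[1]]
  out <- lapply(motifs, function(pat) {
    pchars <- strsplit(pat, "")[[1]]
    wild <- pchars %in% c("x", "X")
    m <- length(pchars)
    n <- length(chars)
    if (m > n) return(NULL)
    starts <- seq_len(n - m + 1L)
    mism <- vapply(starts, function(s) {
      win <- chars[s:(s + m - 1L)]
      sum(win[!wild] != toupper(pchars[!wild]))
    }, integer(1))
    hit <- which(mism <= max_mismatch)
    if (!length(hit)) return(NULL)
    data.frame(pattern = pat, start = hit,
               matched_text = vapply(hit, function(s)
                 paste(chars[s:(s + m - 1L)], collapse = ""), character(1)),
               mismatches = mism[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pattern = character(0), start = integer(0),
                      matched_text = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
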