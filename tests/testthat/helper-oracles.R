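# Independent brute-force oracles, deliberately naive and separate from the
# implementation paths they check.

# Left-most sequon position by an explicit window scan.
oracle_sequon <- function(seq, third = c("S", "T", "C")) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  for (i in seq_len(max(0, n - 2))) {
    if (ch[i] == "N" && ch[i + 2] %in% third) return(i)
  }
  NA_integer_
}

# All NPxxY starts by an explicit window scan.
oracle_npxxy <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- integer(0)
  for (i in seq_len(max(0, n - 4))) {
    if (ch[i] == "N" && ch[i + 1] == "P" && ch[i + 4] == "Y") out <- c(out, i)
  }
  out
}

# Per-character composition tally (percent over the 20 standard residues).
oracle_composition <- function(seqs) {
  ch <- unlist(strsplit(seqs, ""))
  ch <- ch[ch %in% aa_alphabet()]
  100 * table(factor(ch, levels = aa_alphabet())) / length(ch)
}

# Per-offset count of a residue, anchored at the last position (offset 0).
oracle_positional <- function(seqs, residue) {
  counts <- new.env()
  for (s in seqs) {
    ch <- rev(strsplit(s, "")[[1]])
    for (k in which(ch == residue)) {
      key <- as.character(-(k - 1L))
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  out[order(as.integer(names(out)))]
}

# Optimal global affine-gap alignment score by memoized exhaustive recursion
# over all alignment paths (gap of length L costs open + L * ext, matching
# the EMBOSS-needle convention).
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  submat <- get_blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- new.env()
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      best <- max(best, -(ext + if (prev == "X") 0 else open) + rec(i + 1L, j, "X"))
    }
    if (j <= m) {
      best <- max(best, -(ext + if (prev == "Y") 0 else open) + rec(i, j + 1L, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "M")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# A random residue string from the 20 standard letters.
random_seq <- function(n) paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")

# Expected core composition (percent) for a default spec at fixed core
# length L: the two anchors pin N, P, Y and the sequon S/T, one sequon draw
# and the core interior come from the spec composition, and the two NPxxY
# middle draws come from the proline-free composition.
expected_core_composition <- function(comp, L) {
  fixed <- stats::setNames(numeric(20), names(comp))
  fixed["N"] <- 2; fixed["P"] <- 1; fixed["Y"] <- 1
  fixed["S"] <- 0.5; fixed["T"] <- 0.5
  ct <- comp; ct["P"] <- 0; ct <- ct / sum(ct)
  100 * (fixed + (L - 7) * comp + 2 * ct) / L
}

# Reject-reason column names of a filter report.
core_reject_names <- function() {
  c("no_sequon", "no_npxxy", "too_short", "too_long", "nonstandard_letters")
}
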