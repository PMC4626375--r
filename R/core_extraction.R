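# Anchor-motif scanning and core-region extraction.
#
# The analysis unit of the whole pipeline is the "core region": the
# sub-sequence running from the most N-terminal N-linked glycosylation sequon
# (NxS/T/C) through the NPxxY motif at the cytoplasmic end of TM7, counted
# inclusively from the sequon's N to the NPxxY's Y. Families are restricted to
# cores of 270-401 residues.

sequon_regex <- function(alphabet = c("stc", "st"), strict_x = FALSE) {
  alphabet <- match.arg(alphabet)
  sprintf("N%s[%s]", if (strict_x) "[^P]" else "[A-Z]",
          if (alphabet == "stc") "STC" else "ST")
}

#' Find the most N-terminal glycosylation sequon
#'
#' Scans for N-x-S/T (or N-x-S/T/C when `alphabet = "stc"`, the default, which
#' also admits non-consensus sites such as NHC) and returns the left-most
#' match. `strict_x = TRUE` disallows proline at the x position; the default
#' allows any residue because glycosylation-site annotation practice varies.
#'
#' @param residues A single residue string (normalized, upper-case).
#' @param alphabet `"stc"` or `"st"`: third-position alphabet.
#' @param strict_x Disallow P at the middle position.
#' @return A list with `pattern = "sequon"`, `start` (1-based) and
#'   `matched_text`, or `NULL` when no sequon exists.
#' @export
find_sequon <- function(residues, alphabet = c("stc", "st"), strict_x = FALSE) {
  stopifnot(length(residues) == 1L)
  pos <- regexpr(sequon_regex(alphabet, strict_x), residues)[1]
  if (pos < 0) return(NULL)
  list(pattern = "sequon", start = pos,
       matched_text = substr(residues, pos, pos + 2L))
}

# All NPxxY match starts (overlap-safe via look-ahead); one sequence.
npxxy_starts <- function(residues) {
  m <- gregexpr("(?=NP..Y)", residues, perl = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m)
}

#' Find the TM7-terminal NPxxY motif
#'
#' Among all matches of N-P-x-x-Y, returns the most C-terminal one. When a
#' sequon position and a length window are supplied, only matches whose
#' implied core length (sequon N through NPxxY Y, inclusive) falls inside the
#' window qualify; the motif sits anatomically at the end of TM7, so the most
#' C-terminal qualifying match is taken.
#'
#' @param residues A single residue string.
#' @param sequon_start 1-based sequon position, or `NULL` for an
#'   unconstrained scan.
#' @param window Length-2 numeric `c(min, max)` core-length window, or `NULL`.
#' @return A list with `pattern = "npxxy"`, `start`, `matched_text`, or `NULL`.
#' @export
find_npxxy <- function(residues, sequon_start = NULL, window = NULL) {
  stopifnot(length(residues) == 1L)
  starts <- npxxy_starts(residues)
  if (!is.null(sequon_start)) {
    starts <- starts[starts + 4L - sequon_start + 1L >= 8L]  # motif after sequon
    if (!is.null(window)) {
      len <- starts + 4L - sequon_start + 1L
      starts <- starts[len >= window[1] & len <= window[2]]
    }
  }
  if (!length(starts)) return(NULL)
  pos <- max(starts)
  list(pattern = "npxxy", start = pos,
       matched_text = substr(residues, pos, pos + 4L))
}

core_reject_reasons <- function() {
  c("no_sequon", "no_npxxy", "too_short", "too_long", "nonstandard_letters")
}

# Vectorized worker shared by extract_core() and filter_family().
core_scan <- function(id, family, residues, alphabet = "stc", strict_x = FALSE,
                      min_core = 270L, max_core = 401L) {
  n <- length(residues)
  seq_start <- as.integer(regexpr(sequon_regex(alphabet, strict_x), residues))
  seq_start[seq_start < 0] <- NA_integer_
  np_all <- gregexpr("(?=NP..Y)", residues, perl = TRUE)

  np_start <- rep(NA_integer_, n)
  status <- rep("rejected", n)
  reason <- rep("none", n)
  for (i in seq_len(n)) {
    if (is.na(seq_start[i])) { reason[i] <- "no_sequon"; next }
    starts <- np_all[[i]]
    starts <- if (starts[1] < 0) integer(0) else as.integer(starts)
    len <- starts + 4L - seq_start[i] + 1L
    starts <- starts[len >= 8L]          # downstream, non-degenerate
    len <- len[len >= 8L]
    if (!length(starts)) { reason[i] <- "no_npxxy"; next }
    ok <- len >= min_core & len <= max_core
    if (any(ok)) {
      np_start[i] <- max(starts[ok])
      status[i] <- "accepted"
    } else {
      np_start[i] <- max(starts)
      reason[i] <- if (max(len) < min_core) "too_short" else "too_long"
    }
  }
  core_end <- np_start + 4L
  core_length <- ifelse(is.na(np_start), NA_integer_, core_end - seq_start + 1L)
  core <- rep(NA_character_, n)
  has <- !is.na(np_start)
  core[has] <- substr(residues[has], seq_start[has], core_end[has])
  out <- data.frame(
    id = id,
    family = family,
    status = status,
    reject_reason = reason,
    sequon_start = seq_start,
    sequon = ifelse(is.na(seq_start), NA_character_,
                    substr(residues, seq_start, seq_start + 2L)),
    npxxy_start = np_start,
    npxxy = ifelse(is.na(np_start), NA_character_,
                   substr(residues, np_start, np_start + 4L)),
    core_length = as.integer(core_length),
    core = core,
    has_ambiguity = !is.na(core) & grepl("[XBZUJO]", core),
    stringsAsFactors = FALSE
  )
  class(out) <- c("core_regions", class(out))
  out
}

#' Extract the core region of a single sequence
#'
#' Combines [find_sequon()] and [find_npxxy()] and applies the length filter.
#' A sequence is accepted iff both anchors are found and the inclusive
#' sequon-to-NPxxY length is within `[min_core, max_core]`. All failures are
#' encoded in `reject_reason` (`no_sequon`, `no_npxxy`, `too_short`,
#' `too_long`), never raised as errors. Cores containing ambiguity letters are
#' accepted but flagged (`has_ambiguity`); composition counting later excludes
#' those positions.
#'
#' @param residues A single residue string.
#' @param id Identifier carried into the result (default "seq").
#' @param family Family label (default `NA`).
#' @param alphabet,strict_x Sequon options, see [find_sequon()].
#' @param min_core,max_core Inclusive core-length bounds (defaults 270, 401).
#' @return One-row `core_regions` data.frame with anchor coordinates
#'   (1-based), the core sub-sequence, its length, and accept/reject status.
#' @export
extract_core <- function(residues, id = "seq", family = NA_character_,
                         alphabet = c("stc", "st"), strict_x = FALSE,
                         min_core = 270L, max_core = 401L) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(residues) == 1L)
  core_scan(id, family, normalize_residues(residues), alphabet, strict_x,
            min_core, max_core)
}

#' Filter a family to accepted core regions
#'
#' Applies [extract_core()] to every record and tallies an accept/reject
#' report. The report satisfies `n_input = n_accepted + n_rejected` and the
#' per-reason breakdown sums to `n_rejected`.
#'
#' @param fs A [family_set()].
#' @param alphabet,strict_x,min_core,max_core See [extract_core()].
#' @return A list with `cores` (a `core_regions` data.frame, one row per
#'   input record, order preserved) and `report` (one-row data.frame with
#'   columns `family`, `n_input`, `n_accepted`, `n_rejected` and one count per
#'   reject reason).
#' @export
filter_family <- function(fs, alphabet = c("stc", "st"), strict_x = FALSE,
                          min_core = 270L, max_core = 401L) {
  alphabet <- match.arg(alphabet)
  fam <- if (nrow(fs)) fs$family[1] else NA_character_
  if (!nrow(fs)) {
    warning("empty family set")
    cores <- core_scan(character(), character(), character(), alphabet,
                       strict_x, min_core, max_core)
  } else {
    cores <- core_scan(fs$id, fs$family, fs$residues, alphabet, strict_x,
                       min_core, max_core)
  }
  tallies <- vapply(core_reject_reasons(),
                    function(r) sum(cores$reject_reason == r), integer(1))
  report <- data.frame(
    family = fam,
    n_input = nrow(cores),
    n_accepted = sum(cores$status == "accepted"),
    n_rejected = sum(cores$status == "rejected"),
    stringsAsFactors = FALSE
  )
  report <- cbind(report, as.data.frame(as.list(tallies)))
  list(cores = cores, report = report)
}

#' Keep only accepted cores
#'
#' @param cores A `core_regions` data.frame.
#' @return The accepted rows.
#' @export
accepted_cores <- function(cores) {
  cores[cores$status == "accepted", , drop = FALSE]
}
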