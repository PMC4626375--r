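# Sequence and table I/O: FASTA readers, family manifests, result tables.

#' Construct a family set
#'
#' A family set is the unit of input to the pipeline: an ordered collection of
#' named protein sequences sharing one family label (e.g. \code{"or"},
#' \code{"amine"}). Residue strings are normalized on construction: whitespace
#' and digits are stripped and letters upper-cased. Letters outside the 20
#' standard codes plus the ambiguity codes (X, B, Z, U, J, O) are rejected.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings (parallel to `id`).
#' @param family Single family label.
#' @param description Optional per-sequence free text (defaults to "").
#' @param provenance Free-text origin note (file path, filter version).
#' @return A `family_set`: a data.frame with columns `id`, `family`,
#'   `residues`, `description` and attribute `provenance`.
#' @export
family_set <- function(id, residues, family, description = "", provenance = "") {
  id <- as.character(id)
  residues <- normalize_residues(as.character(residues))
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(id) && any(!nzchar(residues))) {
    stop("empty sequence for entry: ", paste(id[!nzchar(residues)], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", paste(c(aa_alphabet(), aa_ambiguous()), collapse = "")),
               residues)
  if (any(bad)) {
    stop("non-amino-acid letters in entry: ", paste(id[bad], collapse = ", "))
  }
  out <- data.frame(
    id = id,
    family = rep_len(as.character(family), length(id)),
    residues = residues,
    description = rep_len(as.character(description), length(id)),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("family_set", class(out))
  out
}

normalize_residues <- function(x) {
  toupper(gsub("[[:space:][:digit:]]", "", x))
}

#' Read one family's sequences from a FASTA file
#'
#' Everything after ">" up to the first whitespace is the id; the remainder of
#' the header line is kept as the description. The family label always comes
#' from the caller (or the manifest), never from the headers, because database
#' header dialects vary.
#'
#' @param path FASTA file path.
#' @param family Family label to attach to every record.
#' @return A [family_set()]. An empty or header-free file yields an empty set
#'   with a warning.
#' @export
read_family_fasta <- function(path, family) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (!length(headers)) {
    warning("no FASTA entries in ", path)
    return(family_set(character(), character(), family, provenance = path))
  }
  if (headers[1] != 1 && any(nzchar(trimws(lines[seq_len(headers[1] - 1)])))) {
    stop("malformed FASTA (sequence before first header) in ", path)
  }
  starts <- headers + 1
  ends <- c(headers[-1] - 1, length(lines))
  seqs <- vapply(seq_along(headers), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  hdr <- sub("^>", "", lines[headers])
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(gsub("[[:space:]]", "", seqs)))) {
    stop("malformed FASTA (entry with empty sequence): ",
         paste(ids[!nzchar(gsub("[[:space:]]", "", seqs))], collapse = ", "))
  }
  family_set(ids, seqs, family, description = desc, provenance = path)
}

#' Read a family manifest
#'
#' Plain-text mapping of family label to FASTA path: one
#' `label<TAB-or-spaces>path` pair per line; blank lines and `#` comments are
#' ignored. Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return Named character vector (names = family labels, values = FASTA paths).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("[[:space:]]+", lines), invert = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed manifest line: ", lines[lengths(parts) != 2][1])
  fam <- vapply(parts, `[`, "", 1)
  fp <- vapply(parts, `[`, "", 2)
  abs <- grepl("^(/|[A-Za-z]:)", fp)
  fp[!abs] <- file.path(dirname(path), fp[!abs])
  stats::setNames(fp, fam)
}

#' Write a family set or core set to FASTA
#'
#' @param x A [family_set()] or the `cores` data.frame from [filter_family()]
#'   (accepted cores only are written in that case).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "core_regions")) {
    x <- x[x$status == "accepted", , drop = FALSE]
    seqs <- Biostrings::AAStringSet(x$core)
  } else {
    seqs <- Biostrings::AAStringSet(x$residues)
  }
  names(seqs) <- x$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a result table to TSV or JSON
#'
#' Output is byte-stable for identical input: column order is preserved and
#' numeric values are serialized at 6 significant digits. A named atomic
#' vector (e.g. a 20-residue profile) becomes a two-column TSV or a keyed JSON
#' object.
#'
#' @param rows A data.frame or named atomic vector.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(rows)) stop("rows must be non-null")
  if (is.atomic(rows) && !is.null(names(rows))) {
    if (format == "json") {
      jsonlite::write_json(as.list(signif6(rows)), path, auto_unbox = TRUE, pretty = TRUE)
      return(invisible(path))
    }
    rows <- data.frame(key = names(rows), value = unname(rows), stringsAsFactors = FALSE)
  }
  rows <- as.data.frame(rows)
  if (format == "tsv") {
    num <- vapply(rows, is.double, logical(1))
    rows[num] <- lapply(rows[num], function(v) formatC(v, digits = 6, format = "g"))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rows[] <- lapply(rows, signif6)
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

signif6 <- function(v) if (is.double(v)) signif(v, 6) else v
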