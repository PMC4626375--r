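# Anchored positional residue-distribution profiles.
#
# Curves are anchored at the NPxxY motif because family members share their
# C-terminal topology while N-terminal lengths vary: offset 0 is the Y of
# NPxxY and negative offsets count residues upstream within the core.

#' Positional distribution of a residue across a family's cores
#'
#' For each offset from 0 (the Y of NPxxY) down to -(longest core - 1),
#' computes how often the residue occurs at that offset across the family's
#' accepted cores. The default normalization divides by per-offset coverage
#' (the number of cores long enough to reach that offset), so upstream
#' frequencies are not deflated by shorter family members;
#' `normalize = "family_size"` divides by the family size instead.
#'
#' @param cores A `core_regions` data.frame (accepted rows are used) or a
#'   character vector of core sequences.
#' @param residue Single standard one-letter code.
#' @param normalize `"coverage"` (default) or `"family_size"`.
#' @return A `positional_profile`: data.frame with `family`, `residue`,
#'   `offset` (ascending, most negative first), `count`, `coverage`,
#'   `frequency`.
#' @export
positional_distribution <- function(cores, residue,
                                    normalize = c("coverage", "family_size")) {
  normalize <- match.arg(normalize)
  stopifnot(nchar(residue) == 1L, residue %in% aa_alphabet())
  family <- NA_character_
  if (inherits(cores, "core_regions")) {
    cores <- accepted_cores(cores)
    if (nrow(cores)) family <- cores$family[1]
    seqs <- cores$core
  } else {
    seqs <- as.character(cores)
  }
  if (!length(seqs)) stop("empty input: no accepted cores")
  lens <- nchar(seqs)
  max_len <- max(lens)
  hits <- gregexpr(residue, seqs, fixed = TRUE)
  # distance from the C-terminal anchor: last residue has offset 0
  from_end <- unlist(lapply(seq_along(seqs), function(i) {
    m <- hits[[i]]
    if (m[1] < 0) integer(0) else lens[i] - as.integer(m) + 1L
  }), use.names = FALSE)
  count <- tabulate(from_end, nbins = max_len)
  coverage <- rev(cumsum(rev(tabulate(lens, nbins = max_len))))
  denom <- if (normalize == "coverage") coverage else rep(length(seqs), max_len)
  out <- data.frame(
    family = family,
    residue = residue,
    offset = -(seq_len(max_len) - 1L),
    count = count,
    coverage = coverage,
    frequency = ifelse(denom > 0, count / denom, 0),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sequences") <- length(seqs)
  class(out) <- c("positional_profile", class(out))
  out
}

#' Call peaks in a positional profile
#'
#' Reports local maxima with frequency at least `min_height` and coverage at
#' least `min_coverage`; runs of adjacent qualifying offsets are collapsed to
#' their highest point. Defaults: height 0.5 and coverage half the family
#' size, so a peak must be present in most sequences that reach it and must
#' be supported by most of the family.
#'
#' @param profile A `positional_profile`.
#' @param min_height Minimum frequency (0-1), default 0.5.
#' @param min_coverage Minimum coverage count; default half the maximum
#'   coverage of the profile.
#' @return data.frame with `offset` and `frequency`, sorted by offset; zero
#'   rows when nothing qualifies.
#' @export
profile_peaks <- function(profile, min_height = 0.5, min_coverage = NULL) {
  if (is.null(min_coverage)) min_coverage <- max(profile$coverage) / 2
  keep <- profile$frequency >= min_height & profile$coverage >= min_coverage
  hits <- profile[keep, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(offset = integer(0), frequency = numeric(0)))
  }
  hits <- hits[order(hits$offset), , drop = FALSE]
  run <- cumsum(c(1L, diff(hits$offset) != 1L))
  peaks <- do.call(rbind, lapply(split(hits, run), function(h) {
    h[which.max(h$frequency), c("offset", "frequency")]
  }))
  peaks <- peaks[order(peaks$offset), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}
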