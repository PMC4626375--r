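test_that("column statistics recover hand counts on a fabricated alignment", {
  aln <- c("MN-AGG",
           "MNQAGG",
           "MNQCGA",
           "MNQAG-")
  cs <- column_stats(aln)
  expect_equal(nrow(cs), 6)
  expect_equal(cs$majority[1:2], c("M", "N"))
  expect_equal(cs$majority_freq, c(1, 1, 1, 0.75, 1, 2 / 3))
  expect_equal(cs$gap_fraction, c(0, 0, 0.25, 0, 0, 0.25))
  freqs <- attr(cs, "frequencies")
  expect_equal(dim(freqs), c(20, 6))
  expect_equal(unname(freqs["A", 4]), 0.75)
  expect_equal(unname(freqs["C", 4]), 0.25)
  # non-gap frequencies sum to 1 in every column
  expect_equal(unname(colSums(freqs)), rep(1, 6))
})

test_that("information content spans 0 to log2(20) and decreases toward uniform", {
  expect_equal(column_stats(c("N", "N", "N", "N"))$ic, log2(20))
  uniform <- vapply(aa_alphabet(), identity, character(1))
  expect_equal(column_stats(uniform)$ic, 0, tolerance = 1e-12)
  # nested fixtures: progressively flatter columns lose information
  cols <- list(rep("L", 8), c(rep("L", 6), "I", "V"),
               c(rep("L", 4), "I", "I", "V", "V"),
               c("L", "L", "I", "I", "V", "V", "F", "F"))
  ics <- vapply(cols, function(col) column_stats(col)$ic, numeric(1))
  expect_true(all(diff(ics) < 0))
  expect_true(all(ics >= 0 & ics <= log2(20)))
})

test_that("ragged alignments are rejected with the offending row named", {
  expect_error(column_stats(c("MNQA", "MNQ")), "row 2")
})

test_that("clustal and aligned-FASTA input give identical statistics", {
  rows <- c("MNQA-G", "MNQAGG", "MN-AGG")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", rows[1], ">s2", rows[2], ">s3", rows[3]), fa)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               paste("s1", rows[1]), paste("s2", rows[2]), paste("s3", rows[3])),
             cl)
  expect_equal(column_stats(fa), column_stats(cl))
  expect_equal(column_stats(fa), column_stats(rows))
})

test_that("conserved_columns thresholds behave at the extremes", {
  unanimous <- c(strrep("A", 10), strrep("A", 10))
  stats_u <- column_stats(unanimous)
  expect_equal(conserved_columns(stats_u, threshold = 0.5), 1:10)
  mixed <- c("AAAA", "AAAC", "ACCC")
  sm <- column_stats(mixed)
  expect_equal(conserved_columns(sm, threshold = 0), 1:4)
  expect_equal(conserved_columns(sm, threshold = 1), integer(0))
  expect_equal(conserved_columns(sm, threshold = 0.9), 1L)
  # uniform columns fall below any majority threshold > 1/20
  expect_equal(conserved_columns(column_stats(vapply(aa_alphabet(), identity,
                                                     character(1))), 0.5),
               integer(0))
  # gappy columns are excluded from the call
  gappy <- c("A---", "A--C", "ACCC")
  expect_equal(conserved_columns(column_stats(gappy), 0.5), c(1L, 4L))
})

test_that("global identity is 100 for self, symmetric, and oracle-optimal", {
  s <- "MNQSTLLVFHE"
  self <- global_align_identity(s, s)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$identities, nchar(s))

  set.seed(31)
  for (i in 1:12) {
    a <- random_seq(sample(3:8, 1))
    b <- random_seq(sample(3:8, 1))
    ab <- global_align_identity(a, b)
    ba <- global_align_identity(b, a)
    expect_equal(ab$identities, ba$identities)
    expect_equal(ab$percent_identity, ba$percent_identity)
    # score equals the exhaustive-search optimum under the same model
    expect_equal(ab$score, oracle_align_score(a, b))
  }
  expect_error(global_align_identity("", "MNQS"), "empty")
})

test_that("terminal-gap exclusion shortens the identity denominator", {
  full <- global_align_identity("AAMNQSTLLVF", "MNQSTLLVF")
  trimmed <- global_align_identity("AAMNQSTLLVF", "MNQSTLLVF",
                                   denominator = "no_terminal_gaps")
  expect_equal(full$identities, trimmed$identities)
  expect_true(trimmed$aligned_length < full$aligned_length)
  expect_equal(trimmed$percent_identity, 100)
})

test_that("motif_map locates exact, wildcard and fuzzy motifs", {
  m71_like <- paste0("MAW", "LHTPMY", strrep("A", 10), "MAYDRYVAIC",
                     strrep("G", 5), "PMLNPLIY")
  hits <- motif_map(m71_like, c("MAYDRYVAIC", "NPxxY", "QQQQ"))
  expect_equal(hits$start[hits$pattern == "MAYDRYVAIC"], 20)
  expect_equal(hits$matched_text[hits$pattern == "NPxxY"], "NPLIY")
  expect_false("QQQQ" %in% hits$pattern)
  expect_equal(nrow(motif_map("AAAA", "MAYDRYVAIC")), 0)

  # fuzzy matching flags single-mismatch hits
  fz <- motif_map("MAYDRFVAIC", "MAYDRYVAIC", max_mismatch = 1)
  expect_equal(fz$mismatches, 1L)

  # positions equal a brute-force substring scan on random sequences
  set.seed(41)
  for (i in 1:10) {
    s <- random_seq(200)
    got <- motif_map(s, "NPxxY")$start
    expect_equal(got, oracle_npxxy(s))
  }
})
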