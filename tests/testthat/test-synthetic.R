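test_that("fixed-length specs generate families the filter fully accepts", {
  spec <- family_spec("f", 10, core_length = 286, seed = 1)
  fs <- generate_family(spec)
  expect_equal(nrow(fs), 10)
  out <- filter_family(fs)
  expect_equal(out$report$n_accepted, 10)
  expect_true(all(accepted_cores(out$cores)$core_length == 286))
})

test_that("generation is bit-reproducible and prefix-stable in n", {
  spec <- family_spec("f", 15, seed = 99)
  a <- generate_family(spec)
  b <- generate_family(spec)
  expect_identical(a$residues, b$residues)
  # growing the family never reshuffles earlier sequences
  big <- generate_family(family_spec("f", 30, seed = 99))
  expect_identical(big$residues[1:15], a$residues)
  # different seeds give different sequences
  other <- generate_family(family_spec("f", 15, seed = 100))
  expect_false(identical(other$residues, a$residues))
})

test_that("acceptance rate is 1 inside the length window and 0 outside", {
  inside <- generate_family(family_spec("in", 40,
                                        core_length = list(range = c(270, 401)),
                                        seed = 2))
  expect_equal(filter_family(inside)$report$n_accepted, 40)
  tiny <- generate_family(family_spec("lo", 40,
                                      core_length = list(range = c(100, 200)),
                                      seed = 3))
  rep_lo <- filter_family(tiny)$report
  expect_equal(rep_lo$n_accepted, 0)
  expect_equal(rep_lo$too_short, 40)
  huge <- generate_family(family_spec("hi", 25,
                                      core_length = list(range = c(430, 500)),
                                      seed = 4))
  rep_hi <- filter_family(huge)$report
  expect_equal(rep_hi$n_accepted, 0)
  expect_equal(rep_hi$too_long, 25)
})

test_that("built-in compositions are proper probability vectors", {
  for (comp in list(amine_like_base(), or_like_composition(),
                    taar_like_composition())) {
    expect_equal(sum(comp), 1, tolerance = 1e-12)
    expect_named(comp, aa_alphabet())
    expect_true(all(comp >= 0))
  }
  expect_true(all(amine_like_base() > 0))
  # the stand-in constructions encode their target summary statistics exactly
  pos <- function(p) sum(p[c("I", "V", "L", "F", "C", "M", "A")])
  base <- amine_like_base()
  expect_equal(100 * (pos(or_like_composition()) - pos(base)), 4, tolerance = 1e-9)
  expect_equal(100 * (pos(taar_like_composition()) - pos(base)), 2, tolerance = 1e-9)
  expect_equal(or_like_composition()[["H"]] / base[["H"]], 1.6, tolerance = 1e-9)
})

test_that("profiling a large sample recovers the spec composition", {
  fs <- generate_family(family_spec("f", 2000, core_length = 286, seed = 21))
  p <- composition_profile(filter_family(fs)$cores)
  got <- stats::setNames(p$percent, p$residue)
  want <- expected_core_composition(amine_like_base(), 286)
  expect_true(all(abs(got - want) < 0.5))
  # the anchor contribution itself is small: every entry is within 0.8 points
  # of the raw base composition
  expect_true(all(abs(got - 100 * amine_like_base()) < 0.8))
})

test_that("multinomial convergence: error shrinks with sample size", {
  err <- vapply(c(100, 10000), function(n) {
    fs <- generate_family(family_spec("f", n, core_length = 286, seed = 22,
                                      nt_flank = c(0, 0), ct_flank = c(0, 0)))
    p <- composition_profile(fs$residues)
    max(abs(stats::setNames(p$percent, p$residue) -
              expected_core_composition(amine_like_base(), 286)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("positional inserts are planted deterministically and validated", {
  spec <- family_spec("f", 25, core_length = 286,
                      positional_inserts = list(list(motif = "CSSH", offset = -60L)),
                      seed = 23)
  cores <- filter_family(generate_family(spec))$cores
  prof <- positional_distribution(cores, "H")
  expect_equal(prof$frequency[prof$offset == -57], 1)  # H is the motif's 4th residue
  expect_error(family_spec("f", 5, core_length = 286,
                           positional_inserts = list(list(motif = "W", offset = -2L))),
               "does not fit")
  expect_error(family_spec("f", 5, core_length = list(range = c(270, 401)),
                           positional_inserts = list(list(motif = "W", offset = -280L))),
               "does not fit")
})

test_that("plant_no_trp leaves a single delta peak and ~1/L tryptophan", {
  spec <- plant_no_trp(family_spec("f", 300, core_length = 286, seed = 24))
  cores <- filter_family(generate_family(spec))$cores
  prof <- positional_distribution(cores, "W")
  pk <- profile_peaks(prof, min_height = 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$offset, -140)
  expect_equal(pk$frequency, 1)
  p <- composition_profile(cores)
  expect_equal(p$percent[p$residue == "W"], 100 / 286, tolerance = 0.15)
  expect_equal(sum(spec$composition), 1, tolerance = 1e-12)
  expect_equal(spec$composition[["W"]], 0)
})

test_that("enrichment renormalizes the sampling composition", {
  spec <- family_spec("f", 5, enrichments = c(H = 1.6), seed = 25)
  base <- amine_like_base()
  expect_equal(sum(spec$composition), 1, tolerance = 1e-12)
  expect_equal(spec$composition[["H"]] / base[["H"]],
               1.6 / sum(base * ifelse(names(base) == "H", 1.6, 1)),
               tolerance = 1e-9)
})
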