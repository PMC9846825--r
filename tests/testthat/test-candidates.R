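test_that("adduct candidates are generated per eligible site at matching mass", {
  # (674.3711 + 136.0289 + 2 protons) / 2
  cands <- enumerate_adduct_candidates("STKSPR", "K", precursor_mz = 406.2073,
                                       charge = 2, tol_ppm = 10,
                                       fixed_mods = list())
  expect_length(cands, 1)
  expect_equal(cands[[1]]$site, 3)
  expect_equal(cands[[1]]$peptide$residues[3], "K")
  expect_lt(abs(cands[[1]]$ppm_error), 10)
  # no glutamate in STKSPR
  expect_length(enumerate_adduct_candidates("STKSPR", "E",
                                            precursor_mz = 406.2073,
                                            charge = 2, tol_ppm = 10,
                                            fixed_mods = list()), 0)
  expect_error(enumerate_adduct_candidates("STKSPR", character(0),
                                           precursor_mz = 1, charge = 1),
               "nonempty")
})

test_that("adduct enumeration handles variable oxidation variants", {
  # Dep-E tubulin peptide with oxidized M11: MH3+ = 828.0189
  cands <- enumerate_adduct_candidates(
    fig2_sequence, c("E", "D", "K", "Y", "S", "T", "H", "R"),
    precursor_mz = 828.019, charge = 3, tol_ppm = 10,
    fixed_mods = list(), variable_mods = list(mod_oxidation()))
  expect_gt(length(cands), 1)  # one candidate per eligible residue
  sites <- vapply(cands, function(x) x$site, integer(1))
  expect_true(9 %in% sites)
  # every candidate carries the oxidation (plain variant misses by ~16 Da)
  for (x in cands) {
    expect_true(any(vapply(x$base$mods, function(m) m$mod$name, character(1))
                    == "Oxidation"))
  }
})

test_that("every candidate re-verifies its precursor within tolerance", {
  pool <- benchmark_pool
  for (x in enumerate_adduct_candidates(pool, c("K", "Y", "E"),
                                        precursor_mz = 406.2073, charge = 2,
                                        tol_ppm = 20, fixed_mods = list())) {
    theo <- mz_from_mass(peptide_mass(x$peptide), 2)
    expect_lt(abs(theo - 406.2073) / 406.2073 * 1e6, 20)
  }
})

test_that("widening the tolerance never removes candidates", {
  pool <- benchmark_pool
  counts <- vapply(c(1, 5, 10, 50, 200, 1000), function(tol) {
    length(enumerate_adduct_candidates(pool, c("K", "Y", "E"),
                                       precursor_mz = 406.21, charge = 2,
                                       tol_ppm = tol, fixed_mods = list()))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  xcounts <- vapply(c(1, 10, 100, 1000), function(tol) {
    length(enumerate_crosslink_candidates(pool, builtin_bridges()$EK_isopeptide,
                                          precursor_mz = 827.06, charge = 3,
                                          tol_ppm = tol, fixed_mods = list()))
  }, numeric(1))
  expect_true(all(diff(xcounts) >= 0))
})

test_that("cross-link enumeration finds the tubulin x MAP2 pair", {
  pool <- c("TIGGGDDSFNTFFSETGA", "STKSPR", "LVPYPR", "GHYTIGK")
  xls <- enumerate_crosslink_candidates(pool, builtin_bridges()$EK_isopeptide,
                                        precursor_mz = 827.0506, charge = 3,
                                        tol_ppm = 10, fixed_mods = list())
  expect_length(xls, 1)
  x <- xls[[1]]
  seqs <- c(x$peptide_a$sequence, x$peptide_b$sequence)
  sites <- c(x$site_a, x$site_b)
  expect_setequal(seqs, c("TIGGGDDSFNTFFSETGA", "STKSPR"))
  expect_equal(sites[seqs == "TIGGGDDSFNTFFSETGA"], 15)  # E15
  expect_equal(sites[seqs == "STKSPR"], 3)               # K3
  # lexicographic normalization puts the smaller sequence first
  expect_true(x$peptide_a$sequence <= x$peptide_b$sequence)
  # nothing at a non-matching precursor under a tight tolerance
  expect_length(enumerate_crosslink_candidates(pool,
                                               builtin_bridges()$EK_isopeptide,
                                               precursor_mz = 500.0, charge = 3,
                                               tol_ppm = 0.1,
                                               fixed_mods = list()), 0)
})

test_that("a peptide can cross-link with itself under a custom bridge", {
  gg <- bridge_definition("GG_loss_water", "G", "G", formula = "H-2 O-1")
  # 2 x 132.0535 - 18.0106 + proton = 247.1037
  xls <- enumerate_crosslink_candidates(c("GG", "GG"), gg,
                                        precursor_mz = 247.1037, charge = 1,
                                        tol_ppm = 10, fixed_mods = list())
  expect_gte(length(xls), 1)
  expect_equal(crosslink_precursor_mz(xls[[1]], 1), 247.1037, tolerance = 1e-4)
})

test_that("candidates are de-duplicated after pair normalization", {
  pool <- c("TIGGGDDSFNTFFSETGA", "STKSPR", "STKSPR")
  xls <- enumerate_crosslink_candidates(pool, builtin_bridges()$EK_isopeptide,
                                        precursor_mz = 827.0506, charge = 3,
                                        tol_ppm = 10, fixed_mods = list())
  keys <- vapply(xls, function(x) {
    paste(x$peptide_a$sequence, x$site_a, x$peptide_b$sequence, x$site_b)
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
})
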