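cfg <- run_config()

test_that("verdict decision is a pure function of the criteria", {
  expect_equal(verdict_decision(c(a = TRUE, b = TRUE)), "accept")
  expect_equal(verdict_decision(c(a = TRUE, b = FALSE)), "reject")
  expect_equal(verdict_decision(c(a = TRUE, b = NA)), "accept")
  expect_equal(verdict_decision(logical(0)), "reject")
})

test_that("adduct validation accepts the true site and rejects competitors", {
  s <- simulate_spectrum(fig2_peptide(), zero_noise(2), 1)
  base <- modified_peptide(fig2_sequence,
                           mods = list(list(pos = 11, mod = mod_oxidation())))
  v9 <- evaluate_adduct(s, adduct_candidate(base, 9), cfg)
  expect_equal(v9$decision, "accept")
  expect_equal(v9$localized_site, 9)
  # same spectrum against a Dep placement on E12: contradicted by the
  # unshifted y series
  v12 <- evaluate_adduct(s, adduct_candidate(base, 12), cfg)
  expect_equal(v12$decision, "reject")
  # correct precursor but no fragment peaks
  s0 <- spectrum("bare", s$precursor_mz, 3, numeric(0), numeric(0))
  expect_equal(evaluate_adduct(s0, adduct_candidate(base, 9), cfg)$decision,
               "reject")
})

test_that("signature ions corroborate lysine adducts when present", {
  mp <- modified_peptide("STKSPR", mods = list(list(pos = 3, mod = mod_dep())))
  s <- simulate_spectrum(mp, zero_noise(4), 1)
  cand <- adduct_candidate(modified_peptide("STKSPR"), 3)
  v <- evaluate_adduct(s, cand, cfg)
  expect_equal(v$decision, "accept")
  expect_gt(v$n_signature_matches, 0)
  # with the signature requirement on, a spectrum lacking them is rejected
  strict <- run_config(require_signature = TRUE)
  ions <- linear_fragment_ions(mp, charges = c(1, 2))
  s2 <- spectrum("nosig", mz_from_mass(peptide_mass(mp), 2), 2, ions$mz,
                 rep(10, nrow(ions)))
  expect_equal(evaluate_adduct(s2, cand, strict)$decision, "reject")
  expect_equal(evaluate_adduct(s, cand, strict)$decision, "accept")
})

test_that("a clean cross-link spectrum passes all five criteria", {
  x <- fig4_pair()
  s <- simulate_spectrum(x, zero_noise(11), 1)
  v <- evaluate_crosslink(s, x, alt_pool = character(), config = cfg)
  expect_equal(v$decision, "accept")
  expect_gt(v$assigned_fraction, 0.4)
  expect_gte(v$xl_specific_series_count, 2)
  expect_true(v$criteria$both_peptides_supported)
  expect_true(v$criteria$fp_screen_passed)
  expect_true(v$criteria$parent_mass_ok)
})

test_that("a 5 Da precursor offset fails the parent-mass check", {
  x <- fig4_pair()
  s <- simulate_spectrum(x, zero_noise(11), 1)
  s$precursor_mz <- s$precursor_mz + 5 / 3
  v <- evaluate_crosslink(s, x, alt_pool = character(), config = cfg)
  expect_false(v$criteria$parent_mass_ok)
  expect_equal(v$decision, "reject")
})

test_that("confounded spectra are rejected as false positives", {
  x <- fig4_pair()
  s <- simulate_confounded_spectrum(x, "DSLSQQLNS", zero_noise(13), 1)
  v <- evaluate_crosslink(s, x, alt_pool = c(benchmark_pool, "DSLSQQLNS"),
                          config = cfg)
  expect_equal(v$decision, "reject")
})

test_that("the false-positive screen spots an alternative linear explanation", {
  alt <- "DSLSQQLNS"
  ions <- linear_fragment_ions(alt, charges = 1)
  flagged <- subset(ions, series == "y" & index %in% 2:6)$mz
  expect_false(false_positive_screen(flagged, c("STKSPR", alt)))
  # an empty pool cannot explain anything away
  expect_true(false_positive_screen(flagged, character(0)))
  # peaks far from every theoretical ion survive the screen
  expect_true(false_positive_screen(c(401.1711, 733.0199, 1111.4242),
                                    c("STKSPR", alt)))
  # explaining only part of the flagged peaks is not enough
  expect_true(false_positive_screen(c(flagged, 1111.4242), c(alt)))
})

test_that("competing site placements are resolved by peak explanation", {
  # AFVHWYVGEGMEEGEFSEAR has five E residues; a clean spectrum of the
  # E15-K pair must win over the other placements
  b <- builtin_bridges()$EK_isopeptide
  x_true <- crosslink_candidate(fig2_sequence, 13, "STKSPR", 3, b)
  s <- simulate_spectrum(x_true, zero_noise(21), 1)
  cands <- lapply(c(9, 12, 13, 15, 18), function(site) {
    crosslink_candidate(fig2_sequence, site, "STKSPR", 3, b)
  })
  verdicts <- lapply(cands, evaluate_crosslink, s = s,
                     alt_pool = character(), config = cfg)
  accepted <- vapply(verdicts, function(v) v$decision == "accept", logical(1))
  keep <- deplink:::.crosslink_site_winners(cands[accepted],
                                            verdicts[accepted])
  winners <- cands[accepted][keep]
  expect_length(winners, 1)
  expect_equal(winners[[1]]$site_a, 13)
})
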