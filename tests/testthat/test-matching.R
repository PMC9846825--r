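test_that("exact peaks are matched with zero error, one-to-one", {
  ions <- linear_fragment_ions("STKSPR", charges = 1)
  y <- subset(ions, series == "y" & index <= 5)
  s <- spectrum("t", 338.19, 2, y$mz, rep(100, 5))
  a <- match_peaks(s, ions, tol_da = 0.02)
  expect_equal(nrow(a), 5)
  expect_true(all(abs(a$error_da) < 1e-9))
  expect_false(anyDuplicated(a$peak_index) > 0)
  # empty spectrum -> no assignments
  s0 <- spectrum("e", 338.19, 2, numeric(0), numeric(0))
  expect_equal(nrow(match_peaks(s0, ions, 0.02)), 0)
})

test_that("small mass errors are tolerated and reported", {
  ions <- linear_fragment_ions(fig2_peptide(), charges = 1)
  b10 <- subset(ions, series == "b" & index == 10)$mz
  s <- spectrum("t", 828.02, 3, b10 + 0.005, 50)
  a <- match_peaks(s, ions, tol_da = 0.02)
  expect_equal(nrow(a), 1)
  expect_equal(a$error_da, 0.005, tolerance = 1e-6)
  expect_equal(nrow(match_peaks(s, ions, tol_da = 0.004)), 0)
})

test_that("ties go to the smallest absolute error", {
  ions <- data.frame(series = "b", index = 1, charge = 1, mz = 500,
                     carries_bridge = FALSE, peptide = "sole")
  s <- spectrum("t", 500, 1, c(499.995, 500.001), c(1, 1))
  a <- match_peaks(s, ions, tol_da = 0.02)
  expect_equal(nrow(a), 1)
  expect_equal(s$peaks$mz[a$peak_index], 500.001)
})

test_that("unsorted peak lists are rejected", {
  s <- structure(list(id = "bad", precursor_mz = 500, precursor_charge = 2,
                      peaks = data.frame(mz = c(300, 200), intensity = c(1, 1))),
                 class = "spectrum")
  expect_error(match_peaks(s, data.frame(mz = 250), 0.02), "sorted")
})

test_that("assigned fraction counts the most intense peaks", {
  s <- spectrum("t", 500, 2, mz = 100 + 1:8 * 10, intensity = 8:1)
  all_assigned <- data.frame(peak_index = 1:8)
  expect_equal(assigned_fraction(s, all_assigned, top_n = 8), 1.0)
  expect_equal(assigned_fraction(s, all_assigned[0, , drop = FALSE], 8), 0.0)
  expect_equal(assigned_fraction(s, data.frame(peak_index = 1:5), 8), 0.625)
  # top_n smaller than the peak count uses only the most intense
  expect_equal(assigned_fraction(s, data.frame(peak_index = 1:2), top_n = 2), 1.0)
})

test_that("assigned fraction is monotone in the fragment tolerance", {
  p <- zero_noise(5); p$jitter_ppm <- 25; p$n_noise <- 10
  s <- simulate_spectrum(fig2_peptide(), p, 1)
  ions <- linear_fragment_ions(fig2_peptide(), charges = c(1, 2))
  fr <- vapply(c(0.001, 0.005, 0.02, 0.1), function(tol) {
    assigned_fraction(s, match_peaks(s, ions, tol), 50)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("fragment ions localize the adduct to the reported glutamate", {
  s <- simulate_spectrum(fig2_peptide(), zero_noise(2), 1)
  base <- modified_peptide(fig2_sequence,
                           mods = list(list(pos = 11, mod = mod_oxidation())))
  sites <- which(base$residues %in% c("E", "D", "K", "Y", "S", "T", "H", "R"))
  loc <- localize_adduct(s, base, sites)
  expect_equal(loc$status, "localized")
  expect_equal(loc$site, 9)
})

test_that("unshifted ions alone leave the site ambiguous", {
  # peaks: only y1..y9 of the unmodified tail -> no shifted evidence
  base <- modified_peptide(fig2_sequence,
                           mods = list(list(pos = 11, mod = mod_oxidation())))
  dep <- modified_peptide(fig2_sequence,
                          mods = list(list(pos = 9, mod = mod_dep()),
                                      list(pos = 11, mod = mod_oxidation())))
  ions <- linear_fragment_ions(dep, charges = 1)
  ymz <- subset(ions, series == "y" & index <= 8)$mz
  s <- spectrum("t", mz_from_mass(peptide_mass(dep), 3), 3, ymz,
                rep(10, length(ymz)))
  loc <- localize_adduct(s, base, c(9, 12, 13, 15, 18))
  expect_equal(loc$status, "ambiguous")
  expect_true(is.na(loc$site))
})

test_that("one shifted and one unshifted ion suffice to bracket a site", {
  # AEKEA with Dep on E2: shifted b2, unshifted y3
  dep2 <- modified_peptide("AEKEA", mods = list(list(pos = 2, mod = mod_dep())))
  ions <- linear_fragment_ions(dep2, charges = 1)
  peaks <- c(subset(ions, series == "b" & index == 2)$mz,
             subset(ions, series == "y" & index == 3)$mz)
  s <- spectrum("t", mz_from_mass(peptide_mass(dep2), 2), 2, peaks, c(5, 5))
  loc <- localize_adduct(s, "AEKEA", c(2, 4))
  expect_equal(loc$status, "localized")
  expect_equal(loc$site, 2)
})

test_that("localization recovers every planted site on clean simulations", {
  withr::local_seed(17)
  peptides <- c("AEKEA", "STKSPR", "GHYTIGK", "APVISAEKAY", "MTEQLETIPK",
                "DSLSQQLNSK", "LVPYPRKE")
  for (seq in peptides) {
    base <- modified_peptide(seq)
    sites <- which(base$residues %in% c("E", "K", "Y"))
    for (site in sites) {
      mp <- modified_peptide(seq, mods = list(list(pos = site, mod = mod_dep())))
      s <- simulate_spectrum(mp, zero_noise(29), 1)
      loc <- localize_adduct(s, base, sites)
      expect_equal(loc$status, "localized")
      expect_equal(loc$site, site)
    }
  }
})
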