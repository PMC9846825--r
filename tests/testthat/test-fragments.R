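test_that("b ions localize the diethyl phosphate adduct on the tubulin peptide", {
  ions <- linear_fragment_ions(fig2_peptide(), charges = 1)
  b <- subset(ions, series == "b")
  # printed values 1225.55 and 1282.56; only b9/b10 carry the +136 shift
  expect_equal(b$mz[b$index == 9], 1225.55, tolerance = 0.02)
  expect_equal(b$mz[b$index == 10], 1282.56, tolerance = 0.02)
  deltas <- numeric(20); deltas[9] <- mod_dep()$delta
  expect_equal(b$mz[b$index == 9], oracle_b_mz(fig2_sequence, 9, deltas),
               tolerance = 1e-5)
  # y1..y9 exclude both modification sites and are unshifted
  y <- subset(ions, series == "y" & index <= 9)
  for (i in 1:9) {
    expect_equal(y$mz[y$index == i], oracle_y_mz(fig2_sequence, i),
                 tolerance = 1e-5)
  }
})

test_that("linear ion tables have the expected shape and values", {
  ions <- linear_fragment_ions("STKSPR", charges = c(1, 2), series = c("b", "y"))
  expect_equal(nrow(ions), 5 * 2 * 2)
  expect_equal(subset(ions, series == "y" & index == 1 & charge == 1)$mz,
               175.1190, tolerance = 1e-4)
  expect_false(any(ions$carries_bridge))
  expect_true(all(ions$mz > 0))
  expect_error(linear_fragment_ions("STKSPR", charges = integer(0)), "nonempty")
  expect_error(linear_fragment_ions("S"), "at least 2")
})

test_that("b/y complementarity holds for random modified peptides", {
  pc <- physical_constants()
  withr::local_seed(23)
  for (rep in 1:30) {
    s <- random_peptide(sample(5:20, 1))
    mp <- modified_peptide(s)
    ions <- linear_fragment_ions(mp, charges = 1)
    b <- subset(ions, series == "b"); y <- subset(ions, series == "y")
    M <- peptide_mass(mp)
    n <- nchar(s)
    for (i in 1:(n - 1)) {
      expect_equal(b$mz[b$index == i] + y$mz[y$index == n - i],
                   M + 2 * pc$proton, tolerance = 1e-4)
    }
  }
})

test_that("cross-link specific ions carry the partner peptide plus bridge", {
  x <- fig4_pair()
  ions <- crosslink_fragment_ions(x, charges = c(1, 2))
  stk <- subset(ions, peptide == "b")  # STKSPR
  # y4 spans K3: cross-link specific, frozen against a residue-sum oracle
  y4 <- subset(stk, series == "y" & index == 4 & charge == 2)
  expect_true(y4$carries_bridge)
  expect_equal(y4$mz, 1146.0324, tolerance = 1e-3)
  # y1 (R alone) is an ordinary linear ion
  y1 <- subset(stk, series == "y" & index == 1 & charge == 1)
  expect_false(y1$carries_bridge)
  expect_equal(y1$mz, 175.1190, tolerance = 1e-4)
  # fragments spanning the site are flagged, all others are not
  expect_true(all(subset(stk, series == "b" & index >= 3)$carries_bridge))
  expect_false(any(subset(stk, series == "b" & index < 3)$carries_bridge))
  expect_equal(nrow(crosslink_fragment_ions(x, charges = integer(0))), 0)
})

test_that("bridge-carrying complements conserve the candidate mass", {
  pc <- physical_constants()
  x <- fig4_pair()
  M <- crosslink_mass(x)
  ions <- crosslink_fragment_ions(x, charges = 1)
  for (lab in c("a", "b")) {
    g <- subset(ions, peptide == lab)
    n <- max(g$index) + 1
    for (i in seq_len(n - 1)) {
      yi <- g$mz[g$series == "y" & g$index == i]
      bi <- g$mz[g$series == "b" & g$index == n - i]
      expect_equal(yi + bi, M + 2 * pc$proton, tolerance = 1e-4)
    }
  }
})

test_that("swapping the peptides of a pair leaves the ion m/z multiset unchanged", {
  b <- builtin_bridges()$EK_isopeptide
  x <- crosslink_candidate("APVISAEKAY", 7, "FDLMYAKR", 7, b)
  xs <- crosslink_candidate("FDLMYAKR", 7, "APVISAEKAY", 7, b)
  m1 <- sort(crosslink_fragment_ions(x, charges = c(1, 2))$mz)
  m2 <- sort(crosslink_fragment_ions(xs, charges = c(1, 2))$mz)
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("cross-link precursor masses match the printed parent ions", {
  x <- fig4_pair()
  expect_equal(crosslink_mass(x),
               peptide_mass("TIGGGDDSFNTFFSETGA") + peptide_mass("STKSPR") - 18.0106,
               tolerance = 1e-4)
  expect_equal(crosslink_precursor_mz(x, 3), 827.0506, tolerance = 1e-4)
  expect_equal(crosslink_precursor_mz(x, 1), 2479.1372, tolerance = 1e-4)
  # degenerate zero-delta bridge on a GG+GG toy pair
  gg <- bridge_definition("GG_test", "G", "G", delta = 0)
  x0 <- crosslink_candidate("GG", 1, "GG", 1, gg)
  expect_equal(crosslink_precursor_mz(x0, 1),
               2 * oracle_peptide_mass("GG") + ORACLE_PROTON, tolerance = 1e-4)
})

test_that("built-in bridges carry the documented mass deltas", {
  br <- builtin_bridges()
  expect_equal(br$EK_isopeptide$delta, -18.0106, tolerance = 1e-4)
  expect_equal(br$YK_loss_water$delta, -18.0106, tolerance = 1e-4)
  expect_equal(br$YK_loss_ammonia$delta, -17.0265, tolerance = 1e-4)
  expect_equal(br$YK_ethoxyphosphoryl$delta, 89.9871, tolerance = 1e-4)
})

test_that("candidate construction validates sites and residues", {
  b <- builtin_bridges()$EK_isopeptide
  expect_error(crosslink_candidate("STKSPR", 9, "TIGGGDDSFNTFFSETGA", 15, b),
               "outside")
  expect_error(crosslink_candidate("STKSPR", 1, "TIGGGDDSFNTFFSETGA", 15, b),
               "not eligible")
  expect_error(bridge_definition("x", character(0), "K", delta = 0), "nonempty")
})

test_that("bridge definitions load from JSON config", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"name":"EK","donors":["E"],"acceptors":["K"],"formula":"H-2 O-1"}]',
             path)
  br <- read_bridges(path)
  expect_equal(br$EK$delta, -18.0106, tolerance = 1e-4)
})
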