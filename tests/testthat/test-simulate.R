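test_that("the zero-noise limit reproduces the theoretical ion list exactly", {
  x <- fig4_pair()
  s <- simulate_spectrum(x, zero_noise(1), 1)
  theo <- sort(crosslink_fragment_ions(x, charges = c(1, 2))$mz)
  expect_equal(s$peaks$mz, theo, tolerance = 1e-10)
  expect_equal(s$precursor_mz, 827.0506, tolerance = 1e-4)
  expect_equal(s$precursor_charge, 3)
})

test_that("adduct spectra include the diagnostic signature ions", {
  mp <- modified_peptide("STKSPR", mods = list(list(pos = 3, mod = mod_dep())))
  s <- simulate_spectrum(mp, zero_noise(1), 1)
  theo <- sort(c(linear_fragment_ions(mp, charges = c(1, 2))$mz,
                 signature_ions("K")$mz))
  expect_equal(s$peaks$mz, theo, tolerance = 1e-10)
})

test_that("simulation is deterministic given seed and index", {
  p <- simulation_params(dropout = 0.3, jitter_ppm = 8, n_noise = 25, seed = 42)
  s1 <- simulate_spectrum(fig2_peptide(), p, 7)
  s2 <- simulate_spectrum(fig2_peptide(), p, 7)
  expect_identical(s1$peaks, s2$peaks)
  s3 <- simulate_spectrum(fig2_peptide(), p, 8)
  expect_false(isTRUE(all.equal(s1$peaks$mz, s3$peaks$mz)))
  # and byte-identical through MGF
  f1 <- withr::local_tempfile(fileext = ".mgf")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s1), f1); write_mgf(list(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("peak dropout behaves binomially across seeds", {
  n_theo <- nrow(linear_fragment_ions(fig2_sequence, charges = c(1, 2)))
  dropout <- 0.2
  counts <- vapply(1:200, function(seed) {
    p <- simulation_params(dropout = dropout, jitter_ppm = 0, n_noise = 0,
                           seed = seed)
    nrow(simulate_spectrum(fig2_sequence, p, 1)$peaks)
  }, numeric(1))
  expected <- n_theo * (1 - dropout)
  se <- sqrt(n_theo * dropout * (1 - dropout)) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("confounded spectra carry the candidate precursor but foreign peaks", {
  x <- fig4_pair()
  s <- simulate_confounded_spectrum(x, "DSLSQQLNS", zero_noise(3), 1)
  expect_equal(s$precursor_mz, crosslink_precursor_mz(x, 3), tolerance = 1e-9)
  theo <- sort(linear_fragment_ions("DSLSQQLNS", charges = c(1, 2))$mz)
  expect_equal(s$peaks$mz, theo, tolerance = 1e-10)
  # sequence overlap with the candidate is an error
  expect_error(simulate_confounded_spectrum(x, "STKSPR", zero_noise(3), 1),
               "shares sequence")
  expect_error(simulate_confounded_spectrum(x, "KSP", zero_noise(3), 1),
               "shares sequence")
})

test_that("benchmark generation validates its inputs", {
  expect_error(generate_benchmark(0, peptides = benchmark_pool), "n must be")
  expect_error(generate_benchmark(5, peptides = character(0)), "empty")
  expect_error(generate_benchmark(5, weights = c(linear = 0.5),
                                  peptides = benchmark_pool), "sum to 1")
  bench <- generate_benchmark(10, weights = c(linear = 1, adduct = 0,
                                              crosslink = 0, confounder = 0),
                              peptides = benchmark_pool,
                              params = zero_noise(5))
  expect_true(all(bench$truth$kind == "linear"))
  expect_equal(nrow(bench$truth), 10)
})

test_that("benchmark output is reproducible and fully labeled", {
  p <- simulation_params(seed = 99)
  b1 <- generate_benchmark(20, peptides = benchmark_pool, params = p)
  b2 <- generate_benchmark(20, peptides = benchmark_pool, params = p)
  expect_identical(b1$truth, b2$truth)
  expect_identical(lapply(b1$spectra, `[[`, "peaks"),
                   lapply(b2$spectra, `[[`, "peaks"))
  expect_equal(length(b1$spectra), nrow(b1$truth))
  expect_false(anyDuplicated(b1$truth$id) > 0)
  f <- withr::local_tempfile(fileext = ".mgf")
  t <- withr::local_tempfile(fileext = ".tsv")
  generate_benchmark(5, peptides = benchmark_pool, params = p,
                     mgf_path = f, truth_path = t)
  expect_length(read_mgf(f), 5)
  expect_equal(nrow(utils::read.delim(t)), 5)
})

test_that("true cross-link acceptance degrades monotonically with dropout", {
  x <- fig4_pair()
  cfg <- run_config()
  rate <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    acc <- vapply(1:100, function(seed) {
      p <- simulation_params(dropout = d, jitter_ppm = 0, n_noise = 0,
                             seed = seed)
      s <- simulate_spectrum(x, p, 1)
      evaluate_crosslink(s, x, alt_pool = character(),
                         config = cfg)$decision == "accept"
    }, logical(1))
    mean(acc)
  }, numeric(1))
  expect_equal(rate[1], 1.0)
  expect_true(all(diff(rate) <= 0))
})
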