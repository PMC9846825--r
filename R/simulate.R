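# Seeded generator of ground-truth-labeled synthetic spectra emulating
# Orbitrap-like peak lists of linear, adduct-bearing, cross-linked and
# confounded (false-positive-style) peptide spectra.

#' Simulation parameters
#'
#' @param dropout Probability that each theoretical peak is absent, in
#'   `[0, 1]` (default 0.1).
#' @param jitter_ppm Gaussian m/z jitter standard deviation in ppm
#'   (default 5, Orbitrap-like).
#' @param n_noise Number of uniform-random noise peaks added (default 30).
#' @param intensity_log10_mean,intensity_log10_sd Log-normal intensity
#'   model: intensities are `10^N(mean, sd)` in arbitrary units (defaults
#'   0 and 1). Intensities only matter through the top-N assigned-peak
#'   rule.
#' @param fragment_charges Fragment charges simulated (default 1:2).
#' @param precursor_charge Precursor charge, or `NULL` to use 2+ for
#'   linear peptides and 3+ for cross-linked pairs.
#' @param seed Master integer seed; each spectrum derives its own RNG
#'   stream from `(seed, index)` so spectra are independently
#'   reproducible.
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(dropout = 0.1, jitter_ppm = 5, n_noise = 30L,
                              intensity_log10_mean = 0,
                              intensity_log10_sd = 1,
                              fragment_charges = c(1L, 2L),
                              precursor_charge = NULL, seed = 1L) {
  stopifnot(dropout >= 0, dropout <= 1, jitter_ppm >= 0, n_noise >= 0)
  structure(list(dropout = dropout, jitter_ppm = jitter_ppm,
                 n_noise = as.integer(n_noise),
                 intensity_log10_mean = intensity_log10_mean,
                 intensity_log10_sd = intensity_log10_sd,
                 fragment_charges = as.integer(fragment_charges),
                 precursor_charge = precursor_charge,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Run expr under a derived seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Per-spectrum stream seed, kept below 2^31.
.stream_seed <- function(master, index, salt = 0) {
  as.integer((as.numeric(master) * 1009 + as.numeric(index) * 7919 +
                salt * 104729) %% 2147483629 + 1)
}

.theoretical_peaks <- function(truth, params) {
  if (inherits(truth, "crosslink_candidate")) {
    ions <- crosslink_fragment_ions(truth, charges = params$fragment_charges)
    list(mz = ions$mz,
         precursor = crosslink_precursor_mz(
           truth, if (is.null(params$precursor_charge)) 3L
                  else params$precursor_charge),
         charge = if (is.null(params$precursor_charge)) 3L
                  else params$precursor_charge)
  } else {
    p <- modified_peptide(truth)
    ions <- linear_fragment_ions(p, charges = params$fragment_charges)
    mz <- ions$mz
    for (m in p$mods) {
      res <- p$residues[m$pos]
      if (res %in% c("K", "Y", "E") && m$mod$name == "Dep") {
        mz <- c(mz, signature_ions(res, m$mod)$mz)
      }
    }
    z <- if (is.null(params$precursor_charge)) 2L else params$precursor_charge
    list(mz = mz, precursor = mz_from_mass(peptide_mass(p), z), charge = z)
  }
}

.noisy_spectrum <- function(id, theo_mz, precursor, charge, params) {
  kept <- theo_mz[stats::runif(length(theo_mz)) >= params$dropout]
  if (length(kept) && params$jitter_ppm > 0) {
    kept <- kept * (1 + stats::rnorm(length(kept), 0,
                                     params$jitter_ppm) * 1e-6)
  }
  noise <- if (params$n_noise > 0) {
    stats::runif(params$n_noise, 100, precursor * charge)
  } else numeric(0)
  mz <- c(kept, noise)
  intensity <- 10^stats::rnorm(length(mz), params$intensity_log10_mean,
                               params$intensity_log10_sd)
  spectrum(id, precursor, charge, mz, intensity)
}

#' Simulate one spectrum from a ground-truth analyte
#'
#' Peaks are the theoretical b/y ions of the truth (plus diethyl
#' phosphate signature ions for adduct-bearing K/Y/E residues), each kept
#' with probability `1 - dropout`, jittered by Gaussian ppm noise, with
#' uniform noise peaks added over `[100, precursor m/z x charge]` and
#' log-normal intensities. The precursor m/z is set from the truth. Fully
#' reproducible given `(params$seed, index)`.
#'
#' @param truth A `modified_peptide` (or sequence) or a
#'   `crosslink_candidate`.
#' @param params A [simulation_params()].
#' @param index Spectrum index; selects the per-spectrum RNG stream and
#'   names the spectrum `sim_<index>`.
#' @return A `spectrum`.
#' @export
simulate_spectrum <- function(truth, params = simulation_params(),
                              index = 1L) {
  theo <- .theoretical_peaks(truth, params)
  .with_seed(.stream_seed(params$seed, index),
             .noisy_spectrum(sprintf("sim_%d", as.integer(index)), theo$mz,
                             theo$precursor, theo$charge, params))
}

#' Simulate a false-positive (confounded) cross-link spectrum
#'
#' The precursor matches the cross-link candidate, but the peaks are the
#' linear b/y ions of an unrelated confounder peptide (plus noise) — the
#' scenario where putative cross-link specific ions really belong to a
#' peptide with no sequence in common with the candidate. The expected
#' validation decision is reject.
#'
#' @param x A `crosslink_candidate`.
#' @param confounder A peptide sharing no sequence with either candidate
#'   peptide (checked; overlap is an error).
#' @param params A [simulation_params()].
#' @param index Spectrum index (RNG stream / id).
#' @return A `spectrum` named `conf_<index>`.
#' @export
simulate_confounded_spectrum <- function(x, confounder,
                                         params = simulation_params(),
                                         index = 1L) {
  stopifnot(inherits(x, "crosslink_candidate"))
  conf <- modified_peptide(confounder)
  for (cs in c(x$peptide_a$sequence, x$peptide_b$sequence)) {
    if (grepl(conf$sequence, cs, fixed = TRUE) ||
        grepl(cs, conf$sequence, fixed = TRUE)) {
      stop("confounder shares sequence with the candidate", call. = FALSE)
    }
  }
  z <- if (is.null(params$precursor_charge)) 3L else params$precursor_charge
  ions <- linear_fragment_ions(conf, charges = params$fragment_charges)
  .with_seed(.stream_seed(params$seed, index, salt = 1),
             .noisy_spectrum(sprintf("conf_%d", as.integer(index)), ions$mz,
                             crosslink_precursor_mz(x, z), z, params))
}

#' Generate a labeled benchmark of synthetic spectra
#'
#' Draws `n` spectra from the four scenario kinds — plain linear peptide,
#' adduct-bearing peptide, cross-linked pair, and confounded cross-link
#' (expected false positive) — with peptides sampled from a pool (e.g. a
#' FASTA digest). Every spectrum gets exactly one ground-truth record.
#'
#' @param n Number of spectra (>= 1).
#' @param weights Named numeric mixture weights over
#'   `c("linear", "adduct", "crosslink", "confounder")`; must sum to 1.
#' @param peptides Nonempty character vector of pool peptide sequences.
#' @param params A [simulation_params()]; `params$seed` fixes everything.
#' @param adduct Adduct used for `"adduct"` spectra (default [mod_dep()]).
#' @param adduct_targets Residues the adduct is planted on (default K, Y,
#'   E).
#' @param bridge Bridge for cross-linked spectra (default the
#'   glutamate-lysine isopeptide bond).
#' @param fixed_mods Fixed modifications applied to all pool peptides.
#' @param mgf_path,truth_path Optional output paths for the MGF peak
#'   lists and the tab-separated truth table.
#' @return List with `spectra` (list of `spectrum`), `truth`
#'   (`data.frame`: id, kind, sequence_a, site_a, sequence_b, site_b,
#'   bridge, expected) and `peptides` (the pool).
#' @export
generate_benchmark <- function(n, weights = c(linear = 0.25, adduct = 0.25,
                                              crosslink = 0.25,
                                              confounder = 0.25),
                               peptides, params = simulation_params(),
                               adduct = mod_dep(),
                               adduct_targets = c("K", "Y", "E"),
                               bridge = builtin_bridges()$EK_isopeptide,
                               fixed_mods = list(mod_carbamidomethyl()),
                               mgf_path = NULL, truth_path = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  kinds <- c("linear", "adduct", "crosslink", "confounder")
  if (!all(names(weights) %in% kinds) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be named over the four kinds and sum to 1",
         call. = FALSE)
  }
  if (!length(peptides)) stop("empty peptide pool", call. = FALSE)
  w <- stats::setNames(numeric(4), kinds)
  w[names(weights)] <- weights

  pool <- lapply(peptides, .apply_fixed_mods, fixed_mods = fixed_mods)
  names(pool) <- peptides
  long <- vapply(pool, function(p) length(p$residues) >= 4L, logical(1))
  has <- function(letters) {
    vapply(pool, function(p) any(p$residues %in% letters), logical(1)) & long
  }
  pool_adduct <- which(has(adduct_targets))
  pool_donor <- which(has(bridge$donors))
  pool_acceptor <- which(has(bridge$acceptors))
  if (w["linear"] > 0 && !any(long)) stop("no usable pool peptides", call. = FALSE)
  if (w["adduct"] > 0 && !length(pool_adduct)) {
    stop("pool has no peptide with an adduct-eligible residue", call. = FALSE)
  }
  if ((w["crosslink"] > 0 || w["confounder"] > 0) &&
      (!length(pool_donor) || !length(pool_acceptor))) {
    stop("pool lacks donor- or acceptor-bearing peptides for the bridge",
         call. = FALSE)
  }

  kind_draw <- .with_seed(.stream_seed(params$seed, 0, salt = 2),
                          sample(kinds, n, replace = TRUE, prob = w))
  spectra <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- kind_draw[i]
    pick <- .with_seed(.stream_seed(params$seed, i, salt = 3), {
      if (kind == "linear") {
        list(a = pool[[sample(which(long), 1L)]])
      } else if (kind == "adduct") {
        p <- pool[[sample(pool_adduct, 1L)]]
        site <- sample(rep(which(p$residues %in% adduct_targets), 2L), 1L)
        list(a = p, site = site)
      } else {
        pa <- pool[[sample(pool_donor, 1L)]]
        pb <- pool[[sample(pool_acceptor, 1L)]]
        sa <- sample(rep(which(pa$residues %in% bridge$donors), 2L), 1L)
        sb <- sample(rep(which(pb$residues %in% bridge$acceptors), 2L), 1L)
        conf <- NULL
        if (kind == "confounder") {
          ok <- vapply(names(pool), function(s) {
            long[[s]] &&
              !grepl(s, pa$sequence, fixed = TRUE) &&
              !grepl(pa$sequence, s, fixed = TRUE) &&
              !grepl(s, pb$sequence, fixed = TRUE) &&
              !grepl(pb$sequence, s, fixed = TRUE)
          }, logical(1))
          if (!any(ok)) stop("no eligible confounder peptide in pool",
                             call. = FALSE)
          conf <- pool[[sample(rep(which(ok), 2L), 1L)]]
        }
        list(a = pa, sa = sa, b = pb, sb = sb, conf = conf)
      }
    })
    if (kind == "linear") {
      spectra[[i]] <- simulate_spectrum(pick$a, params, index = i)
      truth[[i]] <- data.frame(id = spectra[[i]]$id, kind = kind,
                               sequence_a = pick$a$sequence, site_a = NA_integer_,
                               sequence_b = NA_character_, site_b = NA_integer_,
                               bridge = NA_character_, expected = "none",
                               stringsAsFactors = FALSE)
    } else if (kind == "adduct") {
      mp <- modified_peptide(pick$a$sequence,
                             c(pick$a$mods,
                               list(list(pos = pick$site, mod = adduct))))
      spectra[[i]] <- simulate_spectrum(mp, params, index = i)
      truth[[i]] <- data.frame(id = spectra[[i]]$id, kind = kind,
                               sequence_a = pick$a$sequence,
                               site_a = pick$site,
                               sequence_b = NA_character_, site_b = NA_integer_,
                               bridge = NA_character_,
                               expected = "accept_adduct",
                               stringsAsFactors = FALSE)
    } else {
      xl <- crosslink_candidate(pick$a, pick$sa, pick$b, pick$sb, bridge)
      if (kind == "crosslink") {
        spectra[[i]] <- simulate_spectrum(xl, params, index = i)
        expected <- "accept_crosslink"
      } else {
        spectra[[i]] <- simulate_confounded_spectrum(xl, pick$conf, params,
                                                     index = i)
        expected <- "reject"
      }
      truth[[i]] <- data.frame(id = spectra[[i]]$id, kind = kind,
                               sequence_a = pick$a$sequence, site_a = pick$sa,
                               sequence_b = pick$b$sequence, site_b = pick$sb,
                               bridge = bridge$name, expected = expected,
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(spectra = spectra, truth = truth, peptides = peptides)
}
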