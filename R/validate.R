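# The multi-criterion acceptance/rejection procedure for adduct and
# cross-link candidates, including the automated false-positive screen.

#' Decision from per-criterion results
#'
#' Pure function: accept iff every applicable criterion passed
#' (`NA` marks a criterion not applicable to the candidate kind).
#'
#' @param criteria Named logical vector or list.
#' @return `"accept"` or `"reject"`.
#' @export
verdict_decision <- function(criteria) {
  v <- unlist(criteria)
  v <- v[!is.na(v)]
  if (length(v) && all(v)) "accept" else "reject"
}

.new_verdict <- function(kind, candidate, criteria, extra = list()) {
  structure(c(list(kind = kind, candidate = candidate, criteria = criteria,
                   decision = verdict_decision(criteria)), extra),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  flags <- vapply(x$criteria, function(v) {
    if (is.na(v)) "-" else if (v) "pass" else "FAIL"
  }, character(1))
  cat(sprintf("<verdict> %s: %s\n", x$kind, toupper(x$decision)))
  for (nm in names(flags)) cat(sprintf("  %-24s %s\n", nm, flags[nm]))
  invisible(x)
}

#' Screen cross-link specific peaks for an alternative explanation
#'
#' Automates the manual re-evaluation step: a candidate's bridge-carrying
#' peak assignments are tested against the linear b/y ions of every
#' alternative peptide in `alt_pool`. The screen fails (returns `FALSE`)
#' when a single alternative peptide explains at least as many of the
#' flagged peaks as the cross-link interpretation does (i.e. all of
#' them) — the flagged ions then fit an unrelated linear peptide and give
#' no support for a cross-link.
#'
#' @param flagged_mz m/z values of the peaks assigned to cross-link
#'   specific ions.
#' @param alt_pool Character vector (or list of `modified_peptide`) of
#'   alternative linear peptides; an empty pool passes.
#' @param tol_da Fragment tolerance in Da.
#' @param charges Fragment charges tried for the alternatives.
#' @return `TRUE` (screen passed) or `FALSE` (candidate is explained away).
#' @export
false_positive_screen <- function(flagged_mz, alt_pool, tol_da = 0.02,
                                  charges = c(1L, 2L)) {
  if (!length(flagged_mz) || !length(alt_pool)) return(TRUE)
  for (alt in alt_pool) {
    alt <- modified_peptide(alt)
    if (length(alt$residues) < 2L) next
    theo <- linear_fragment_ions(alt, charges = charges)$mz
    explained <- vapply(flagged_mz,
                        function(m) any(abs(theo - m) <= tol_da), logical(1))
    if (sum(explained) >= length(flagged_mz)) return(FALSE)
  }
  TRUE
}

# Alternative pool with peptides sharing sequence with the candidate
# removed (the screen targets peptides with no sequence in common).
.screen_pool <- function(alt_pool, sequences) {
  seqs <- vapply(alt_pool, function(p) {
    if (inherits(p, "modified_peptide")) p$sequence else as.character(p)
  }, character(1))
  related <- vapply(seqs, function(s) {
    any(vapply(sequences, function(cs) {
      grepl(s, cs, fixed = TRUE) || grepl(cs, s, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  alt_pool[!related]
}

#' Validate an adduct candidate against a spectrum
#'
#' Accepts the candidate iff the parent (precursor) mass matches the
#' adduct-bearing peptide within tolerance and the fragment ions localize
#' the adduct uniquely to the candidate's site (competing placements on
#' every other eligible residue of the peptide are re-scored and must
#' lose). Signature-ion matches are recorded as corroboration and only
#' required when `config$require_signature` is set.
#'
#' @param s A `spectrum`.
#' @param cand An `adduct_candidate`.
#' @param config A [run_config()].
#' @param sites Candidate sites competing for the placement; defaults to
#'   every residue of the peptide in the configured target set.
#' @return A `validation_verdict` with criteria `parent_mass_ok`,
#'   `site_localized`, `signature_ok` (NA unless required), and fields
#'   `localized_site`, `n_signature_matches`, `assignments`.
#' @export
evaluate_adduct <- function(s, cand, config = run_config(), sites = NULL) {
  stopifnot(inherits(s, "spectrum"), inherits(cand, "adduct_candidate"))
  theo <- mz_from_mass(peptide_mass(cand$peptide), s$precursor_charge)
  parent_ok <- abs(.ppm_error(theo, s$precursor_mz)) <= config$parent_tol_ppm

  base <- cand$base
  if (is.null(sites)) {
    sites <- which(base$residues %in%
                     intersect(config$target_residues, cand$adduct$targets))
    sites <- setdiff(sites, vapply(base$mods, function(m) m$pos, integer(1)))
    if (!length(sites)) sites <- cand$site
  }
  loc <- localize_adduct(s, base, sites, adduct = cand$adduct,
                         tol_da = config$frag_tol_da,
                         charges = config$fragment_charges)
  localized <- loc$status == "localized" && loc$site == cand$site

  res <- cand$peptide$residues[cand$site]
  n_sig <- 0L
  if (res %in% c("K", "Y", "E")) {
    sig <- signature_ions(res, cand$adduct)
    n_sig <- nrow(match_peaks(s, sig, config$frag_tol_da))
  }
  signature_ok <- if (config$require_signature) n_sig > 0L else NA
  .new_verdict("adduct", cand,
               list(parent_mass_ok = parent_ok, site_localized = localized,
                    signature_ok = signature_ok),
               list(localized_site = loc$site, n_signature_matches = n_sig,
                    site_counts = loc$n_assigned,
                    assignments = loc$assignments))
}

# Longest run of consecutive-index, bridge-carrying assignments within one
# (peptide, series, charge) group whose m/z step equals the intervening
# residue mass; returns the maximum qualifying run length.
.xl_series_run <- function(assignments, x, tol_da) {
  a <- assignments[assignments$carries_bridge, , drop = FALSE]
  if (nrow(a) < 2L) return(as.integer(nrow(a) > 0L))
  best <- 1L
  rm <- residue_masses()
  for (key in unique(paste(a$peptide, a$series, a$charge))) {
    g <- a[paste(a$peptide, a$series, a$charge) == key, , drop = FALSE]
    g <- g[order(g$index), , drop = FALSE]
    pep <- if (g$peptide[1] == "a") x$peptide_a else x$peptide_b
    n <- length(pep$residues)
    run <- 1L
    for (r in seq_len(nrow(g) - 1L)) {
      step_ok <- FALSE
      if (g$index[r + 1L] == g$index[r] + 1L) {
        # residue added going from index i to i+1
        pos <- if (g$series[1] == "b") g$index[r] + 1L else n - g$index[r]
        gap <- unname(rm[pep$residues[pos]])
        for (m in pep$mods) if (m$pos == pos) gap <- gap + m$mod$delta
        step_ok <- abs((g$mz[r + 1L] - g$mz[r]) * g$charge[1] - gap) <=
          tol_da * g$charge[1]
      }
      run <- if (step_ok) run + 1L else 1L
      best <- max(best, run)
    }
  }
  best
}

#' Annotated peak list for a validated spectrum
#'
#' Joins a spectrum's peaks with the ion assignments of a verdict, for
#' human review of a candidate (every peak appears once; unassigned peaks
#' have empty annotation columns).
#'
#' @param s The `spectrum` the verdict was computed on.
#' @param verdict A `validation_verdict` (its `assignments` field is
#'   used; may be `NULL`).
#' @return `data.frame` with `mz`, `intensity`, `series`, `index`,
#'   `charge`, `peptide`, `carries_bridge`, `error_da`.
#' @export
annotated_peaks <- function(s, verdict) {
  stopifnot(inherits(s, "spectrum"))
  out <- data.frame(mz = s$peaks$mz, intensity = s$peaks$intensity,
                    series = NA_character_, index = NA_integer_,
                    charge = NA_integer_, peptide = NA_character_,
                    carries_bridge = NA, error_da = NA_real_,
                    stringsAsFactors = FALSE)
  a <- verdict$assignments
  if (!is.null(a) && nrow(a)) {
    out$series[a$peak_index] <- a$series
    out$index[a$peak_index] <- a$index
    out$charge[a$peak_index] <- a$charge
    out$peptide[a$peak_index] <- a$peptide
    out$carries_bridge[a$peak_index] <- a$carries_bridge
    out$error_da[a$peak_index] <- a$error_da
  }
  out
}

# Among accepted cross-link candidates for one spectrum, competing site
# placements of the same (unordered) peptide pair are resolved by maximal
# peak explanation, mirroring adduct localization: keep the placement(s)
# whose assignment count is maximal within the pair.
.crosslink_site_winners <- function(cands, verdicts) {
  if (!length(cands)) return(logical(0))
  key <- vapply(cands, function(x) {
    paste(sort(c(x$peptide_a$sequence, x$peptide_b$sequence)), collapse = "|")
  }, character(1))
  n_assigned <- vapply(verdicts, function(v) nrow(v$assignments), integer(1))
  keep <- logical(length(cands))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx] <- n_assigned[idx] == max(n_assigned[idx])
  }
  keep
}

#' Validate a cross-link candidate against a spectrum
#'
#' Applies the five acceptance criteria: (1) more than
#' `assigned_fraction_cutoff` of the `top_n` most intense peaks assigned
#' to the cross-linked pair; (2) at least `min_xl_series` cross-link
#' specific ions in one series consecutive by one residue; (3) fragment
#' ions from both peptides present; (4) the false-positive screen against
#' `alt_pool` passes; (5) the parent mass matches the candidate. The
#' candidate is accepted iff all five pass.
#'
#' @param s A `spectrum`.
#' @param x A `crosslink_candidate`.
#' @param alt_pool Alternative linear peptides for the screen (peptides
#'   sharing sequence with the candidate are ignored).
#' @param config A [run_config()].
#' @return A `validation_verdict` with criteria `assigned_fraction_ok`,
#'   `xl_series_ok`, `both_peptides_supported`, `fp_screen_passed`,
#'   `parent_mass_ok`, and fields `assigned_fraction`,
#'   `xl_specific_series_count`, `assignments`.
#' @export
evaluate_crosslink <- function(s, x, alt_pool = character(),
                               config = run_config()) {
  stopifnot(inherits(s, "spectrum"), inherits(x, "crosslink_candidate"))
  ions <- crosslink_fragment_ions(x, charges = config$fragment_charges)
  a <- match_peaks(s, ions, config$frag_tol_da)
  af <- assigned_fraction(s, a, config$top_n)
  crit1 <- af > config$assigned_fraction_cutoff

  run <- .xl_series_run(a, x, config$frag_tol_da)
  crit2 <- run >= config$min_xl_series

  crit3 <- any(a$peptide == "a") && any(a$peptide == "b")

  flagged <- a[a$carries_bridge, , drop = FALSE]
  pool <- .screen_pool(alt_pool,
                       c(x$peptide_a$sequence, x$peptide_b$sequence))
  crit4 <- false_positive_screen(s$peaks$mz[flagged$peak_index], pool,
                                 config$frag_tol_da,
                                 config$fragment_charges)

  theo <- crosslink_precursor_mz(x, s$precursor_charge)
  crit5 <- abs(.ppm_error(theo, s$precursor_mz)) <= config$parent_tol_ppm

  .new_verdict("crosslink", x,
               list(assigned_fraction_ok = crit1, xl_series_ok = crit2,
                    both_peptides_supported = crit3, fp_screen_passed = crit4,
                    parent_mass_ok = crit5),
               list(assigned_fraction = af, xl_specific_series_count = run,
                    assignments = a))
}
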