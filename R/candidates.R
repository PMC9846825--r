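# Enumeration of adduct and cross-link candidates matching an observed
# precursor mass within a ppm tolerance.

# Normalize a peptide pool to data.frame(peptide, protein, start).
.as_peptide_pool <- function(peptides) {
  if (is.character(peptides)) {
    return(data.frame(peptide = peptides, protein = NA_character_,
                      start = 1L, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(peptides), "peptide" %in% names(peptides))
  if (is.null(peptides$protein)) peptides$protein <- NA_character_
  if (is.null(peptides$start)) peptides$start <- 1L
  peptides[, c("peptide", "protein", "start"), drop = FALSE]
}

# Apply fixed modifications (e.g. carbamidomethyl-C) at every matching
# residue of a bare sequence; returns a modified_peptide.
.apply_fixed_mods <- function(sequence, fixed_mods) {
  p <- modified_peptide(sequence)
  if (!length(fixed_mods)) return(p)
  mods <- list()
  for (fm in fixed_mods) {
    for (pos in which(p$residues %in% fm$targets)) {
      mods[[length(mods) + 1L]] <- list(pos = pos, mod = fm)
    }
  }
  modified_peptide(sequence, mods)
}

# All variants of a peptide with at most `max_var` variable modifications
# (single occurrence each); always includes the unmodified variant.
.variable_mod_variants <- function(p, variable_mods, max_var = 1L) {
  variants <- list(p)
  if (!length(variable_mods) || max_var < 1L) return(variants)
  taken <- vapply(p$mods, function(m) m$pos, integer(1))
  for (vm in variable_mods) {
    sites <- setdiff(which(p$residues %in% vm$targets), taken)
    for (pos in sites) {
      variants[[length(variants) + 1L]] <-
        modified_peptide(p$sequence, c(p$mods, list(list(pos = pos, mod = vm))))
    }
  }
  variants
}

.ppm_error <- function(theoretical, observed) {
  (theoretical - observed) / observed * 1e6
}

#' An adduct candidate
#'
#' One peptide with one positioned adduct, plus provenance. Normally
#' produced by [enumerate_adduct_candidates()].
#'
#' @param base `modified_peptide` without the adduct (may carry fixed or
#'   variable modifications).
#' @param site 1-based adduct position.
#' @param adduct The adduct `modification`.
#' @param protein Protein identifier.
#' @param protein_pos 1-based protein position of the adducted residue.
#' @return Object of class `adduct_candidate`; field `peptide` holds the
#'   adduct-bearing `modified_peptide`.
#' @export
adduct_candidate <- function(base, site, adduct = mod_dep(),
                             protein = NA_character_,
                             protein_pos = NA_integer_) {
  base <- modified_peptide(base)
  site <- as.integer(site)
  peptide <- modified_peptide(base$sequence,
                              c(base$mods, list(list(pos = site, mod = adduct))))
  structure(list(peptide = peptide, base = base, site = site,
                 adduct = adduct, protein = protein,
                 protein_pos = as.integer(protein_pos)),
            class = "adduct_candidate")
}

#' @export
print.adduct_candidate <- function(x, ...) {
  cat(sprintf("<adduct_candidate> %s-%s on %s%s (%s %s%s)\n",
              x$adduct$name, x$peptide$residues[x$site], x$peptide$sequence,
              paste0(" @", x$site),
              ifelse(is.na(x$protein), "?", x$protein),
              x$peptide$residues[x$site],
              ifelse(is.na(x$protein_pos), "?", x$protein_pos)))
  invisible(x)
}

#' Enumerate adduct candidates matching a precursor
#'
#' For every peptide of the pool (optionally expanded by variable
#' modifications) whose mass plus the adduct delta matches the observed
#' precursor within `tol_ppm`, emits one candidate per eligible site.
#'
#' @param peptides Character vector of sequences, or a `data.frame` with
#'   columns `peptide`, `protein`, `start` as produced by [digest()].
#' @param target_residues Residue letters eligible for the adduct
#'   (intersected with the adduct's own target set); nonempty.
#' @param adduct The adduct `modification` (default [mod_dep()]).
#' @param precursor_mz,charge Observed precursor m/z and charge.
#' @param tol_ppm Precursor tolerance in ppm (default 10).
#' @param fixed_mods List of fixed modifications applied at every matching
#'   residue (default carbamidomethyl-C).
#' @param variable_mods List of variable modifications tried at up to one
#'   site each (default Met oxidation).
#' @return List of `adduct_candidate` objects, each with attributes
#'   `mz_theoretical` and `ppm_error` stored as fields.
#' @export
enumerate_adduct_candidates <- function(peptides, target_residues,
                                        adduct = mod_dep(),
                                        precursor_mz, charge, tol_ppm = 10,
                                        fixed_mods = list(mod_carbamidomethyl()),
                                        variable_mods = list(mod_oxidation())) {
  if (!length(target_residues)) {
    stop("target residue set must be nonempty", call. = FALSE)
  }
  stopifnot(tol_ppm > 0)
  targets <- intersect(toupper(target_residues), adduct$targets)
  pool <- .as_peptide_pool(peptides)
  out <- list()
  for (i in seq_len(nrow(pool))) {
    base0 <- .apply_fixed_mods(pool$peptide[i], fixed_mods)
    for (base in .variable_mod_variants(base0, variable_mods)) {
      theo <- mz_from_mass(peptide_mass(base) + adduct$delta, charge)
      ppm <- .ppm_error(theo, precursor_mz)
      if (abs(ppm) > tol_ppm) next
      sites <- which(base$residues %in% targets)
      sites <- setdiff(sites, vapply(base$mods, function(m) m$pos, integer(1)))
      for (s in sites) {
        cand <- adduct_candidate(base, s, adduct, pool$protein[i],
                                 pool$start[i] + s - 1L)
        cand$mz_theoretical <- theo
        cand$ppm_error <- ppm
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Enumerate cross-link candidates matching a precursor
#'
#' Considers all (unordered) pairs of pool peptides whose combined mass
#' plus the bridge delta matches the observed precursor within `tol_ppm`,
#' and emits one candidate per eligible donor/acceptor site pair. Pairs
#' from the same protein (including a peptide with itself) are allowed.
#' Candidates are normalized with the lexicographically smaller sequence
#' as `peptide_a` and de-duplicated.
#'
#' @inheritParams enumerate_adduct_candidates
#' @param bridge A `bridge_definition`.
#' @return List of `crosslink_candidate` objects with `mz_theoretical` and
#'   `ppm_error` fields.
#' @export
enumerate_crosslink_candidates <- function(peptides, bridge,
                                           precursor_mz, charge, tol_ppm = 10,
                                           fixed_mods = list(mod_carbamidomethyl())) {
  stopifnot(inherits(bridge, "bridge_definition"), tol_ppm > 0)
  pool <- .as_peptide_pool(peptides)
  n <- nrow(pool)
  if (!n) return(list())
  mods_list <- lapply(pool$peptide, .apply_fixed_mods, fixed_mods = fixed_mods)
  masses <- vapply(mods_list, peptide_mass, numeric(1))
  target <- mass_from_mz(precursor_mz, charge) - bridge$delta
  tol_da <- mass_from_mz(precursor_mz, charge) * tol_ppm * 1e-6

  out <- list()
  seen <- character(0)
  for (ii in seq_len(n)) {
    # unordered pairs once (jj == ii allowed)
    js <- which(seq_len(n) >= ii & abs(masses + masses[ii] - target) <= tol_da)
    for (jj in js) {
      theo <- mz_from_mass(masses[ii] + masses[jj] + bridge$delta, charge)
      ppm <- .ppm_error(theo, precursor_mz)
      for (swap in c(FALSE, TRUE)) {
        i1 <- if (swap) jj else ii
        i2 <- if (swap) ii else jj
        if (swap && ii == jj) next
        p1 <- mods_list[[i1]]; p2 <- mods_list[[i2]]
        s1s <- which(p1$residues %in% bridge$donors)
        s2s <- which(p2$residues %in% bridge$acceptors)
        for (s1 in s1s) for (s2 in s2s) {
          # lexicographic normalization
          if (p1$sequence <= p2$sequence) {
            key <- paste(p1$sequence, s1, p2$sequence, s2, sep = "|")
            if (key %in% seen) next
            seen <- c(seen, key)
            cand <- crosslink_candidate(p1, s1, p2, s2, bridge,
                                        pool$protein[i1], pool$protein[i2],
                                        pool$start[i1] + s1 - 1L,
                                        pool$start[i2] + s2 - 1L)
          } else {
            key <- paste(p2$sequence, s2, p1$sequence, s1, sep = "|")
            if (key %in% seen) next
            seen <- c(seen, key)
            cand <- crosslink_candidate(p2, s2, p1, s1, bridge,
                                        pool$protein[i2], pool$protein[i1],
                                        pool$start[i2] + s2 - 1L,
                                        pool$start[i1] + s1 - 1L)
          }
          cand$mz_theoretical <- theo
          cand$ppm_error <- ppm
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}
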