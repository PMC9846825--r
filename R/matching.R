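# Peak-to-ion matching and adduct site localization.

#' Match theoretical ions to observed peaks
#'
#' Greedy one-to-one assignment: candidate (peak, ion) pairs within
#' `tol_da` are taken in order of increasing absolute mass error; each
#' peak is assigned to at most one ion and each ion to at most one peak.
#'
#' @param s A `spectrum` (peaks must be sorted by m/z).
#' @param ions Ion table with at least an `mz` column (from
#'   [linear_fragment_ions()], [crosslink_fragment_ions()] or
#'   [signature_ions()]).
#' @param tol_da Fragment tolerance in Da (default 0.02).
#' @return `data.frame` of assignments: `peak_index`, the ion columns, and
#'   `error_da`, `error_ppm`.
#' @export
match_peaks <- function(s, ions, tol_da = 0.02) {
  stopifnot(inherits(s, "spectrum"), tol_da > 0)
  if (is.unsorted(s$peaks$mz)) {
    stop("spectrum peaks must be sorted by m/z", call. = FALSE)
  }
  empty <- cbind(data.frame(peak_index = integer(0)),
                 ions[0, , drop = FALSE],
                 data.frame(error_da = numeric(0), error_ppm = numeric(0)))
  if (!nrow(s$peaks) || !nrow(ions)) return(empty)
  pk <- s$peaks$mz
  pairs <- list()
  for (i in seq_len(nrow(ions))) {
    lo <- findInterval(ions$mz[i] - tol_da, pk) + 1L
    hi <- findInterval(ions$mz[i] + tol_da, pk)
    if (hi >= lo) {
      for (j in lo:hi) {
        pairs[[length(pairs) + 1L]] <- c(i, j, pk[j] - ions$mz[i])
      }
    }
  }
  if (!length(pairs)) return(empty)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(abs(pm[, 3])), , drop = FALSE]
  used_ion <- logical(nrow(ions)); used_peak <- logical(length(pk))
  keep <- logical(nrow(pm))
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    if (!used_ion[i] && !used_peak[j]) {
      used_ion[i] <- TRUE; used_peak[j] <- TRUE; keep[r] <- TRUE
    }
  }
  pm <- pm[keep, , drop = FALSE]
  out <- cbind(data.frame(peak_index = as.integer(pm[, 2])),
               ions[pm[, 1], , drop = FALSE],
               data.frame(error_da = pm[, 3],
                          error_ppm = pm[, 3] / ions$mz[pm[, 1]] * 1e6))
  rownames(out) <- NULL
  out[order(out$peak_index), , drop = FALSE]
}

#' Fraction of the most intense peaks that are assigned
#'
#' The acceptance rule "more than 40% of the peaks are assigned" is
#' evaluated over the `top_n` most intense peaks (raw Orbitrap peak lists
#' carry abundant low-intensity noise, so the denominator is capped).
#'
#' @param s A `spectrum`.
#' @param assignments Assignment table from [match_peaks()] (tables from
#'   several ion sets may be row-bound).
#' @param top_n Number of most intense peaks forming the denominator
#'   (default 50); if the spectrum has fewer peaks, all are used.
#' @return Number in `[0, 1]`; `0` for an empty spectrum.
#' @export
assigned_fraction <- function(s, assignments, top_n = 50L) {
  stopifnot(inherits(s, "spectrum"), top_n >= 1L)
  n <- nrow(s$peaks)
  if (!n) return(0)
  top <- utils::head(order(s$peaks$intensity, decreasing = TRUE),
                     min(top_n, n))
  assigned <- unique(assignments$peak_index)
  mean(top %in% assigned)
}

# Does fragment (series, index) of an n-residue peptide span residue k?
.span_includes <- function(series, index, n, k) {
  ifelse(series == "b", index >= k, index >= n - k + 1L)
}

#' Localize an adduct site from fragment evidence
#'
#' Places the adduct at each candidate site in turn, matches the resulting
#' theoretical b/y ions to the spectrum, and returns the unique site whose
#' placement explains the most peaks, provided it is bracketed by at least
#' one mass-shifted assigned ion (spanning the site) and one unshifted
#' assigned ion (excluding it). Any tie, or missing bracketing evidence,
#' is reported as ambiguous: an adduct is only called when fragment ions
#' define its exact location.
#'
#' @param s A `spectrum`.
#' @param peptide Base `modified_peptide` (or sequence) without the
#'   adduct.
#' @param sites Integer vector of candidate 1-based sites (>= 1 site).
#' @param adduct The adduct `modification` (default [mod_dep()]).
#' @param tol_da Fragment tolerance in Da.
#' @param charges Fragment charges considered.
#' @return List with `site` (integer or `NA`), `status` (`"localized"` or
#'   `"ambiguous"`), `n_assigned` (named per-site assignment counts) and
#'   `assignments` (table for the winning site, or `NULL`).
#' @export
localize_adduct <- function(s, peptide, sites, adduct = mod_dep(),
                            tol_da = 0.02, charges = c(1L, 2L)) {
  peptide <- modified_peptide(peptide)
  sites <- as.integer(sites)
  if (!length(sites)) stop("need at least one candidate site", call. = FALSE)
  n <- length(peptide$residues)
  counts <- stats::setNames(integer(length(sites)), sites)
  tables <- vector("list", length(sites))
  for (k in seq_along(sites)) {
    mp <- modified_peptide(peptide$sequence,
                           c(peptide$mods,
                             list(list(pos = sites[k], mod = adduct))))
    ions <- linear_fragment_ions(mp, charges = charges)
    tables[[k]] <- match_peaks(s, ions, tol_da)
    counts[k] <- nrow(tables[[k]])
  }
  best <- max(counts)
  winners <- which(counts == best)
  ambiguous <- list(site = NA_integer_, status = "ambiguous",
                    n_assigned = counts, assignments = NULL)
  if (best == 0L || length(winners) != 1L) return(ambiguous)
  w <- winners[1]
  a <- tables[[w]]
  shifted <- .span_includes(a$series, a$index, n, sites[w])
  if (!any(shifted) || !any(!shifted)) return(ambiguous)
  list(site = sites[w], status = "localized", n_assigned = counts,
       assignments = a)
}
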