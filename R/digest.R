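# In-silico tryptic digestion with full, semi and unspecific modes.

#' Digestion settings
#'
#' Trypsin rule: cleave after K or R, not before P. `specificity` controls
#' how many peptide termini must conform: `"full"` (both), `"semi"` (at
#' least one; protein termini always conform), or `"none"` (any
#' substring). Several adduct-bearing peptides reported for CPO-treated
#' tubulin are semi-tryptic, hence the `"semi"` default.
#'
#' @param specificity One of `"semi"`, `"full"`, `"none"`.
#' @param max_missed Maximum internal missed cleavage sites (default 2).
#' @param length_range Integer `c(min, max)` peptide length (default
#'   `c(4, 60)`; min may be as low as 1).
#' @return Object of class `digest_spec`.
#' @export
digest_spec <- function(specificity = c("semi", "full", "none"),
                        max_missed = 2L, length_range = c(4L, 60L)) {
  specificity <- match.arg(specificity)
  max_missed <- as.integer(max_missed)
  length_range <- as.integer(length_range)
  stopifnot(max_missed >= 0L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1])
  structure(list(specificity = specificity, max_missed = max_missed,
                 length_range = length_range),
            class = "digest_spec")
}

# Positions i such that trypsin cleaves after residue i.
.cleavage_sites <- function(residues, noncleavable = integer()) {
  n <- length(residues)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  sites <- i[residues[i] %in% c("K", "R") & residues[i + 1L] != "P"]
  setdiff(sites, as.integer(noncleavable))
}

#' Digest a protein sequence
#'
#' Enumerates all peptides satisfying the cleavage rule, specificity,
#' missed-cleavage and length constraints, each with its 1-based start
#' coordinate in the protein. Positions listed in `noncleavable` (e.g. a
#' lysine blocked by a diethyl phosphate adduct) are not cleavage sites
#' and do not count as missed cleavages.
#'
#' @param protein Protein sequence (character scalar, standard residues).
#' @param spec A [digest_spec()].
#' @param noncleavable Integer protein positions excluded from cleavage.
#' @return `data.frame` with columns `peptide`, `start`, `end`, `missed`.
#' @examples
#' digest("AKRGFEK", digest_spec("full", 0, c(1, 60)))
#' @export
digest <- function(protein, spec = digest_spec(), noncleavable = integer()) {
  stopifnot(inherits(spec, "digest_spec"))
  residues <- .check_sequence(protein)
  n <- length(residues)
  sites <- .cleavage_sites(residues, noncleavable)
  lmin <- spec$length_range[1]; lmax <- spec$length_range[2]
  starts <- c(1L, sites + 1L)         # tryptic N-termini
  ends <- c(sites, n)                 # tryptic C-termini
  is_site <- logical(n); is_site[sites] <- TRUE

  rows <- list()
  add <- function(s, e) {
    internal <- if (e - 1L >= s) sum(is_site[s:(e - 1L)]) else 0L
    if (internal <= spec$max_missed) {
      rows[[length(rows) + 1L]] <<- c(s, e, internal)
    }
  }
  if (spec$specificity == "full") {
    for (s in starts) for (e in ends[ends >= s]) {
      len <- e - s + 1L
      if (len >= lmin && len <= lmax) add(s, e)
    }
  } else if (spec$specificity == "semi") {
    for (s in starts) {
      for (e in s:min(n, s + lmax - 1L)) {
        if (e - s + 1L >= lmin) add(s, e)
      }
    }
    for (e in ends) {
      for (s in max(1L, e - lmax + 1L):e) {
        if (e - s + 1L >= lmin && !(s %in% starts)) add(s, e)
      }
    }
  } else {
    for (s in seq_len(n)) {
      for (e in s:min(n, s + lmax - 1L)) {
        if (e - s + 1L >= lmin) add(s, e)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    peptide = vapply(seq_len(nrow(m)),
                     function(i) paste(residues[m[i, 1]:m[i, 2]], collapse = ""),
                     character(1)),
    start = m[, 1], end = m[, 2], missed = m[, 3],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$start, out$end), , drop = FALSE]
}
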