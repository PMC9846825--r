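# Independent oracles for mass arithmetic and digestion, kept separate
# from the package's own constants and code paths: a literal residue-mass
# table (standard monoisotopic values) and brute-force reference
# implementations used to freeze expected values.

ORACLE_RESIDUE <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)
ORACLE_PROTON <- 1.0072765
ORACLE_WATER <- 18.0105647

oracle_peptide_mass <- function(seq, extra = 0) {
  sum(ORACLE_RESIDUE[strsplit(seq, "")[[1]]]) + ORACLE_WATER + extra
}

# b_i / y_i singly charged m/z by direct residue summation; deltas is a
# numeric vector of per-position modification masses (0 where none).
oracle_b_mz <- function(seq, i, deltas = NULL, z = 1) {
  r <- strsplit(seq, "")[[1]]
  if (is.null(deltas)) deltas <- numeric(length(r))
  (sum(ORACLE_RESIDUE[r[1:i]]) + sum(deltas[1:i]) + z * ORACLE_PROTON) / z
}
oracle_y_mz <- function(seq, i, deltas = NULL, z = 1) {
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  if (is.null(deltas)) deltas <- numeric(n)
  span <- (n - i + 1):n
  (sum(ORACLE_RESIDUE[r[span]]) + sum(deltas[span]) + ORACLE_WATER +
     z * ORACLE_PROTON) / z
}

# Brute-force digest: enumerate every substring and filter by the
# trypsin rule (cleave after K/R, not before P), specificity, internal
# missed-cleavage count and length range.
oracle_digest <- function(seq, specificity, max_missed, lrange) {
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  sites <- which(r[-n] %in% c("K", "R") & r[-1] != "P")
  rows <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1
    if (len < lrange[1] || len > lrange[2]) next
    internal <- sum(sites >= s & sites <= e - 1)
    if (internal > max_missed) next
    nt <- s == 1 || (s - 1) %in% sites
    ct <- e == n || e %in% sites
    ok <- switch(specificity,
                 full = nt && ct,
                 semi = nt || ct,
                 none = TRUE)
    if (ok) rows[[length(rows) + 1]] <- c(s, e)
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0)))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    peptide = vapply(seq_len(nrow(m)),
                     function(i) substr(seq, m[i, 1], m[i, 2]), character(1)),
    start = m[, 1], end = m[, 2])
  unique(out[order(out$start, out$end), ])
}

random_peptide <- function(len, alphabet = names(ORACLE_RESIDUE)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Worked-example fixtures used across test files
fig2_sequence <- "AFVHWYVGEGMEEGEFSEAR"
fig2_peptide <- function() {
  modified_peptide(fig2_sequence,
                   mods = list(list(pos = 9, mod = mod_dep()),
                               list(pos = 11, mod = mod_oxidation())))
}
fig4_pair <- function() {
  crosslink_candidate("TIGGGDDSFNTFFSETGA", 15, "STKSPR", 3,
                      builtin_bridges()$EK_isopeptide)
}
benchmark_pool <- c("TIGGGDDSFNTFFSETGA", "STKSPR", "AFVHWYVGEGMEEGEFSEAR",
                    "DSLSQQLNSK", "LVPYPR", "GHYTIGK", "EADSLSR",
                    "MTEQLETIPK", "APVISAEKAY", "FDLMYAKR")
zero_noise <- function(seed = 1L) {
  simulation_params(dropout = 0, jitter_ppm = 0, n_noise = 0, seed = seed)
}
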