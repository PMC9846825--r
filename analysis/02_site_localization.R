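#!/usr/bin/env Rscript

# Adduct site localization on simulated spectra: the +136.0289 Da shift
# must be bracketed by shifted and unshifted fragment ions before a site
# is called. Writes per-site evidence under results/localization/.

suppressPackageStartupMessages(library(deplink))
out_dir <- "results/localization"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

base <- modified_peptide("AFVHWYVGEGMEEGEFSEAR",
                         mods = list(list(pos = 11, mod = mod_oxidation())))
sites <- which(base$residues %in% c("E", "D", "K", "Y", "S", "T", "H", "R"))
truth <- modified_peptide(base$sequence,
                          c(base$mods, list(list(pos = 9, mod = mod_dep()))))

params <- simulation_params(dropout = 0, jitter_ppm = 0, n_noise = 0, seed = 2)
s <- simulate_spectrum(truth, params, 1)
loc <- localize_adduct(s, base, sites)
tab <- data.frame(site = sites, residue = base$residues[sites],
                  n_assigned = as.integer(loc$n_assigned))
write.table(tab, file.path(out_dir, "per_site_evidence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Clean spectrum of the Dep-E9 peptide:\n")
print(tab, row.names = FALSE)
cat(sprintf("-> localization: %s at site %s (truth: E9)\n",
            loc$status, loc$site))

# Degraded spectra: with increasing peak dropout the site call must
# either stay correct or become ambiguous - never flip to a wrong site.
rows <- list()
for (d in c(0, 0.2, 0.4, 0.6, 0.8)) {
  res <- vapply(1:100, function(seed) {
    p <- simulation_params(dropout = d, jitter_ppm = 5, n_noise = 10,
                           seed = seed)
    l <- localize_adduct(simulate_spectrum(truth, p, 1), base, sites)
    if (l$status != "localized") "ambiguous"
    else if (l$site == 9) "correct" else "wrong"
  }, character(1))
  rows[[length(rows) + 1]] <- data.frame(
    dropout = d, correct = mean(res == "correct"),
    ambiguous = mean(res == "ambiguous"), wrong = mean(res == "wrong"))
}
grid <- do.call(rbind, rows)
write.table(grid, file.path(out_dir, "dropout_grid.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nLocalization vs dropout (100 spectra per point):\n")
print(grid, row.names = FALSE)
if (all(grid$wrong == 0)) {
  cat("-> no wrong-site call at any dropout level\n")
} else {
  cat("-> WARNING: wrong-site calls observed\n")
}
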