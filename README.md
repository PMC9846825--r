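# deplink

Identification of organophosphate-derived **diethyl phosphate (Dep)
adducts** and **zero-length glutamate–lysine isopeptide cross-links**
in peptide tandem mass spectra.

Chlorpyrifos oxon and related organophosphates phosphylate nucleophilic
side chains (Glu, Asp, Lys, Tyr, Ser, Thr), adding C4H9O3P =
+136.0289 Da to the residue. A Dep-activated glutamate or lysine can
then condense with a nearby lysine/glutamate into an
ε-(γ-glutamyl)lysine isopeptide bond; the cross-linked pair weighs the
sum of the two peptides **minus one water** (bridge H-2 O-1,
−18.0106 Da). `deplink` implements the complete desk procedure for
finding both analyte classes in peak lists, for proteomics researchers
studying organophosphate adductomics and protein cross-linking:

* monoisotopic mass arithmetic — elemental formulas (negative counts
  allowed), modified peptides, MH^z+ ions: m/z = (M + z·m_p)/z;
* theoretical **b/y fragment ions** for linear peptides and for
  cross-linked pairs, where fragments spanning the linked residue carry
  the intact partner peptide plus the bridge (*cross-link specific
  ions*), and immonium-derived **signature ions** for Dep-K/Y/E
  (nominal 237, 220 / 272, 244, 226, 216, 198 / 238, 210, 192, 182,
  164);
* in-silico tryptic digestion (full / semi / unspecific, missed
  cleavages, Dep-blocked lysines non-cleavable) and precursor-mass
  candidate enumeration within ppm tolerance;
* peak matching and the multi-criterion acceptance decision:
  >40% of the top-50 peaks assigned, ≥2 consecutive cross-link
  specific ions in a series, fragments from both peptides, an
  automated false-positive screen against alternative linear peptides,
  and a parent-mass check; adducts additionally require unique site
  localization bracketed by shifted and unshifted ions;
* a **seeded synthetic-spectrum generator** (dropout, ppm jitter,
  noise peaks, log-normal intensities, confounder scenarios) so the
  whole pipeline is benchmarked against known ground truth without any
  raw-data download.

## Worked example

The tubulin α 1A × MAP2 cross-linked pair and the Dep-glutamate
tubulin peptide:

```r
library(deplink)

pair <- crosslink_candidate("TIGGGDDSFNTFFSETGA", 15, "STKSPR", 3,
                            builtin_bridges()$EK_isopeptide)
crosslink_precursor_mz(pair, 3)
#> [1] 827.0506

dep <- modified_peptide("AFVHWYVGEGMEEGEFSEAR",
                        mods = list(list(pos = 9,  mod = mod_dep()),
                                    list(pos = 11, mod = mod_oxidation())))
b <- subset(linear_fragment_ions(dep, charges = 1), series == "b")
b$mz[b$index %in% c(9, 10)]
#> [1] 1225.544 1282.566

signature_ions("K")$nominal
#> [1] 237 220
```

827.0506 is the 3+ parent ion of the −18 Da cross-linked pair; the b9
and b10 ions, both carrying the +136.0289 shift while y1–y9 are
unshifted, pin the adduct to E9; 237 and 220 are the diagnostic
low-mass ions of diethylphospho-lysine. Running the end-to-end pipeline
on a simulated spectrum of the pair against the bundled synthetic
protein fragments:

```r
fasta <- system.file("extdata", "synthetic_fragments.fasta", package = "deplink")
s <- simulate_spectrum(pair, simulation_params(dropout = 0, jitter_ppm = 0,
                                               n_noise = 0, seed = 11), 1)
write_mgf(list(s), "demo.mgf")
run_pipeline(run_config(), fasta, "demo.mgf")$crosslinks[, c("peptide_a",
  "site_a", "peptide_b", "site_b", "mz_theoretical", "assigned_fraction")]
#>   peptide_a site_a          peptide_b site_b mz_theoretical assigned_fraction
#> 1    STKSPR     K7 TIGGGDDSFNTFFSETGA    E40       827.0506                 1
```

one accepted cross-link row: K7/E40 are the linked residues in the
coordinates of the two synthetic protein fragments, with every top peak
assigned.

## Analysis scripts

The numbered scripts under `analysis/` re-run the package's studies and
write tab-separated tables under `results/`:

| script | what it does |
|---|---|
| `01_worked_examples.R` | chemistry constants, signature-ion tables, fragment tables, parent masses |
| `02_site_localization.R` | per-site fragment evidence; localization vs peak dropout |
| `03_benchmark.R` | 100-spectrum zero-noise benchmark (precision/recall), dropout degradation curve |
| `04_pipeline_demo.R` | FASTA + MGF pipeline round trip including a confounded spectrum |

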