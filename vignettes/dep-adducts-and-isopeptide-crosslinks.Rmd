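---
title: "Detecting diethyl phosphate adducts and zero-length isopeptide cross-links in peptide MS/MS data"
author: "deplink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diethyl phosphate adducts and zero-length isopeptide cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deplink)
```

## The problem

Organophosphate toxicants such as chlorpyrifos oxon (CPO) transfer a
diethyl phosphate group (Dep, elemental composition C4H9O3P once the
nucleophile's proton is lost) onto nucleophilic protein side chains,
raising the residue's monoisotopic mass by 136.0289 Da. A Dep-activated
glutamate γ-carboxyl (or lysine ε-amine) can then react with a nearby
lysine (or glutamate), expelling the diethyl phosphate and water and
leaving a zero-length ε-(γ-glutamyl)lysine isopeptide bond. The
cross-linked pair's mass is the sum of the two peptide masses **minus**
one water (bridge composition H-2 O-1, −18.0106 Da). Such cross-links
aggregate proteins and are a candidate mechanism linking chronic
low-dose organophosphate exposure to neurodegeneration.

`deplink` implements the identification procedure for both analyte
classes in tryptic MS/MS peak lists: candidate generation by added
mass, theoretical b/y fragment and signature-ion computation, peak
matching, and a multi-criterion acceptance decision with an automated
false-positive screen. Because the procedure is fully specified by mass
arithmetic, every stage is testable on synthetic spectra with known
ground truth; the package ships a seeded generator for exactly that
purpose.

## Mass model

All arithmetic is monoisotopic. A peptide's neutral mass is the residue
sum plus one water plus all modification deltas; a protonated ion has

$$ m/z \;=\; \frac{M + z\,m_p}{z}, \qquad m_p = 1.0072765\ \mathrm{Da}. $$

Fragmentation is modeled with b and y ions only (the spectra this
procedure was built for are annotated exclusively with b/y series):
$b_i$ is the sum of the first $i$ position masses plus protons, $y_i$
the sum of the last $i$ plus water plus protons, so that
$b_i + y_{n-i} = M + 2 m_p$ at charge 1 — a complementarity identity the
test suite checks over thousands of random peptides.

A modification inside a fragment's span shifts that fragment by its
delta. This is what localizes an adduct: for the tubulin α 1A peptide
AFVHWYVGEGMEEGEFSEAR with Dep on E9 and oxidized M11, the b9 and b10
ions appear at 1225.54 and 1282.57 (+136.0289 relative to the
unmodified series) while y1–y9 are unshifted, pinning the adduct to E9
and excluding the peptide's four other glutamates.

For a cross-linked pair, fragments of one peptide that do **not** span
its linked residue are ordinary linear ions; fragments that do span it
carry the entire partner peptide plus the bridge delta. These
*cross-link specific* ions contain sequence from both peptides and are
the only direct evidence of the link, so they are flagged
(`carries_bridge`) and treated specially by the acceptance criteria.

### Signature ions

Dep adducts on K, Y and E produce low-mass diagnostic ions: the
immonium ion (residue mass − CO + proton) plus 136.0289, with
characteristic neutral losses — ammonia for lysine; one or two
ethylenes, each optionally with water, for tyrosine and glutamate:

```{r}
signature_ions("K")$nominal
signature_ions("Y")$nominal
signature_ions("E")$nominal
```

The immonium convention (residue − CO + proton) was chosen because it
reproduces all twelve printed nominal masses exactly; "nominal" means
rounded half-up to the nearest integer. Signature ions are
*corroborative* by default (`require_signature = FALSE`): Dep-E
signature ions are calculable but not observed in practice, so making
them mandatory would veto true glutamate adducts.

## The acceptance procedure

`evaluate_crosslink()` applies five criteria; a candidate is accepted
iff all pass:

1. **Assigned fraction** — more than 40% of the spectrum's peaks are
   assigned to the cross-linked pair. The denominator is capped at the
   `top_n = 50` most intense peaks, because raw Orbitrap peak lists
   carry abundant low-intensity noise and an uncapped denominator would
   make the criterion depend on the vendor's peak-picking threshold
   rather than on the identification.
2. **Cross-link specific series** — at least 2 bridge-carrying ions in
   the same series and charge state, consecutive by index, whose m/z
   gap equals the intervening residue mass within tolerance ("a series
   that defines an amino acid").
3. **Both peptides supported** — at least one assigned fragment from
   each peptide.
4. **False-positive screen** — the manual re-evaluation step,
   automated: the bridge-flagged peaks are tested against the linear
   b/y ions of every alternative peptide in the digest pool (peptides
   sharing sequence with the candidate are excluded). If a single
   alternative linear peptide explains *all* of the flagged peaks, the
   putative cross-link specific ions fit an unrelated peptide and the
   candidate is rejected. `annotated_peaks()` exports the per-peak
   evidence for human review.
5. **Parent mass** — the precursor m/z matches the candidate's
   theoretical MH^z+ within 10 ppm.

`evaluate_adduct()` accepts an adduct candidate iff the parent mass
matches and the site is *uniquely* localized: every eligible residue of
the peptide is re-scored as an alternative placement, the winner must
explain strictly more peaks than every competitor, and the call must be
bracketed by at least one shifted and one unshifted assigned ion.
Without bracketing evidence the site is reported ambiguous and the
candidate rejected — an adduct is only called when fragment ions define
its exact location.

The five cross-link criteria validate the *pair*, not the link site:
with several glutamates on one peptide, every placement can pass. Site
competition is therefore resolved the same way as for adducts: among
accepted placements of the same unordered pair, only those explaining
the maximal number of peaks are reported.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| precursor / parent tolerance | 10 ppm | Orbitrap-class accuracy |
| fragment tolerance | 0.02 Da | Orbitrap-class fragment accuracy |
| assigned-fraction cutoff | 0.40 (strict >) | the printed criterion |
| min. consecutive specific ions | 2 | the printed criterion |
| top-N denominator | 50 peaks | see criterion 1 above |
| fragment charges | {1, 2} | 1+ and 2+ fragment ions are the ones annotated in practice; the charge states actually searched upstream are not documented, so this is a package decision |
| digestion | semi-tryptic, ≤2 missed cleavages, length 4–60 | several reported adduct peptides are semi-tryptic; a `"none"` mode exists for exact reproduction of arbitrary sub-peptides |
| Dep target residues | E, D, K, Y, S, T, H, R | the full searched set; observed adducts cover E, D, K, Y, S, T |
| fixed / variable modifications | carbamidomethyl-C; Met oxidation | iodoacetamide alkylation; ubiquitous Mox |

A Dep-blocked lysine is chemically non-cleavable; `digest()` takes a
`noncleavable` argument so such sites neither cleave nor count as
missed cleavages.

Bridge chemistries are data, not code: `builtin_bridges()` provides the
glutamate–lysine isopeptide bond (H-2 O-1) plus three hypothetical
tyrosine–lysine chemistries searched as expected-negative modes — loss
of water (−18.0106), loss of ammonia (−17.0265) and an
ethoxyphosphoryl link (C2H3O2P, +89.9871). Custom adducts and bridges
load from JSON (`read_modifications()`, `read_bridges()`).

## The synthetic-spectrum generator

`simulate_spectrum()` emulates an Orbitrap-like peak list of a known
analyte: the theoretical b/y ions (plus signature ions for
Dep-bearing K/Y/E residues), each kept with probability
`1 − dropout` (default 0.1), jittered by Gaussian ppm noise (default
5 ppm), plus uniform-random noise peaks (default 30) over
[100, precursor m/z × charge], with log-normal intensities
(10^N(0, 1), arbitrary units — intensities only matter through the
top-N rule). `simulate_confounded_spectrum()` builds the
false-positive scenario: a precursor matching a cross-link candidate
over the fragment ions of an unrelated peptide.

Each spectrum draws from its own RNG stream derived from
`(seed, index)`, so any spectrum is reproducible in isolation and MGF
output is byte-identical across runs. Note one deliberate idealization:
the generator emits Dep-E signature ions although real spectra do not
show them; they are corroborative only, so this affects no decision.

What the generator does *not* emulate: isotope envelopes,
chromatography, co-isolation chimerism, intensity structure of real
fragmentation, and mass-error correlation across peaks. Passing the
zero-noise benchmark therefore demonstrates the correctness of the
arithmetic and the decision logic, not real-data sensitivity; the
dropout/jitter grids probe robustness only within this idealized noise
model.

## Numerical choices and degenerate inputs

* Proton 1.0072765 Da; water 18.010565 Da; CHNOPS atomic masses only.
  Average-mass mode is unsupported.
* Elemental formulas accept negative counts (`"H-2 O-1"`); the empty
  formula has mass 0.
* Peak matching is one-to-one and greedy by smallest absolute error;
  ties at equal index are impossible after sorting, and each ion/peak
  is used at most once.
* `assigned_fraction()` returns 0 on an empty spectrum; localization
  with no matched shifted ion returns `"ambiguous"` rather than
  guessing; `verdict_decision()` is a pure function of the per-criterion
  fields, and inapplicable criteria (`NA`) do not block acceptance.
* Candidate pairs are normalized lexicographically (smaller sequence
  first) and de-duplicated; a peptide may pair with itself, and pairs
  from the same protein are allowed (internal cross-links occur).
* MGF m/z values are written with 5 decimals, so a write/read round
  trip is identity to 4 decimals; blocks without CHARGE default to 2+
  with a warning, blocks without PEPMASS are an error naming the block.

## Problem sizes used in the checks

The bundled analyses and tests run at desk scale, chosen to exercise
every code path on a single CPU in minutes: b/y complementarity over
1,000 random peptides; digestion against a brute-force substring oracle
on random sequences up to 60 residues; exhaustive site-localization
round trips over all eligible sites of a panel of short peptides; a
100-spectrum zero-noise benchmark (mixture of linear, adduct,
cross-link and confounder spectra) on a 10-peptide pool, on which the
pipeline must reach precision = recall = 1.0 with every confounder
rejected; and 100-spectra-per-point dropout grids for the degradation
curves.

## Interfaces

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported
functions (worked examples, localization study, benchmark, pipeline
demo), writing tab-separated tables under `results/`. `run_pipeline()`
is the single entry point for FASTA + MGF inputs and emits
adduct/cross-link report tables in the field's customary shape (site
notation `E411`, `K1635`: residue letter + protein position);
`run_config()` / `write_config()` record every tunable of a run as
JSON. No separate shell CLI is provided — the scripts and functions are
the interface.

## Known limitations

* No probabilistic site-localization score and no target-decoy FDR:
  acceptance is the printed rule set, not a statistical model.
* Only b/y series; no internal fragments, no neutral-loss backbone
  variants (a configurable flag is reserved), no intensity prediction.
* Precursor charges are taken from the MGF as given; charge
  deconvolution and isotope-envelope handling are upstream concerns.
* The false-positive screen tests alternative *linear* peptides only,
  mirroring the manual procedure it automates; it does not re-search
  alternative cross-links.
* `Biostrings` handles FASTA; malformed records are reported per file,
  not per line.
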