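---
title: "Methods: O-glycan profiling and site localization in oglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: O-glycan profiling and site localization in oglyco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oglyco)
```

## Scope and model

`oglyco` implements the two halves of a mucin-type O-glycosylation
characterization workflow for CTP-fusion glycoproteins such as rhFSH-CTP:
released 2-AB labeled glycan profiling, and OpeRATOR-based glycopeptide
identification with tiered site localization. Everything is desk-scale,
deterministic given a seed, and driven by monoisotopic mass arithmetic from
a single mass table.

### Mass model

Residue masses cover exactly the 20 standard amino acids; glycan
compositions live over the alphabet {HexNAc, Hex, NeuAc, Fuc} in residue
form (e.g. core 1 = HexNAc(1)Hex(1) = 365.1322 Da). Constants:

| constant | value (Da) | note |
|---|---|---|
| water | 18.010565 | peptide/free-glycan termini |
| proton | 1.0072765 | charging; *not* the H-atom mass |
| 2-AB net label | 120.068748 | +C7H8N2O − H2O + H2 (reductive amination) |
| acetyl | 42.010565 | mono-deacetylation byproducts |
| HexNAc remnant | 203.079373 | "b + N" diagnostic increment |

Two interpretation choices matter and are deliberate:

- Instrument-report phrasing like "theoretical m/z of the unmodified peptide
  segment = 625.3547" refers to the *neutral monoisotopic mass*
  (Σ residues + H2O); `peptide_mass()` reproduces those values exactly, and
  `glycopeptide_mz()` adds glycan residue masses and protons for observed
  precursors.
- The 2-AB derivative is modeled as a net +120.0687 Da on the free reducing
  glycan. The informal description of 2-AB adducts as "m/z 139" (the
  protonated reagent) matches no single mass delta of the labeled product
  and is not used numerically.

Variable modifications (Met oxidation +15.995, N/Q deamidation +0.9804) are
supported in `peptide_mass()` for precursor arithmetic; fragment ions are
generated for unmodified backbones plus glycans, which is sufficient for
the CTP glycopeptides (none were reported carrying variable
modifications).

### Fragment conventions

HCD yields b/y ions; because HCD preferentially cleaves glycosidic bonds,
ions are emitted in three glycan states: naked, +203.079 per glycosite in
range (HexNAc remnant), and full glycan. EThcD yields c/z ions with the
glycan retained wherever the fragment range contains a glycosite. The z-ion
convention is configurable because published spectra annotations mix them:
z = y − 17.02655, z• (default, standard for electron-driven dissociation)
= y − 16.01872, z+1 = y − 15.01090. The default reproduces the
theory-consistent published values (z•4 = 397.22 for glycosylated SLPSP,
z•6 = 945.45 for doubly glycosylated SSKAPPP); three published z values
follow other conventions (or are typos) and are excluded from exact tests.

### Digestion semantics

OpeRATOR cleaves immediately N-terminal to an O-glycosylated Ser/Thr (core
1/3 substrate, hence the sialidase co-treatment, which `apply_sialidase()`
models by zeroing NeuAc counts). Glycosites are an *input* — occupancy is
sample-dependent and OpeRATOR only cuts occupied sites — with an
all-S/T-candidates convenience mode.

A design point worth recording: missed cleavages are counted over
*occupied* internal sites, not over all candidate sites. An unoccupied S/T
is not an OpeRATOR substrate, so leaving it uncut costs nothing. This is
visible in the reported data: the glycopeptide SLPSPSRLPGPSDTPILPQ
(121–139, glycans at 121 and 132 only) spans four candidate sites but has a
single missed cleavage. `digest_operator()` itself enumerates spans bounded
by candidate-site counts (and is verified against a brute-force substring
oracle); `build_candidates()` applies the ≤3 budget at the glycoform level,
where occupancy is known.

### Identification

Closed search: candidates = digest × glycoform enumeration (internal sites
optionally unoccupied) over the allowed glycan set, default
{core 1, mono-, disialyl core 1}, desialylated to {core 1} when the
sialidase flag is on. A spectrum is matched to candidates within 10 ppm
precursor tolerance at its charge; candidates are scored by the count of
theoretical backbone ions matched within 20 ppm (nearest peak by |ppm|,
intensity only breaks ties), and the top candidate wins with deterministic
tie-breaking (smaller precursor error, fewer sites, lexicographic). There
is no FDR model: the search space is a closed enumeration, mirroring
validation practice for a known protein, not a discovery search.

### Localization: the cut-point constraint system

Published practice states two HCD confidence criteria (single-candidate
backbone fragments; retention of at least one core GalNAc on a fragment)
and demonstrates EThcD bracketing. `oglyco` generalizes these into one
deterministic rule. Every matched backbone ion fixes a *cut*: a b/c ion at
index *k* bounds prefix 1..k, a y/z ion of suffix length *j* bounds prefix
1..(n−j); cut 0 and cut n are always known (nothing, and the
precursor-determined total). Between consecutive known cuts, the candidate
map places *g* glycans; if the region contains exactly *g* S/T residues and
g ≥ 1, every S/T in it must be occupied — those sites are ion-confirmed.

- In EThcD mode all backbone ions contribute cuts (glycans survive
  electron-driven dissociation), and confirmed sites are
  `direct_bracketing`. This reproduces the published reasoning that a
  single glycan-bearing z6 localizes both S114 and S115 of SSKAPPP, and
  that a naked z6 of SDTPILPQ pins S132.
- In HCD mode only glycan-bearing (full or remnant) ions contribute cuts,
  because a naked HCD fragment may have lost its glycan in the gas phase;
  confirmed sites are `remnant_localized`, and the single-S/T shortcut
  gives `single_candidate`.
- At least one real matched ion is required before regions are evaluated,
  so a precursor alone never localizes (e.g. SSKAPPP with two glycans and
  two serines is combinatorially forced, but is still reported as
  `enzyme_inferred` without fragments — evidence is never silently
  upgraded).

Aggregation across spectra keeps the best tier per position (best-tier-wins
is a design choice; no reconciliation rule is published), counts distinct
supporting glycopeptides, and flags positions absent from the prior site
list as novel (default prior: the six reported CTP sites 114, 115, 121,
126, 132, 134 — which is how S124 surfaces as novel).

No probabilistic localization score is computed. The published procedure is
criterion-based; a deterministic tier system reports exactly what the
evidence supports and nothing more.

## Glycan profiling

`assign_glycan_peaks()` matches integrated chromatogram peaks (the module
consumes peak tables, not raw chromatograms — integration is instrument
software territory) to a built-in library of eight species: the four major
core 1 derived glycoforms plus peeling products (NeuAcGal 592.23, NeuAc
430.18 — compositions without HexNAc, modeled as ordinary smaller
compositions) and mono-deacetylated variants (−42.0106 Da). Matching is
nearest-by-mass within 0.02 Da; the two monosialylated core 1 isomers share
m/z 795.32 and are resolved only by retention-time windows (±0.4 min
defaults around typical HILIC values); a peak in neither window is reported
as an isomer group rather than guessed. MS/MS-based isomer calls are out of
scope.

Quantitation: percentages are computed over the four major glycoforms by
default (matching the usual reporting), with an all-assigned option;
replicate RSD uses the sample (n−1) standard deviation (unspecified in the
source; this is the conservative choice); linearity is plain OLS with R²
defined as 0 for a constant response; recovery scales a 40 µg reference
proportionally. All four metrics are scale-invariant in area units.

## Synthetic data: what it emulates, and what a green test proves

The generator's defaults are the stated conditions of the validation
experiments, chosen once:

- **Spectra**: one spectrum per glycopeptide of the reported 16-entry CTP
  inventory at its observed charge; ion coverage fraction, Gaussian mass
  error *in ppm* (instrument behavior; tolerances are ppm), uniform decoy
  peaks with intensities resampled from real ions. Intensities are
  rank-based (y/z > b/c > remnant) and explicitly arbitrary — no intensity
  model is claimed, and intensity never affects identity decisions.
- **Area tables**: species area = response × amount × proportion ×
  lognormal(CV). Proportions default to {10, 30, 15, 45}% for GalGalNAc,
  NeuAcGalGalNAc, Gal(NeuAcGalNAc), NeuAcGal(NeuAcGalNAc): disialylated
  core 1 dominant and GalGalNAc minor, consistent with a CHO-produced
  sialylated product whose GalGalNAc peak fell below the detection limit
  in the smallest samples. The published figures do not print the
  percentages, so these are realistic placeholders, not reproductions.
  CV = 1% (replicate RSD was < 1.5%, n = 6), amounts {10, 20, 40, 60, 100}
  µg with a 40 µg reference, peeling fraction 3% (the cited minimal peeling
  level), deacetylation 1% ("trace").

Green tests on this world establish that the *formulas and algorithms* are
correct: the digestion oracle equivalence, fragment complementarity
(b+y = c+z = M+2H⁺ to 1e-6 Da), exact recovery of planted proportions at
CV 0, R² = 1 and recovery = 100% on noiseless dilutions, ≥0.9 planted-site
recall with zero false localizations at 5 ppm/50% coverage, and exact
identification of all 16 inventory glycopeptides from noiseless spectra.
They do **not** establish instrument-bound results: real replicate RSDs,
real recovery ranges (70–130%), chromatographic behavior, co-elution,
chimeric spectra, or in-source decay are outside the simulation.

## Numerical choices and degenerate inputs

- Observed (instrument-printed) values are compared at ±0.02 Da or 10 ppm,
  whichever is larger; theoretical printed values at printed precision.
- Desialylation of a pure-NeuAc composition yields an empty composition:
  rejected downstream with a warning rather than silently dropped.
- `digest_operator()` with an empty site set returns an empty table; the
  protein-N-terminal leftover (no glycosite at its start) is emitted
  flagged as a non-glycopeptide.
- Peak matching with an empty spectrum returns an empty match table (not an
  error); equal-|ppm| ties go to the higher-intensity peak.
- All randomness sits behind one integer seed per ground-truth object;
  identical truth objects produce byte-identical MGF/CSV output.

## Known limitations

- Composition-level glycan calls only: no linkage/anomericity, no GU
  calibration, no structure elucidation beyond retention-time isomer labels.
- Closed search against enumerated candidates; no decoy/FDR machinery.
- Fragment generation ignores variable modifications (precursor arithmetic
  supports them).
- Site occupancy/stoichiometry is not quantified, matching the scope of the
  underlying workflow.
- The published z-ion annotations mix conventions; three printed values are
  not reproducible under any single convention and are documented rather
  than fitted.
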