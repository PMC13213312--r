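# sumoscape

Landscape analysis of human protein SUMOylation from mass-spectrometry
evidence.

SUMO (Small Ubiquitin-like MOdifier) proteins are conjugated to substrate
lysines through an isopeptide bond. After proteolysis, a short SUMO-derived
remnant (QQTGG, pyro-QQTGG, NQTGG, DVFQQQTGG or the diGly tail shared with
ubiquitin) stays attached to the modified lysine and is searched as a
variable modification. Large-scale reanalysis of public SUMO proteomics
datasets poses three statistical problems that this package addresses as a
tested, reusable pipeline:

1. **Spectral preprocessing.** Fragmentation of the SUMO side chain floods
   MS2 spectra with remnant fragment ions that search engines cannot
   score. `sumoscape` counts spectra carrying diagnostic remnant peaks
   (relative intensity > 0.1) and, for datasets where more than 30% of
   MS2 spectra are affected, strips those m/z windows before searching.
2. **False localization rate (FLR) control.** Even a correct
   peptide-spectrum match (PSM) can place the modification on the wrong
   residue. Searching the modification additionally on alanine — a residue
   that cannot be SUMOylated — gives a decoy channel: ranking collapsed
   peptidoform-sites by localization probability, the running ratio of
   cumulative decoy-alanine to target-lysine sites estimates the FLR,
   `FLR(r) = D_r / T_r` (monotonized). Sites below 5% FLR enter the build
   and are tiered **Gold** (FLR < 1% in ≥ 2 datasets), **Silver** (< 1% in
   exactly 1) or **Bronze** (otherwise, but < 5%).
3. **Downstream characterization.** Disorder enrichment via the odds ratio
   `OR = (pDis_obs / pDis_exp) / (pOrd_obs / pOrd_exp)`, solvent
   accessibility (rASA ≥ 20% = exposed), secondary structure, disease
   variant positional profiles, phosphosite proximity (±10 window),
   flanking-residue enrichment (per-1000 normalization against the
   proteome), motif-x style iterative motif extraction (binomial
   overrepresentation, occurrence ≥ 25, p ≤ 1e-6), and SUMO–ubiquitin
   crosstalk partitioning.

Every stage runs on synthetic data generated by the built-in simulator
(`sim_config()` / `gen_dataset()`), which plants sites with configurable
motif adherence, disorder bias, mislocalization rate and decoy-alanine
hits, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(sumoscape)

cfg <- sim_config(seed = 42, n_proteins = 60, n_sites = 300, epsilon = 0.05)
d   <- gen_dataset(cfg)

# PSM FDR -> site expansion -> peptidoform-site collapse -> decoy FLR
res <- flr_pipeline(d$psms, footprint_mass_2dp = 471.21)

# per-dataset site tables -> tiered build
per_ds <- lapply(split(res$site_rows, res$site_rows$dataset_id), function(r)
  protein_site_table(decoy_flr(collapse_peptidoform_sites(r))))
build <- assign_tiers(per_ds)
table(build$tier)
tier_set_flr(build)
```

Output:

```
Bronze   Gold Silver
    37    182    100

                 set n_target n_decoy flr_pct
1               Gold      182       0    0.00
2        Gold-Silver      279       3    1.08
3 Gold-Silver-Bronze      296      23    7.77
```

The 300 planted sites are recovered into the three tiers; the recalculated
set-level FLR (percentage of decoy-alanine sites per lysine site) rises as
lower-confidence tiers are included, exactly the behavior the tiering is
designed to expose. Downstream:

```r
gold <- build[build$tier == "Gold" & !build$is_decoy, ]
fl   <- extract_flanks(gold, d$proteome)
adherence_rate(fl, 2, "E")        # 0.346  - core KxE-motif adherence
proportion_disordered(...)        # 0.522  - Gold sites in disordered regions
disorder_odds_ratio(0.52, 0.48, 0.322, 0.678)  # 2.3 - vs proteome background
```

The simulator planted 29% KxE adherence (plus naturally occurring E at +2)
and a disorder odds ratio of 2.4 over a 32.2% background; both are
recovered within sampling error.

## Package layout

| module | contents |
| --- | --- |
| `R/chem.R` | monoisotopic mass table, remnant delta masses, fragment ions, ppm windows |
| `R/spectra.R` | diagnostic-peak counting/stripping, minimal mzML I/O |
| `R/digest.R` | Lys-C / Asp-N / Glu-C in-silico digestion, peptide FASTA, reversal decoys |
| `R/flr.R` | PSM FDR, site expansion, peptidoform-site collapse, decoy-alanine FLR |
| `R/build.R` | dataset merging, Asp-N C-terminal rule, Gold/Silver/Bronze tiering, non-SUMO set |
| `R/features.R` | disorder, rASA, structure, variants, PTM proximity, flank enrichment, test statistics |
| `R/motifs.R` | 15-mer extraction, motif-x, classification, hierarchy, retention rules |
| `R/crosstalk.R` | SUMO/ubiquitin overlap partition and per-category analyses |
| `R/synth.R` | synthetic proteome / sites / PSM / spectra / annotation generators |

A thin command-line front end is installed under `inst/cli/sumoscape.R`.
See `vignettes/sumoscape-methods.Rmd` for the statistical model, the
design decisions and the limits of what the synthetic world establishes.
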