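---
title: "sumoscape: models, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sumoscape: models, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoscape)
```

# The problem

SUMOylation attaches a small ubiquitin-like protein to substrate lysines.
Proteolysis leaves a short remnant tail on the modified lysine whose mass
is searched as a variable modification; which tail depends on the SUMO
paralog and the protease protocol (QQTGG and its pyroglutamate form for
tryptic SUMO-2, NQTGG for SUMO-3 mutants, DVFQQQTGG for endogenous
SUMO2/3 with Lys-C/Asp-N, and the diGly tail shared with ubiquitin for
Lys-C/Glu-C protocols). Assembling a reference set of human SUMO sites
from heterogeneous public datasets needs consistent answers to three
questions: is the spectrum usable, is the peptide right, and is the
*residue* right? This package implements the full chain, from remnant
mass arithmetic to downstream sequence/structure statistics, with a
synthetic-data module that makes each stage testable in isolation and
end to end.

# Mass arithmetic and spectral prefiltering

Remnant delta masses are plain sums of monoisotopic residue masses: the
isopeptide attachment adds no water, and pyroglutamate formation at an
N-terminal glutamine removes one ammonia
(`remnant_delta_mass("QQTGG", pyro = TRUE)` = 454.18121 Da). Residue
masses are fixed 5-decimal standard values; tests verify them against an
independent elemental-composition oracle and against the published search
parameters at 1e-4 Da.

Because search engines cannot score ions from fragmentation of the SUMO
side chain, spectra rich in remnant fragment ions depress identification
rates. The diagnostic ion set per footprint is the singly charged b, y
and a series plus the intact remnant `[M+H]+`; which ions the original
online calculator emitted is not documented, so the set is configurable
(`remnant_diagnostic_ions()`). A spectrum counts as diagnostic when any
peak inside a ppm window around these ions exceeds 0.1 of the base peak
intensity (strict inequality, per the stated counting rule). Datasets
with a pooled diagnostic fraction above 30% (strict) are stripped:
removal is by m/z match only, with no intensity threshold — the counting
threshold exists to *estimate prevalence*, while removal is conservative.
Window boundaries are closed on both ends, again the conservative choice.
The ppm used for the windows defaults to each dataset's precursor
tolerance, the (unusual) documented choice, and is overridable.

mzML I/O is a minimal subset (ms level, precursor m/z, uncompressed
64-bit float peak arrays) written and parsed with `xml2`: no mzML-capable
R package is available in the supported dependency set, and the pipeline
touches nothing else in the format. Foreign cvParams are not preserved;
files written by `write_mzml()` round-trip exactly.

# In-silico digestion

Multi-enzyme protocols with up to eight missed cleavages exceed common
search-engine digestion limits, so peptide databases are enumerated here.
Lys-C is modelled as cleaving after K unless followed by P — proline
suppression is kept although Lys-C conventionally cleaves K-P, because
the documented protocol states it. Leader-methionine removal emits each
N-terminal peptide additionally without the initial M; proteins lacking
any cleavage site contribute their whole sequence. Secondary digestion
(before D/E for Asp-N, after D/E for Glu-C) counts missed cleavages
within its own stage, and Met-removed variants pass through the secondary
stage as ordinary peptides. Duplicate peptides collapse on (sequence,
parent, start), so identical sequences from homologous proteins are
retained per parent. Correctness is established against a brute-force
oracle that enumerates every substring and checks the cleavage rule
directly. Reversed-sequence decoys are provided as plumbing; generating
information-preserving decoys (de Bruijn style) is out of scope.

# FLR estimation

The decoy amino acid method searches the SUMO modification on alanine as
well as lysine. Alanine cannot carry SUMO, so alanine "sites" count
false localizations. The stages are:

1. **PSM FDR.** Target-decoy competition on search scores; q-values are
   the monotonized running decoys/targets ratio; targets with q < 0.01
   are retained (decoys drop out of the output).
2. **Site expansion.** Each retained PSM contributes one row per
   candidate site whose modification mass matches the footprint mass
   rounded to two decimals.
3. **Peptidoform-site collapse.** Redundant spectra observing the same
   site within the same peptidoform are combined:
   `p = 1 - prod(1 - p_i)`, capped at 0.999999. The published pipeline
   cites a binomial adjustment without printing the formula; this
   combiner rewards redundant observations as intended, the cap prevents
   a single saturated probability from freezing the ranking, and the
   combiner is pluggable (`collapse_peptidoform_sites(combiner = )`).
4. **Decoy FLR.** Sites ranked by combined probability; raw FLR at rank
   r is `scale * D_r / T_r`; ties share the worst FLR of their group and
   the curve is monotonized by a cumulative minimum from the worst rank
   upward. At probability ties decoys sort first (conservative). The
   scale factor defaults to 1.0 — no lysine:alanine frequency correction
   — because the published recalculated set-level FLRs equal unscaled
   decoy/target ratios; a frequency-ratio scale is available as
   configuration.

Sites map to proteins one row per matched protein; shared peptides
multi-map, and build-level site identity is (accession, 1-based
position).

# The build

Parallel footprint/digestion searches within one dataset merge first
(union on coordinates, minimum FLR), so a site seen by two searches of
one dataset counts once toward tiering. "Two or more datasets" counts
distinct dataset identifiers. Tiers: Gold = FLR < 1% in ≥ 2 datasets,
Silver = in exactly one, Bronze = neither but minimum FLR < 5%; at ≥ 5%
the site is excluded. The tier partition is re-derived in tests by brute
force from the per-dataset FLR maps.

For Asp-N protocols, a SUMO site on a peptide C-terminal lysine is kept
only when the *following* protein residue is D or E. The protocol
description says "preceding residue" in one place and "following
residue" in another; the following-residue reading is implemented, as it
is the one consistent with Asp-N cleaving N-terminal to D/E (a C-terminal
lysine followed by D/E arises from cleavage, not from the peptide's own
sequence). A lysine at the protein C-terminus has no following residue
and is dropped.

Set-level FLR is recalculated per cumulative tier set as
`100 * n_decoy / n_target` (2 dp). The non-SUMOylated reference set takes
every lysine covered by an FDR-retained peptide and removes any lysine
with candidate-site evidence in any dataset at any FLR — the strictest
reading of "not detected at any threshold".

# Feature statistics

Residues with disorder score > 0.5 (strict) are disordered; rASA ≥ 0.20
is exposed. The disorder preference odds ratio is
`(pDis_obs / pDis_exp) / (pOrd_obs / pOrd_exp)`; it is undefined (and
rejected) when any proportion is 0 or 1. Secondary structure assigns one
element per lysine with fixed priority helix > strand > turn >
coiled-coil; overlaps are rare and the priority is arbitrary but stable.
Variant positional profiles report disease-associated proportions per
relative position (−2..+2); zero-denominator positions are *missing*,
never zero, to avoid biasing profiles. Phosphosite proximity counts PTM
sites within ±10 residues; the center (offset 0) is excluded for
phosphosites (S/T/Y cannot coincide with the lysine) and included for
ubiquitin, giving 20- and 21-position profiles respectively.
Flanking-residue enrichment normalizes per-position counts to 1000 over
21 categories (20 residues + X for off-terminus positions) and divides
by the proteome's per-1000 values.

Multiple-testing families follow the published analysis exactly:
Bonferroni with the stated divisors for flank analyses (0.05/84; the
protease-stratified family uses the *computed* 0.05/252 = 0.000198 — the
printed 0.00012 is inconsistent with its own divisor and is treated as a
misprint), and Benjamini–Hochberg with the stated family sizes (15 for
variant positions, 20 or 21 for positional profiles). The Mann–Whitney
comparison of rASA distributions is a contract over the standard routine,
asserted in tests against exact small-sample permutation enumeration, as
is Fisher's exact test against hypergeometric enumeration.

# Motif extraction

Foreground windows are K-centered 15-mers padded with X at protein
termini and deduplicated; the background is every proteome lysine,
*not* deduplicated. The iterative extraction scores every
(offset, residue) pair by the exact binomial upper tail of its foreground
count against the background frequency at that offset (X never matches
and leaves frequency denominators), fixes the most significant pair
meeting the thresholds (occurrence ≥ 25, p ≤ 1e-6), reduces both pools,
and repeats; when no pair qualifies the motif is emitted, its matched
windows leave the foreground, and the background is restored in full —
standard motif-x behavior, recorded as a decision since the published
description does not specify it. Tie-breaking is deterministic: lowest
p-value, then highest count, then smallest |offset|, then lexicographic
residue. The binomial tail is evaluated in log space so selection stays
stable down to p ~ 1e-300. Motif classes follow fixed precedence (E at
+2 → KxE; E at −2 → ExK; D at +2 → KxD; D at −2 → DxK; else unique), and
hierarchy labels (parent/child/orphan) come from strict-subset relations
between fixed-position maps. The 0.5% retention rule rounds half-up —
the only rounding consistent with all three published thresholds (73,
105, 467).

# Crosstalk

Lysines from the SUMO and ubiquitin builds partition into SUMO-unique,
Ub-unique and SUMO–Ub overlap by coordinate set algebra. Both builds
enter at Gold–Silver–Bronze depth for the partition (matching the
published build-wide split), while proximity/positional profiles use
Gold-only sites; depth is a configuration knob with these defaults. The
per-category analyses reuse the feature operations, including the 15
pairwise variant tests (5 positions × 3 comparisons) under BH.

# The synthetic world

The generator states one world and the tests measure it; its parameters
were chosen from the reported quantities *before* any test was run and
are not tuned:

- residue frequencies approximate the human proteome (notably K 5.7%,
  A 7.0% — near-equal, the situation the decoy method relies on);
- planted motif mixture defaults to the Gold-set adherence rates
  (KxE 0.29, ExK 0.127, KxD 0.063, DxK 0.103);
- disorder background 0.322 and planted-site odds 2.4, giving ~53%
  disordered sites via `p = OR*r/(1 + OR*r)`, `r = 0.322/0.678`;
- diagnostic spectra fraction 0.65 at relative intensity 0.5;
- disease-variant proportions 0.057 background, 0.066 at the lysine and
  its −2 position; phosphosite excess at −2/+1/+5.

**Mislocalization model.** Each PSM reports the correct lysine with
probability 1 − 2ε, a wrong lysine with probability ε and the decoy
alanine with probability ε. Two deliberate choices make the planted
truth and the decoy estimate comparable: (i) mislocalization is only
applied when the peptide contains both an alanine and an eligible wrong
lysine, keeping the two error rates exactly balanced — realizing the
decoy method's core assumption rather than approximating it through
residue counts; (ii) wrong-lysine candidates exclude genuinely
SUMOylated lysines, because an error that lands on a real site is
indistinguishable from true evidence and is invisible to any FLR
estimator. Peptides are ±10-residue windows around the planted site
rather than strict Lys-C products, so candidate residues of both classes
are usually available. Correct assignments draw localization
probabilities from Beta(12, 1.5), incorrect from Beta(2, 4); the
published pipeline constrains only the resulting FLR behavior, not the
score model.

**What a green test does and does not establish.** The synthetic world
has i.i.d. residues, no homologous proteins (so no shared-peptide
multi-mapping ambiguity, and none of the zinc-finger-type motif
inflation that ambiguity causes in real data), no correlated noise
between datasets, no retention-time or isotope structure, and
localization probabilities from a clean two-component mixture. Recovery
of planted FLR, tiers, motif mixture and disorder odds demonstrates that
the *estimators are consistent in a world that satisfies their
assumptions* — it does not validate the assumptions against real
spectra, which is what the decoy channel itself is for.

# Numerical choices and degenerate inputs

- FLR and q-values carry full precision; percentages round to 2 dp only
  at report time.
- Ranks before the first target have FLR 1; an empty decoy channel gives
  FLR 0 with (for the FDR stage) a warning.
- `flr_threshold()` and tier cutoffs use strict inequalities throughout;
  boundary sites (FLR exactly 5%) drop.
- Empty peak lists are valid spectra; stripping every peak keeps the
  spectrum.
- Proportions with zero denominators are missing, never zero.
- `retention_threshold()` rounds half-up with a floor of 1.
- Seeds: every generator derives an independent stream from the master
  seed, so components can be regenerated separately and byte-identically.

# Known limitations

- The published build's absolute site counts (Table-scale, tens of
  thousands of sites over 13 datasets) are not reproducible at desk
  scale; the acceptance targets therefore cover the printed set-level
  arithmetic, and the statistical machinery is validated on synthetic
  data.
- The exact published binomial-adjustment formula for redundant PSM
  evidence is not public; the implemented combiner is one member of the
  intended family and is pluggable.
- mzML support is a functional subset, not a general reader.
- De Bruijn decoy generation, search-engine scoring, disorder/structure
  prediction and GO enrichment are consumed as inputs, not reimplemented.
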