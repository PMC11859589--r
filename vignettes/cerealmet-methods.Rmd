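---
title: "Methods: rule-based glycoside annotation and comparative panel analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based glycoside annotation and comparative panel analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerealmet)
```

`cerealmet` packages two things: a fragmentation grammar for annotating
benzoxazinoid and flavonoid glycosides from MS/MS spectra, and the
comparative analytics used to contrast metabolite panels across a set of
species. This vignette is the package's account of the underlying methods:
the models, their assumptions, the tunable parameters, and the design
choices taken where more than one convention was defensible.

## Mass arithmetic

All annotation rests on exact-mass arithmetic over molecular formulas.
Formulas are element-count maps supporting element-wise addition and
subtraction; subtraction that would drive a count negative is an error,
which is how the engine guarantees that a fragmentation rule only removes
atoms the precursor actually contains. Monoisotopic masses come from a
bundled principal-isotope table (C 12, H 1.0078250319, N 14.0030740052,
O 15.9949146221, ...); ion m/z uses the proton mass 1.00727646677 Da.
Two deliberate simplifications:

* only singly protonated/deprotonated species are modeled — `[M+H]+` and
  `[M−H]−`; multiply charged ions and other adducts are out of scope;
* the electron mass is not tracked separately: the resulting bias is
  below 1 mDa, an order of magnitude under the matching tolerance.

Nominal (integer) masses are *rounded monoisotopic* values (half away
from zero), not integer-unit sums. This matters: it is the convention
under which the familiar diagnostic fragments of this chemistry come out
at 134, 164, 166, 153, 120, 150 and 90 Da.

## The fragmentation grammar

The rulebase (a YAML file; `defaultRulebase()` loads the packaged one)
declares aglycone skeletons and substituent residues.

**Aglycones** carry a formula, a compound class, supported polarities,
a list of characteristic neutral losses, and optional absolute fragments.
The packaged rules cover the four benzoxazinoid skeletons in negative
mode — the lactams HBOA and HMBOA losing CO, CH2O2 and 2CO; DIBOA losing
CH2O2; DIMBOA losing CO2 and CH2O2 — and four flavones (apigenin,
luteolin, tricetin, tricin) in positive mode with the 5,7-dihydroxy
A-ring retro-Diels–Alder fragment at nominal m/z 153.

**Substituents** are glycoside building blocks with one of three linkage
semantics: `O` (cleavable; forms Y ions), `C` (carbon–carbon linked;
never fully cleaved, fragments by cross-ring losses — C4H8O4/C5H10O5,
nominal 120/150, for a C-hexose; C3H6O3/C4H8O4, nominal 90/120, for a
C-pentose), and `mod` (a retained modification; methylation). Sugar
identity is deliberately reported only at the hexose/pentose/deoxyhexose
mass level — MS cannot distinguish glucose from galactose — with trivial
names (glucose, rhamnose, ...) accepted as aliases on input. Methylation
is a substituent so that the methylated tricetin series (tricin and its
4′-methylated product trimethoxytricetin) is reachable from the tricetin
and tricin skeletons.

### Annotation

Given a spectrum with precursor m/z and polarity, for every
polarity-compatible aglycone the engine decomposes the residual mass
(precursor minus aglycone ion) into substituent multisets by exhaustive
bounded search (`decomposeNeutralLoss()`): at most `max_substituents`
residues (default 3), per-residue multiplicity caps from the rulebase,
and at most one C-linked sugar per hypothesis. The tolerance is
interpreted in ppm of the precursor m/z. Expected fragments for each
hypothesis are computed *from formulas*, never chained from observed
peaks, so errors do not propagate; each expected fragment is matched to
the nearest unused peak within the tolerance.

Ranking is lexicographic: most matched characteristic fragments, then
fewest substituents (parsimony), then smallest |precursor ppm|, then an
alphabetical tie-break that makes the order total and deterministic.
Two scoring subtleties are deliberate:

* the Y0 ion counts as evidence only when it differs from the precursor
  (i.e. at least one cleavable substituent exists); otherwise a C-linked
  hypothesis of identical mass would collect a meaningless self-match on
  the precursor peak and tie with the O-linked reading;
* at equal mass, decomposition order prefers the O-linked reading of a
  neutral loss over the C-linked one — a residue observed as a *complete*
  neutral loss has, by definition, cleaved.

One ambiguity in the underlying chemistry literature deserves a flag: the
characteristic lactam losses are sometimes described relative to an
[M−OH]− species of HBOA/HMBOA. The engine applies them to the glycoside
Y0 ion ([aglycone − H]−), which is the reading consistent with the
worked HMBOA-acetyl-hexose example (Y0 194.046 → 166.051 → 138.056); the
alternative is not modeled.

The default tolerance of 10 ppm (precursor and fragments alike) was
chosen to cover quadrupole-TOF accuracy with margin; the largest
deviation across the two bundled worked examples is ≈ 6.7 ppm. It is a
parameter, not a constant.

## QC and feature filtering

`filterFeatures()` retains a feature iff all three strict inequalities
hold: max sample height / blank height > 5 (a zero blank passes), max
height > 500 counts, and S/N > 10. The height criterion uses the maximum
across samples deliberately: on a multi-species panel a metabolite
present strongly in a single species must survive filtering. Background
subtraction is realized as the blank-ratio test only — feature tables
carry no blank spectra to subtract. `qcCvFilter()` keeps metabolites
whose QC-injection CV (sample sd / mean) is ≤ 30%; decisions are
invariant under rescaling a metabolite's values. Replicates are averaged
arithmetically per crop with non-detected values as zero. MS2 spectra are
paired to features (`buildMS2T()`) within 10 ppm and 0.2 min by default —
the pairing tolerances are method parameters with no canonical value —
each spectrum linking to the candidate minimizing |ppm|.

## Comparative statistics

Presence is binary: abundance > 0 after QC, with no detection-limit
modeling. Shared, species-specific (present in exactly one species) and
species-missing (absent from exactly one) sets follow directly. The
per-class dispersion statistic is the coefficient of variation of the
class's nine detection proportions, `100·sd/mean` with the **sample
(n−1) standard deviation**. The convention matters: a class detected at
any equal proportion in exactly 3 of 9 species scores exactly 150% under
the sample sd (population sd would give ≈ 141%), and 150% brackets the
≈ 151% reported for real benzoxazinoid panels whose 3-species pattern is
only approximately equal. The statistic is scale-invariant in the common
proportion, which the tests exercise directly.

## Abundance analytics

PCA operates on log2-transformed abundances (pseudocount 1), species as
observations, centered but not variable-scaled — the log2 transform is
the only scaling applied. Clustering operates on row Z-scores of the
log2 data: Euclidean distance, Ward ("ward.D2") agglomeration, cut into
k = 9 clusters (one per crop). Neither linkage nor metric has a canonical
choice for Z-scored heatmap clustering; Ward/Euclidean is the standard
deterministic default and both are arguments. Constant rows cannot be
Z-scored and are dropped with a message. Cluster labels are relabeled by
smallest member id, so the partition is invariant under row permutation;
each cluster is attributed to the species with the highest mean Z-score
over its members (`cropOfCluster()`), a choice made here in the absence
of any canonical mapping rule.

Composition tables cross-tabulate classes against clusters and flag
cells holding at least 20% (`*`) or 40% (`**`) of a class, using the
class total as denominator. The thresholds are *inclusive* — a cell at
exactly 20.0% is flagged — because reference distributions of this kind
flag 6/30 = 20.0% cells; note that published tables of this kind are not
always consistent with any single threshold rule, and the packaged
distribution is reproduced under the class-total convention without
silently editing its flags.

Enrichment is the one-sided upper-tail hypergeometric probability
P(X ≥ k) with cluster size n, pathway size K and background N (all
metabolites carrying a pathway mapping, by default), computed via
`stats::phyper`. No multiple-testing correction is applied by default —
raw p-values of the order 0.1 are themselves informative at n = 9 crops —
with Benjamini–Hochberg available behind a flag.

## Pathway graphs

Pathway graphs are small DAGs whose edges are labelled reactions flagged
`established` or `proposed`. Proposed edges must be re-derivable from
node formulas: `proposeStep()` returns a reaction label iff the child
minus parent elemental difference equals exactly one catalog delta
(hexosylation +C6H10O5, pentosylation +C5H8O4, rhamnosylation +C6H10O4,
acetylation +C2H2O, methylation +CH2, hydroxylation +O). Deltas are
additions, so a label in one direction implies none in the reverse;
hexose and rhamnose additions are distinguished by exact elemental
delta, not nominal mass. The packaged benzoxazinoid graph contains the
core enzymatic route (enzyme names are edge labels only, never computed
with) plus the eight detected glycosides, the four single-step
glycosylation/acetylation extensions carried as proposed edges; the
flavonoid graph is at subclass resolution with generic O-/C-glycoside
extensions. Abundance mapping reports each quantified node's per-species
abundances and maximal species, with ties reported together.

## The synthetic generator

`generatePanel()` draws a metabolite × species panel with known ground
truth, emulating the structure the analytics assume: 1131 metabolites in
18 classes over 9 species; a shared core of 530; species-specific counts
of 4–12 per crop (the per-crop values are inputs; one species' count is
not printed in the reference material and defaults to 8, a mid-range
choice); species-missing counts of 3–43; an 8-member benzoxazinoid-like
class restricted to exactly 3 species (equal detection, hence a class CV
of exactly 150%); remaining metabolites present in 2–7 species so they
can never collide with the planted set definitions. Every metabolite has
a home crop (quota-filled toward per-crop block sizes of 100–154) and
log-normal abundance elevated in that crop.

The abundance scale is expressed in detection-limit units: log2 baseline
4 ± 1.5 (i.e. detected metabolites sit ~16× above the detection floor)
with a home-crop elevation of 5 log2 units (~32×) and residual noise of
0.5 log2 units. The elevation is deliberately strong: the generator
emulates panels whose hierarchical clustering is dominated by
crop-enrichment blocks (home-crop Z ≈ +2.5, uniformly low elsewhere),
and with structural absence at the rates above, a weak elevation would
leave the absence pattern — not the home crop — as the leading clustered
structure. Under the defaults, 9-cluster recovery of the planted homes
reaches an adjusted Rand index ≈ 0.99.

What the generator does *not* emulate: chromatographic peak shapes,
isotope envelopes, matrix effects, censoring at a detection limit
(non-detection is a structural mask), correlated metabolite families, or
class-dependent abundance distributions. Passing tests therefore
demonstrate the correctness of the analytics on data satisfying the
stated structure, not instrument-level realism.

Randomness: every generator derives a stream seed from the single user
seed and a stream name, and runs under `withr::with_seed`, so
sub-generators are independent, reproducible, and leave the session RNG
untouched.

## Numerical and degenerate-input conventions

* CV with mean 0: all-zero QC rows are kept (nothing varies), zero mean
  with positive sd is dropped; all-absent classes raise an error rather
  than returning a 0/0.
* `decomposeNeutralLoss` of a ~zero loss returns the empty multiset; a
  clearly negative loss returns no decomposition.
* Empty spectra match no fragments; spectra without precursor m/z are
  rejected at annotation.
* Cluster counts k must lie in [1, #non-constant rows]; k = 1 returns the
  trivial partition.
* Ties: fragment matching consumes each peak at most once (nearest-ppm
  wins); abundance maxima report all tied species.

## Problem sizes used in the test suite

The suite runs the full 1131 × 9 panel through generation, comparative
analysis and clustering (a few seconds), the complete 216-case
annotation round-trip grid at 0 and 5 ppm noise, decomposition against a
brute-force enumerator over a 6-item catalog (~500 losses), and
enrichment against literal subset enumeration for backgrounds up to
N = 12 (200 random margin sets). These sizes were chosen to exercise
every code path with exact oracles while keeping a full run in well
under a minute.

## Known limitations

* The grammar covers the packaged chemistry (benzoxazinoid and flavone
  glycosides); flavonols, anthocyanins and other classes would need
  their own aglycone entries — the rulebase file format supports this
  without code changes.
* Positional isomers (e.g. 4′- vs 3′-methylation, glycosylation sites)
  are outside what MS-level mass arithmetic can claim and are never
  reported.
* Spectral-library cosine matching, retention-time prediction and MS1
  isotope scoring are out of scope; the engine is purely rule-based.
* The PCA variance fractions of a real panel depend on the raw feature
  matrix and are not reproducible from class-level summaries; the
  package asserts only structural PCA properties (ordering, orthogonality,
  rank-1 and isotropic behavior).
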