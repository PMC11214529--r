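---
title: "Methods: peptide-centric metaproteomics of glycan fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-centric metaproteomics of glycan fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoferm)
```

## The analysis problem

When a fecal microbial community ferments dietary fibers and host mucins in
sealed calorimeter vials, the questions are: who grew (community
composition), with what machinery (carbohydrate-active enzymes and central
fermentation pathways), and with what physiological outcome (biomass, gases,
short-chain fatty acids). Bottom-up metaproteomics answers the first two
from peptide-level mass-spectrometry evidence; isothermal microcalorimetry
and headspace/supernatant chemistry answer the third. `mucoferm` implements
the post-search analysis stack for this design — everything downstream of
the search engine's peptide tables — together with a synthetic-community
generator so that every stage can be validated against known ground truth.

## Peptide uniqueness and community composition

The quantification currency is the *taxon-unique peptide*. Every protein of
every candidate taxon is digested in silico with trypsin (cleavage
C-terminal to K/R, by default suppressed before proline; up to 1 missed
cleavage; peptide length 7–40), and the resulting peptide → (taxon, protein)
occurrence index defines, for any observed peptide and any rank r, whether
the peptide is *unique* (all occurrences collapse to one taxon at r),
*shared*, or *unmatched*. Composition per sample is then

$$a_{s,t} \;=\; \frac{\sum_{p \,\in\, U_t} I_{s,p}}{\sum_{t'} \sum_{p \,\in\, U_{t'}} I_{s,p}}$$

where \(U_t\) is the set of peptides unique to bacterial taxon \(t\) at the
chosen rank and \(I_{s,p}\) the summed intensity of peptide \(p\) in sample
\(s\). Shared and unmatched peptides never enter the quantification (they
are logged as QC counts); host (human, pig) intensity is reported as a
separate percentage and excluded from the bacterial simplex, mirroring how
host contamination is reported in fecal metaproteomes. Repeated rows for
one peptide in one sample — technical injections — are summed; the
combination rule across injections is not uniquely determined by practice,
and summation (equivalent to union for identifications) is the default.

Choices worth making explicit:

* **Cleavage rule.** "Trypsin" is read conservatively as the classic rule
  (no cleavage before proline); the permissive `trypsin/P` variant is a
  switch, since search engines differ.
* **I/L handling.** Isoleucine and leucine are isobaric; de novo evidence
  cannot distinguish them. Indexes used for de novo matching are built with
  I/L collapsed to a common symbol; closed-search quantification keeps them
  distinct. Both modes are exposed because published unique-peptide analyses
  rarely state which was used.
* **Peptide-level throughout.** Protein inference and protein groups are
  deliberately not modeled: composition is defined on peptides, which keeps
  the estimator simple and the oracle exact.
* **Non-standard residues** (B, Z, X, U, O) are rejected at load rather
  than expanded, so indexing is deterministic.

## De novo-guided database refinement

Large search spaces hurt sensitivity, so the pipeline refines the taxon
database from de novo evidence before the final search: de novo peptides
are filtered at average local confidence (ALC) ≥ 80 % (boundary inclusive),
matched against the index, and a taxon counts as *identified in a sample*
when at least one species-unique peptide from that sample hits it (the
threshold is exposed as `min_specific_peptides`, because "identified" admits
stricter readings). Retention then applies, in order: (i) kingdom must be
Bacteria; (ii) some substrate group must contain identifications in ≥ 3 of
its samples; (iii) taxa reported by 16S rRNA sequencing are added back.
Host proteomes are always appended. The "< 3 samples per substrate group"
phrasing admits two readings — removal when *no* group reaches 3 (our
default, `group_rule = "any"`) or when *any* group falls short
(`group_rule = "all"`); the default is the permissive reading, the strict
one is a switch. 16S additions bypass the count rule by construction, and
16S taxa with no resolvable proteome are reported as unresolved rather than
silently dropped.

## Functional mapping

CAZyme annotation consumes per-tool hit tables (HMM-profile, alignment, and
peptide-pattern tools, as produced by the dbCAN family of annotators) and
retains a (protein, family) pair only when at least two distinct tools
report that exact family — duplicate reports by one tool count once.
Sulfatase annotations come from a single catalog and pass through the same
machinery with an effective threshold of one, flagged `sulfatase` so
downstream consumers can treat them separately.

Metabolic mapping matches observed peptides to reference enzyme sequences
for key fermentation reactions: a peptide matches an enzyme iff it is among
the enzyme's tryptic products under the index parameters (a
substring-anywhere mode exists for sensitivity checks). The *enzyme copy
number* of a (taxon, reaction, sample) is the count of distinct matching
peptide sequences — counts, not intensities, which is the literal reading
of "sum of matching peptides". Taxa roll up into eight metabolic guilds
(Butyric, Akkermansia, Bifido, Bacteroides, Enterobacteria,
Lachnoclostridium, Asaccharolytic, Succinivorans); group matrices are exact
sums of member-taxon matrices, and per-condition means ± SD across
replicates are computed when a design is supplied. The packaged default
group map (cyclic assignment over synthetic taxa) is a stand-in for curated
genome-based assignments and is labelled as such; real analyses load a
curated TSV map.

## Culture physiology

* **Biomass from heat.** Accumulated heat is the trapezoidal integral of
  the heat-flow channel (μW·h → J, × 3.6 × 10⁻³); dry weight is
  Q / 4000 J g⁻¹, the standard anaerobic heat yield. Integration error
  against the closed-form logistic curve is < 1 % at 5-minute sampling.
* **Dissolved gases.** Henry's law `c = Hcp*·p` with a pH-dependent
  effective constant: for CO₂,
  `Hcp* = Hcp (1 + Ka1/[H⁺] + Ka1·Ka2/[H⁺]²)` (bicarbonate + carbonate);
  H₂S analogously with its first dissociation; H₂ and CH₄ are
  pH-independent. The shipped constants (CO₂ 3.3 × 10⁻² M atm⁻¹, pKa 6.35 /
  10.33; H₂ 7.8 × 10⁻⁴; CH₄ 1.4 × 10⁻³; H₂S 0.1, pKa₁ 7.0; 25 °C) are
  standard compilation values and fully user-overridable; a van 't Hoff
  temperature correction with tabulated solution enthalpies is available
  and off by default.
* **Normalization.** Metabolite concentrations (mM) are converted to
  mmol per g dry weight via the 2 mL working volume; zero dry weight yields
  an explicit undefined (`NA`), never an infinity.
* **Mucin-proline propionate bound.** Mucin backbones are proline-rich;
  proline can be fermented Pro → Glu → GABA → succinate → propionate at up
  to 1 mol/mol. With 0.5 g L⁻¹ protein-equivalent mucin, ~10 mol-% proline
  and a mean residue mass of 105 g mol⁻¹ (typical for a Pro/Thr/Ser-rich
  sequence; the value is a parameter), the bound is
  1000 × (0.5/105) × 0.10 ≈ 0.48 mM, i.e. 0.5 mM at one decimal. The
  protein-equivalent concentration is an explicit input: glycosylated mucin
  preparations have a much higher total mass than protein mass, and the
  function makes no attempt to convert one into the other.

## Community statistics

Alpha diversity is Gini–Simpson, `1 − Σ pᵢ²` (the behavior of the standard
ecology implementations; the raw concentration is a flag). Beta diversity
is Bray–Curtis, computed through vegan. Ordination is classical principal
coordinates (double-center −D²/2, eigendecompose, scale by √λ); negative
eigenvalues from the non-Euclidean Bray–Curtis are reported but never used
for coordinates, and outputs are labelled PCoA. Group comparisons use the
tie-corrected Kruskal–Wallis test with a χ² reference, Dunn's two-sided
post hoc z-tests with the pooled tie correction, and Benjamini–Hochberg
step-up adjustment with the family defined as all pairwise comparisons of
one response variable.

A calibration note: with triplicate groups (the default 11 × 3 design) the
discrete rank distribution makes the χ² reference of Kruskal–Wallis
markedly conservative — the empirical level at α = 0.05 is near 0.015, a
property of the test itself, reproducible with the stock R implementation
on plain Gaussian noise. The package's null-calibration test therefore
checks two things: that the level is ≈ α (± 0.02) at a replication level
where the asymptotic reference applies (4 groups × 30 replicates), and
that at triplicate scale the level never exceeds α. Practically this means
p-values from triplicate designs are valid but conservative.

## The synthetic community generator

The generator emulates the study design — substrate groups × triplicates,
a multi-taxon bacterial community, human/pig background, de novo evidence
with ALC scores, logistic-growth heat curves, and SCFA/gas/pH tables —
with every distribution chosen for testability:

* **Sequences** are i.i.d. over the 20 residues with a configurable
  combined K/R frequency (default 0.1), so tryptic fragment lengths follow
  a geometric law and peptide counts have analytic expectations.
* **Sharing** is created by copying proteins between taxa on a ring: each
  taxon donates and receives exactly `s = round(f/(1+f)·P)` proteins, which
  makes the distinct-peptide shared fraction equal the target `f` and —
  crucially — gives every taxon the same expected unique-peptide fraction,
  so the unique-peptide estimator is unbiased under the noiseless
  condition and recovery can be tested at ± 0.02 absolute. Consecutive
  taxa pair into genera, so ring sharing produces both within- and
  cross-genus shared peptides.
* **Observations** draw a taxon per row by its ground-truth weight (host
  with probability 3 %, matching the few-percent host share of real fecal
  metaproteomes), then a peptide uniformly from the taxon's digest;
  intensities are lognormal around a common mean (CV configurable, 0 =
  noiseless). The intensity law of real evidence tables is not published;
  lognormal is a stand-in, not a claim about deposited data.
* **ALC scores** are truncated-normal on [0, 100] (simple, bounded,
  parameterizable); de novo errors are single-residue substitutions at a
  configurable per-peptide rate, with I/L swaps always reachable.
* **Heat curves** are exact logistic-growth derivatives scaled by the
  4000 J/g yield, with closed-form accumulated heat for testing; the
  default grid is 64 h at 5-minute steps (769 points).
* **Chemistry** uses SCFA baselines of tens of mM with additive Gaussian
  noise, lognormal headspace pressures (non-negative by construction), and
  a pH shift of +0.7 for sole-mucin groups emulating proteolytic ammonia
  release. Group effects are additive and fully specified by the caller,
  so nonparametric tests have known signal (or exactly none).

What passing these tests does *not* show: real proteomes are not i.i.d.
strings (homology makes sharing block-structured), real intensities span
orders of magnitude with peptide-specific response factors, and real de
novo errors are position- and mass-dependent. The generator validates the
*bookkeeping and estimators*, not search-engine behavior.

## Problem sizes and determinism

Default test and demo sizes — 12 taxa × 30 proteins of mean length 300,
observation depth 2 000 per sample (50 000 for recovery checks), 500
replicates for level calibration, 20 random fixtures for oracle
equivalence — were chosen so the whole validation suite represents each
regime meaningfully while running in minutes on a laptop. Every stochastic
function takes an explicit seed and is byte-reproducible; the pipeline
derives per-stage seeds from one global seed and persists a resolved
configuration plus MD5 checksums for every output.

## Known limitations

* No protein inference, FDR modeling, match-between-runs or imputation:
  the package starts from table-level search output by design.
* Exact-match peptide-to-enzyme mapping: mutation-tolerant matching is out
  of scope (an I/L-collapsed and a substring mode are the only relaxations).
* The default metabolic-group map for synthetic taxa is a labelled
  stand-in; guild assignments for real communities must be curated.
* Henry constants ship at 25 °C; the van 't Hoff correction uses constant
  enthalpies and should not be extrapolated far from ambient temperature.
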