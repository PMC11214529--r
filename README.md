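# mucoferm

Post-search analysis of **fecal-community fermentation metaproteomics**: who
grew on which glycan, with which enzymes, and with what physiological
outcome. The package is written for microbiome researchers who have
table-level mass-spectrometry output (peptide observations, de novo calls,
CAZyme annotation hits) from in vitro fermentations of dietary fibers and
mucins, plus culture measurements (microcalorimetry heat curves, headspace
gases, short-chain fatty acids, pH), and want a reproducible, testable
pipeline from those tables to community profiles, enzyme copy numbers and
normalized physiology.

## What it computes

* **Peptide uniqueness index** — in-silico tryptic digestion (cleavage
  C-terminal to K/R, not before P; ≤ 1 missed cleavage; length 7–40) of
  taxon-labeled proteomes into a peptide → (taxon, protein) index; a
  peptide is *unique* at rank *r* when all its occurrences collapse to one
  taxon at *r*.
* **Community composition** — per sample, the relative intensity of
  unique peptides:
  *a*<sub>s,t</sub> = Σ<sub>p∈U<sub>t</sub></sub> I<sub>s,p</sub> /
  Σ<sub>t′</sub>Σ<sub>p∈U<sub>t′</sub></sub> I<sub>s,p</sub>,
  over bacterial taxa; host (human/pig) share reported separately. Rank
  rollups, replicate means, top-N + "other" summaries.
* **De novo-guided database refinement** — ALC ≥ 80 % filter, per-sample
  taxon evidence from species-unique peptides, retention rules (Bacteria
  only; identified in ≥ 3 samples of some substrate group; union with 16S
  taxa), and deterministic FASTA export.
* **Functional mapping** — ≥ 2-of-3-tool consensus CAZyme filter
  (single-source sulfatases flagged), peptide matching against reference
  enzymes for key fermentation reactions, enzyme copy numbers (distinct
  matching peptides) per taxon or per metabolic guild, mean ± SD per
  condition.
* **Culture physiology** — accumulated heat by trapezoidal integration
  (μW·h → J), biomass dry weight as Q / 4000 J g⁻¹, dissolved gases by
  Henry's law with pH-dependent effective constants
  (Hcp\* = Hcp(1 + Ka₁/[H⁺] + Ka₁Ka₂/[H⁺]²) for CO₂), metabolite
  normalization to mmol/gDW, and the stoichiometric upper bound on
  propionate from mucin proline.
* **Community statistics** — Gini–Simpson diversity, Bray–Curtis
  dissimilarity, principal-coordinates ordination, tie-corrected
  Kruskal–Wallis, Dunn's post hoc with Benjamini–Hochberg adjustment.
* **Synthetic community generator** — taxon proteomes with controlled
  cross-taxon peptide sharing, weighted peptide observations with host
  background, de novo tables with ALC scores, logistic heat curves with
  closed-form accumulated heat, and SCFA/gas/pH tables with injectable
  group effects — so the whole pipeline is testable against known ground
  truth. See `vignette("mucoferm-methods")` for the modeling choices.

## Worked example

```r
library(mucoferm)

proteomes <- generate_taxon_proteomes(n_taxa = 4, shared_fraction = 0.2, seed = 1)
hosts     <- generate_host_proteomes(seed = 1)
design    <- sample_design(groups = c("Xyl", "Xyl+PCM"), replicates = 3)
truth     <- community_truth(design, c(t01 = 0.4, t02 = 0.3, t03 = 0.2, t04 = 0.1))

index <- build_peptide_index(c(proteomes, hosts))
index
#> <peptide_index> 5526 distinct peptides over 6 taxa (missed cleavages 1, length 7-40, I/L collapse FALSE)

obs <- simulate_peptide_observations(proteomes, truth, depth = 5000,
                                     intensity_noise = 0.3,
                                     background_fraction = 0.03,
                                     hosts = hosts, seed = 2)
profile <- quantify_unique_peptide_profile(obs, index)
subset(profile, sample_id == "Xyl_r1")
#> # A tibble: 4 × 6
#>   sample_id taxon               rank    abundance n_unique_peptides valid
#> 1 Xyl_r1    Genus_01 species_01 species     0.399               663 TRUE
#> 2 Xyl_r1    Genus_01 species_02 species     0.304               584 TRUE
#> 3 Xyl_r1    Genus_02 species_03 species     0.196               452 TRUE
#> 4 Xyl_r1    Genus_02 species_04 species     0.101               280 TRUE
```

The estimated abundances (0.399, 0.304, 0.196, 0.101) recover the simulated
weights (0.4, 0.3, 0.2, 0.1) from unique-peptide intensity alone, despite
20 % peptide sharing and 3 % host background; the host share for this
sample, reported outside the bacterial simplex, is
`attr(profile, "host")` → 3.2 %.

```r
mucin_propionate_bound(protein_g_per_L = 0.5, proline_mole_fraction = 0.10)
#> [1] 0.4761905
```

— with 0.5 g/L protein-equivalent mucin at ~10 mol-% proline, at most
≈ 0.5 mM propionate can derive from the mucin backbone, which bounds the
mucin-protein contribution against measured propionate.

A full demo run (`run_pipeline(outdir = "demo")`) simulates an 11-condition
× triplicate fermentation screen, refines the database from de novo
evidence, profiles the community, maps enzymes and physiology, runs the
statistics, and writes every stage interface as TSV plus a checksummed
manifest.

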