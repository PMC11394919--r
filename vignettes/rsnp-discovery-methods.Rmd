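---
title: "Methods: regulatory-SNP discovery from allele-specific binding and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-SNP discovery from allele-specific binding and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpscan)
```

# Scope and model

`rsnpscan` implements a pipeline for identifying regulatory SNPs: promoter
variants whose alleles are differentially bound by active-chromatin marks
(allele-specific binding, ASB, from H3K4me3/H3K27ac ChIP-seq) and whose
target genes are differentially expressed between alleles
(allele-specific expression, ASE, from RNA-seq of the same individuals).
The input contract starts at per-individual allele-depth tables: read
alignment, genotyping mechanics and reference-bias removal via a
personalised "alternative genome" are upstream of the package and are
represented in the synthetic data by a bias switch (below).

The chain is: heterozygote calling from pooled assay counts; exact
binomial asymmetry tests per site and assay with Benjamini–Hochberg (BH)
control at 0.1; gene-level ASE aggregation; strand-aware promoter
construction (±1000 bp around every distinct TSS); intersection of
promoter ASB SNPs with ASE genes; and downstream characterisation
(catalog enrichment, differential expression, PPI topology).

## Assumptions

* Sites are biallelic SNVs; indels are out of scope.
* Read counts at a het site are exchangeable draws from the allele pool:
  the binomial test assumes no residual mapping bias (the dual-genome
  protocol's job) and no overdispersion. The second assumption is only
  approximately true in real data; see *Limitations*.
* ASB and ASE evidence is paired within an individual: a promoter ASB
  SNP needs ASE of its target gene in the *same* individual
  (`same_individual = TRUE`, the default; the cross-individual variant
  is available). Panel membership needs support in at least one
  individual (`min_individuals = 1`) — no replication threshold is
  imposed, matching a discovery-oriented design.

# SNP-level testing

`binomial_asymmetry_p()` implements the two-sided exact binomial p-value
in the minimum-likelihood convention (sum of all outcome probabilities
not exceeding the observed one, with a `1 + 1e-7` relative tolerance for
ties — the same convention as `stats::binom.test`), vectorised by
grouping sites on total depth. BH families are per (individual, assay):
the published description does not fix the family, and per-stratum
families keep ChIP and RNA evidence independent, matching the separate
ASB/ASE definitions; a global family is available via
`call_events(family = "global")`. Tied counts can never be significant;
the preferred allele is recorded as `ref` with a `tie` flag.

# Gene-level ASE: the pseudo-phasing Monte Carlo test

The gene-level ASE method named in the literature (MBASED) merges SNV
evidence by pseudo-phasing — assigning each SNV's major allele to one
nominal haplotype. We implement the 1-sample, phase-unknown core as a
Monte-Carlo test rather than the full beta-binomial meta-analysis
("MBASED-lite"): the statistic is the count-weighted aggregate
major-haplotype frequency `T`, and the null replicates re-apply the same
per-SNV maximisation to Binomial(total, 1/2) draws. This null
replication is the essential bias correction: `T` is inflated above 0.5
under balance, and any null that omits the maximisation is anti-
conservative. The p-value floor is `1/(n_sim + 1)` with `n_sim = 9999`
by default (a warning is issued below 999). An overdispersion parameter
`rho` can be folded into the null (default 0). Per-gene Monte-Carlo
seeds are derived from the sorted gene identifier, so results are
invariant to row order.

For a multi-SNV gene the default decision rule is the MBASED-lite test
with BH across multi-SNV genes within an individual (`rule = "mbased"`);
the alternative reading — ASE if any single SNV is significant — is
available as `rule = "any_snv"`. Single-SNV genes always inherit the
SNP-level decision. The gene-level significance threshold reuses
`p_adj < 0.1`; only the SNP-level threshold is fixed by the source
method description.

# The synthetic-data generator

`sim_config()` fixes the study conditions; every generator is
deterministic given the seed. The defaults emulate a nine-donor cohort
with two ChIP marks plus RNA:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 9 | cohort size of the emulated study design |
| `n_genes` | 200 | desk-scale chromosome; promoters never overlap neighbouring genes (gaps ≥ 2000 bp) |
| `mean_depth` | 60 reads/site/assay | chosen by a design power computation: the exact binomial test at the BH-effective per-test level (~0.02) has power 0.95 against the planted 0.75 imbalance at 60×, but only 0.67 at 30×; 60× is typical of ASB-grade coverage at het sites |
| `imbalanced_maf` | 0.75 | a strong but realistic allelic imbalance; more extreme values (e.g. 0.9) are mostly *removed by the heterozygote filter itself* (pooled minor fraction < 0.2), which would make end-to-end sensitivity a property of the filter, not the pipeline |
| `overdispersion_rho` | 0.002 | see *Numerical choices* |
| `imbalance_fraction` | 0.15 | fraction of genes planted as regulatory (ASB + ASE; their promoter sites are the true rSNPs) |
| `asb_only_fraction`, `ase_only_fraction` | 0.05 each | decoy genes exercising the intersection logic |
| `het_prob` | 0.7 | per-donor heterozygosity at a segregating site |
| `de_fraction`, `de_log2fc`, `nb_dispersion` | 0.1, 1.0, 0.05 | moderate negative-binomial DE signal |
| `n_modules`, `module_size`, `background_edge_p` | 3, 8, 0.02 | planted cliques on an Erdős–Rényi background |

The generator emulates: beta-binomial overdispersion; reference-mapping
bias as an additive shift of the read-level reference probability,
applied only in `mode = "naive"` (so the naive/dual-genome contrast
demonstrates why bias removal matters); multi-SNP genes and alternative
TSSs; catalogs with planted overlap enrichment via sampling weights; NB
counts with planted fold changes and log-uniform size factors; and PPI
graphs with planted dense modules.

It does **not** emulate: read-level alignment artefacts, linkage
disequilibrium between sites, isoform-level expression, genotype error,
or human-genome coordinates. Passing tests therefore demonstrate the
statistical machinery and the intersection logic under the stated
generative model — not robustness to alignment artefacts or LD structure
in real data.

# Numerical choices

* **Overdispersion default.** The asymmetry test is binomial by
  definition, so the realised false-discovery proportion depends on how
  overdispersed the simulated counts are: the variance inflation is
  `1 + (depth − 1)·rho`, which at 60× is 2.2 for `rho = 0.02` but 1.12
  for `rho = 0.002`. With the default 0.002 the planted-recovery
  condition (500 null + 50 planted sites, depth 60) keeps the realised
  FDP near the nominal 0.1; larger `rho` values are configurable and
  illustrate the binomial test's miscalibration on strongly
  overdispersed counts.
* **NB-Wald dispersion floor.** Per-gene method-of-moments dispersions
  at 10–20 samples/group are noisy, and a spuriously small estimate
  inflates the Wald statistic. Dispersions are floored at the dataset
  median of the per-gene estimates (and at 1e-8); this is still a pure
  moment estimator — there is no gene-wise shrinkage, Cook's filtering
  or fold-change moderation, which are deliberately out of scope.
* **Zero handling.** All-zero genes are excluded from DE (count kept in
  an attribute). A zero group mean gets a 0.125 continuity offset before
  the log-ratio. Empty 2×2 cells trigger Haldane's 0.5 correction for
  the odds ratio and Woolf CI; Fisher and χ² p-values use the
  uncorrected counts.
* **Rounding.** Reported percentages round half-up at one decimal
  (`report_fractions()`); published tables are not always consistent on
  this point, so the convention is fixed and documented.
* **Ties.** Hub selection keeps all nodes tied with the k-th value
  (inclusion over exclusion). AUC uses midranks (tie half-credit).
  MCODE seeds are ordered by score with node name as a deterministic
  tie-break.

# Network stage conventions

Betweenness and stress follow the unordered-pair, unnormalised
convention of the Cytoscape/CytoNCA tools: for node `v`, betweenness
sums `σ_st(v)/σ_st` and stress counts the shortest paths through `v`
over pairs `s < t` distinct from `v`. MCODE is implemented from its
published algorithm (local k-core node scoring, seeded breadth-first
complex prediction with score threshold `seed_score · (1 − cutoff)`,
2-core post-filter) with the parameterisation max depth 100, degree
cut-off 2, node score cut-off 0.2, K-score 2, and reporting at
`density × nodes ≥ 4`; *fluff* and *haircut* are implemented but off by
default. When background edges happen to connect two planted cliques,
MCODE merges them into one complex — this is faithful algorithm
behaviour, and the module-recovery tests therefore verify (and require)
that the planted cliques are unconnected in the instance under test.

ROC screening treats the disease group as positive and does not
auto-orient the AUC by default (`orient = TRUE` reflects values below
0.5), because published per-gene AUC tables list the value regardless of
regulation direction.

# Problem sizes used by the test suite

The suite validates calibration and recovery at sizes chosen to make
Monte-Carlo error small relative to the asserted margins: 20-seed
replications for FDR/sensitivity properties; 1000 null genes × 9999
Monte-Carlo replicates for the pseudo-phasing calibration check;
exhaustive oracle comparisons for the exact tests (all binomial totals
to 60, random 2×2 tables to n = 60, all-shortest-path enumeration on
graphs to 12 nodes). The full pipeline check runs the default
configuration over 20 seeds.

# Limitations

* The binomial test ignores overdispersion; on strongly overdispersed
  real counts its FDR control degrades (quantified above). A
  beta-binomial test would be the natural extension.
* MBASED-lite is the phase-unknown 1-sample core only: no true
  haplotype phasing, no isoform-level ASE, no 2-sample mode.
* The NB-Wald DE core is not a DESeq2 replica; thresholds and
  intersection logic, not the DE engine, are the point. Results on real
  cohort data will differ from a DESeq2 analysis.
* Catalog matching is positional/identifier-based; no LD expansion.
* The synthetic chromosome has independent sites; LD, mappability and
  annotation errors present in real data are not modelled.
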