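# rsnpscan

Discovery of regulatory SNPs (rSNPs) from paired allele-specific binding
and allele-specific expression evidence, with the downstream
interpretation stages used in regulatory-genomics studies of complex
disease: catalog enrichment, differential-expression intersection, and
protein–protein-interaction (PPI) hub/module analysis.

The package is aimed at computational genomicists who have per-individual
allele-depth tables at candidate heterozygous sites from ChIP-seq of
active-chromatin marks (H3K4me3, H3K27ac) and RNA-seq of the same
samples, and who want a tested, reproducible implementation of the full
rSNP-calling chain rather than a collection of ad hoc scripts. A
synthetic-data module generates every input with known ground truth, so
each stage — and the pipeline end to end — is validated against planted
signal without any external download.

## The method

**Heterozygote calling.** For each individual, read counts are pooled
over all assays per site; a site is heterozygous when pooled depth
exceeds 20 and the pooled minor-allele fraction is at least 0.2.

**SNP-level allelic asymmetry.** At a heterozygous site with `n_ref`
reference and `n_alt` alternative reads, asymmetry is tested with the
exact binomial test of `n_ref` out of `n = n_ref + n_alt` against
`p = 1/2`, using the minimum-likelihood two-sided p-value

```
p = sum over k of  P(X = k) * 1{ P(X = k) <= P(X = observed) },  X ~ Bin(n, 1/2)
```

Benjamini–Hochberg adjustment is applied within each
(individual, assay) family; events with `p_adj < 0.1` in a ChIP mark are
allele-specific binding (ASB), in RNA allele-specific expression (ASE).

**Gene-level ASE ("MBASED-lite").** For a gene with SNVs
`i = 1..m` (counts `(r_i, a_i)`, totals `t_i`), the phase-unknown
aggregate statistic is the pseudo-phased major-haplotype frequency

```
T = sum_i max(r_i, a_i) / sum_i t_i
```

Because the per-SNV maximum inflates `T` under the null, the p-value is
Monte Carlo: each replicate draws `k_i ~ Bin(t_i, 1/2)`, re-applies the
same maximization, and `p = (1 + #{T* >= T}) / (n_sim + 1)`.

**Panel assembly.** Promoters are the ±1000 bp windows around every
distinct transcription start site (strand-aware, alternative TSSs
included). A promoter ASB SNP whose target gene is ASE in the same
individual is an rSNP; evidence is merged across individuals by position.

**Downstream stages.** Catalog matching (direct identifier/position or
±1000 bp proximal) with 2×2 enrichment (odds ratio `ad/bc`, Haldane 0.5
correction, Woolf 95% CI, Fisher exact and Pearson χ² p-values) and
per-trait ranking; negative-binomial Wald differential expression
(median-of-ratios size factors, method-of-moments dispersion, gates
`|log2FC| > 0.2` and `p_adj < 0.05`) with DEG-promoter/rSNP
intersection; PPI topology (degree, betweenness, stress; hubs = merged
top-20 lists), MCODE module detection (max depth 100, degree cut-off 2,
node score cut-off 0.2, K-score 2, reported at score ≥ 4),
hypergeometric over-representation analysis, and ROC/AUC screening
(`AUC = U / (n_pos · n_neg)` with tie half-credit; predictors at
AUC > 0.7).

## Worked example

```r
library(rsnpscan)

cfg <- sim_config(seed = 42, n_genes = 60, n_individuals = 3)
sim <- simulate_all(cfg)
res <- rsnp_pipeline(sim$depths, sim$annotation, n_sim = 999, seed = 1,
                     id_map = sim$id_map)
res$panel
#> # A tibble: 16 × 10
#>   chrom    pos ref_base alt_base target_genes n_target_genes individuals
#>   <chr>  <int> <chr>    <chr>    <list>                <int> <list>
#> 1 chrS    1181 T        C        <chr [1]>                 1 <chr [2]>
#> 2 chrS  104450 C        G        <chr [1]>                 1 <chr [1]>
#> 3 chrS  104901 A        T        <chr [1]>                 1 <chr [2]>
#> 4 chrS  104968 T        C        <chr [1]>                 1 <chr [2]>
#> # i 12 more rows
```

Each row is one panel SNP: its position, target gene(s) whose promoter
contains it, the individuals contributing same-individual ASB + ASE
evidence, the ChIP marks involved, and its rs identifier. Against the
generator's ground truth this run recovers planted rSNPs with

```r
got <- paste0(res$panel$chrom, ":", res$panel$pos)
mean(sim$truth$true_rsnps %in% got)  # sensitivity: 0.75
mean(got %in% sim$truth$true_rsnps)  # precision:   0.938
```

Enrichment of a panel against a catalog uses the 2×2 machinery:

```r
e <- enrichment_2x2(20, 10, 10, 20)
e
#> <enrich2x2> [20 10; 10 20]  OR = 4 (95% CI 1.37-11.7)
#>   Fisher p = 0.0194, chi-square p = 0.00982
tidy(e)   # broom-style one-row tibble of estimate, CI and p-values
```

The odds ratio of 4 says panel membership quadruples the odds of catalog
membership relative to background heterozygous sites; the Fisher p-value
is exact at this table size.

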