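#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. The defaults describe a desk-scale cohort
#' modelled on a paired ChIP-seq/RNA-seq allele-specific study: nine
#' heterozygous donors, two active-chromatin marks (H3K4me3, H3K27ac) plus
#' RNA, beta-binomially overdispersed allele counts, and a planted subset of
#' regulatory genes whose promoter sites carry allele-specific binding and
#' whose bodies carry allele-specific expression.
#'
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_individuals Number of donors.
#' @param n_genes Number of non-overlapping genes on the synthetic chromosome.
#' @param n_transcripts_per_gene Integer vector of allowed transcript counts
#'   per gene; one value is drawn uniformly per gene.
#' @param n_het_sites_per_promoter,n_het_sites_per_gene_body Mean number of
#'   candidate heterozygous sites per promoter / gene body; realised counts
#'   are `1 + Poisson(mean - 1)` so every gene has at least one of each.
#' @param mean_depth Mean sequencing depth (reads) per site per assay;
#'   realised depths are Poisson.
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   `[0, 1)`; 0 reduces to a plain binomial.
#' @param imbalance_fraction Fraction of genes planted as regulatory
#'   (allelic imbalance in both ChIP marks at promoter sites and in RNA at
#'   gene-body sites); these genes' promoter sites are the true rSNPs.
#' @param asb_only_fraction,ase_only_fraction Fractions of genes planted
#'   with imbalance in ChIP only / RNA only (decoys for the intersection).
#' @param imbalanced_maf True major-allele frequency at planted sites, in
#'   `(0.5, 1]`.
#' @param ref_bias_delta Additive shift of the read-level reference-allele
#'   probability toward the reference; applied only in `mode = "naive"`
#'   counting (the dual-genome protocol removes it).
#' @param het_prob Probability that a given donor is heterozygous at a site.
#' @param de_fraction,de_log2fc,nb_dispersion,n_samples_per_group
#'   Differential-expression simulation: fraction of genes with a planted
#'   log2 fold change of magnitude `de_log2fc`, negative-binomial dispersion,
#'   and samples per condition group.
#' @param n_modules,module_size,background_edge_p,n_network_nodes
#'   PPI simulation: number and size of planted cliques, Erdos-Renyi
#'   background edge probability, and total node count.
#' @param catalog_overlap_enrichment Sampling-weight multiplier for true
#'   rSNP positions when drawing catalog membership (1 = no planted
#'   enrichment).
#' @param catalog_background_n Number of non-site background positions added
#'   to the catalog sampling pool.
#' @param trait_sizes Named integer vector: catalog size per GWAS-like
#'   trait; defaults straddle the 100-variant trait filter.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' cfg$imbalanced_maf
sim_config <- function(seed = 1L,
                       n_individuals = 9L,
                       n_genes = 200L,
                       n_transcripts_per_gene = 1:3,
                       n_het_sites_per_promoter = 2,
                       n_het_sites_per_gene_body = 3,
                       mean_depth = 60,
                       overdispersion_rho = 0.002,
                       imbalance_fraction = 0.15,
                       asb_only_fraction = 0.05,
                       ase_only_fraction = 0.05,
                       imbalanced_maf = 0.75,
                       ref_bias_delta = 0.05,
                       het_prob = 0.7,
                       de_fraction = 0.1,
                       de_log2fc = 1.0,
                       nb_dispersion = 0.05,
                       n_samples_per_group = 10L,
                       n_modules = 3L,
                       module_size = 8L,
                       background_edge_p = 0.02,
                       n_network_nodes = 100L,
                       catalog_overlap_enrichment = 4,
                       catalog_background_n = 1000L,
                       trait_sizes = c(anemia = 40, bmi = 80, t2dm = 120,
                                       hba1c = 150, lymphocyte_count = 250,
                                       platelet_count = 400)) {
  cfg <- list(
    seed = as.integer(seed),
    n_individuals = n_individuals,
    n_genes = n_genes,
    n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
    n_het_sites_per_promoter = n_het_sites_per_promoter,
    n_het_sites_per_gene_body = n_het_sites_per_gene_body,
    mean_depth = mean_depth,
    overdispersion_rho = overdispersion_rho,
    imbalance_fraction = imbalance_fraction,
    asb_only_fraction = asb_only_fraction,
    ase_only_fraction = ase_only_fraction,
    imbalanced_maf = imbalanced_maf,
    ref_bias_delta = ref_bias_delta,
    het_prob = het_prob,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    nb_dispersion = nb_dispersion,
    n_samples_per_group = n_samples_per_group,
    n_modules = n_modules,
    module_size = module_size,
    background_edge_p = background_edge_p,
    n_network_nodes = n_network_nodes,
    catalog_overlap_enrichment = catalog_overlap_enrichment,
    catalog_background_n = catalog_background_n,
    trait_sizes = trait_sizes
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_count(cfg$seed, "seed", min = 0)
  check_count(cfg$n_individuals, "n_individuals")
  check_count(cfg$n_genes, "n_genes")
  stop_if_not(length(cfg$n_transcripts_per_gene) >= 1 &&
                all(cfg$n_transcripts_per_gene >= 1),
              "`n_transcripts_per_gene` values must be >= 1")
  stop_if_not(cfg$n_het_sites_per_promoter >= 1 &&
                cfg$n_het_sites_per_gene_body >= 1,
              "het-site means must be >= 1")
  stop_if_not(cfg$mean_depth >= 1, "`mean_depth` must be >= 1")
  stop_if_not(cfg$overdispersion_rho >= 0 && cfg$overdispersion_rho < 1,
              "`overdispersion_rho` must be in [0, 1)")
  check_prob(cfg$imbalance_fraction, "imbalance_fraction")
  check_prob(cfg$asb_only_fraction, "asb_only_fraction")
  check_prob(cfg$ase_only_fraction, "ase_only_fraction")
  stop_if_not(cfg$imbalance_fraction + cfg$asb_only_fraction +
                cfg$ase_only_fraction <= 1,
              "planted gene fractions must sum to <= 1")
  stop_if_not(cfg$imbalanced_maf > 0.5 && cfg$imbalanced_maf <= 1,
              "`imbalanced_maf` must be in (0.5, 1]")
  check_prob(cfg$ref_bias_delta, "ref_bias_delta")
  check_prob(cfg$het_prob, "het_prob", open_low = TRUE)
  check_prob(cfg$de_fraction, "de_fraction")
  stop_if_not(cfg$nb_dispersion >= 0, "`nb_dispersion` must be >= 0")
  check_count(cfg$n_samples_per_group, "n_samples_per_group", min = 2)
  check_count(cfg$n_modules, "n_modules", min = 0)
  check_count(cfg$module_size, "module_size", min = 3)
  check_prob(cfg$background_edge_p, "background_edge_p")
  check_count(cfg$n_network_nodes, "n_network_nodes", min = 3)
  stop_if_not(cfg$catalog_overlap_enrichment > 0,
              "`catalog_overlap_enrichment` must be positive")
  stop_if_not(cfg$n_network_nodes >= cfg$n_modules * cfg$module_size,
              "planted modules must fit in `n_network_nodes`")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_individuals, "donors |",
      x$n_genes, "genes | depth", x$mean_depth, "| maf", x$imbalanced_maf,
      "| rho", x$overdispersion_rho, "\n")
  invisible(x)
}
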