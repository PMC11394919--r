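#' Run the full rSNP discovery pipeline
#'
#' Chains the discovery stages over all individuals of an allele-depth
#' table: heterozygote calling from pooled assays, SNP-level asymmetry
#' testing (ASB for the ChIP marks, ASE for RNA), gene-level ASE
#' aggregation, strand-aware promoter construction, promoter-ASB
#' intersection, and panel assembly.
#'
#' @param depths Allele-depth tibble covering one or more individuals.
#' @param annotation Transcript tibble (`gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`).
#' @param alpha SNP- and gene-level adjusted-significance threshold,
#'   default 0.1.
#' @param n_sim Monte-Carlo replicates for multi-SNV gene ASE, default
#'   9999.
#' @param seed Seed for the gene-level Monte Carlo, default 1.
#' @param id_map Optional `(chrom, pos, rs_id)` lookup; when supplied the
#'   panel gains an `rs_id` column.
#' @param gene_ase_rule Multi-SNV gene rule, `"mbased"` or `"any_snv"`.
#' @param same_individual,min_individuals Panel assembly rules, see
#'   [assemble_panel()].
#' @return A list: `het_sites`, `calls`, `gene_ase`, `promoters`,
#'   `promoter_hits`, `panel`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 40, n_individuals = 3)
#' sim <- simulate_allele_depths(cfg)
#' ann <- simulate_annotation(cfg)
#' res <- rsnp_pipeline(sim$depths, ann, n_sim = 999)
#' nrow(res$panel)
rsnp_pipeline <- function(depths, annotation, alpha = 0.1, n_sim = 9999,
                          seed = 1L, id_map = NULL,
                          gene_ase_rule = c("mbased", "any_snv"),
                          same_individual = TRUE, min_individuals = 1L) {
  gene_ase_rule <- match.arg(gene_ase_rule)
  het_sites <- depths |>
    dplyr::group_split(.data$individual_id) |>
    purrr::map(pool_and_call_het) |>
    bind_rows()
  calls <- call_events(het_sites, depths, alpha = alpha)
  if (!is.null(id_map)) calls <- assign_rs_ids(calls, id_map)

  rna_sites <- calls |> filter(.data$assay == "RNA") |>
    distinct(.data$chrom, .data$pos)
  gene_sites <- snvs_in_gene(rna_sites, annotation)
  gene_ase <- call_ase_genes(gene_sites, calls, alpha = alpha,
                             n_sim = n_sim, seed = seed,
                             rule = gene_ase_rule)

  promoter_tbl <- promoters(annotation)
  hits <- promoter_asb(calls, promoter_tbl)
  panel <- assemble_panel(hits, gene_ase,
                          same_individual = same_individual,
                          min_individuals = min_individuals)
  if (!is.null(id_map)) {
    panel <- assign_rs_ids(panel, id_map)
  }
  list(het_sites = het_sites, calls = calls, gene_ase = gene_ase,
       promoters = promoter_tbl, promoter_hits = hits, panel = panel)
}
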