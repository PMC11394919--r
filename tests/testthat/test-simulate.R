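test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_genes = 30, n_individuals = 2)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_identical(simulate_allele_depths(cfg)$depths,
                   simulate_allele_depths(cfg)$depths)
  expect_identical(simulate_counts(cfg)$counts, simulate_counts(cfg)$counts)
  expect_identical(simulate_ppi(cfg)$edges, simulate_ppi(cfg)$edges)
  s1 <- simulate_allele_depths(cfg)
  expect_identical(simulate_catalogs(cfg, s1), simulate_catalogs(cfg, s1))
})

test_that("annotation genes are separated, strand-consistent, multi-TSS", {
  cfg <- sim_config(seed = 2, n_genes = 80)
  ann <- simulate_annotation(cfg)
  genes <- ann |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(start = min(start), end = max(end),
                     n_tss = dplyr::n_distinct(tss),
                     strand = strand[1], tss1 = tss[1])
  ord <- genes[order(genes$start), ]
  expect_true(all(diff(ord$start) > 0))
  expect_true(all(ord$start[-1] - ord$end[-nrow(ord)] >= 2000))
  # >= 10% of genes carry alternative TSSs
  expect_gte(mean(genes$n_tss > 1), 0.10)
  # strand convention: minus-strand TSS is the transcript end
  minus <- ann[ann$strand == "-", ]
  expect_true(all(minus$tss == minus$end))
  plus <- ann[ann$strand == "+", ]
  expect_true(all(plus$tss == plus$start))
})

test_that("single-transcript configuration gives one TSS per gene", {
  cfg <- sim_config(seed = 4, n_genes = 25, n_transcripts_per_gene = 1L)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 25L)
  expect_equal(dplyr::n_distinct(ann$gene_id), 25L)
})

test_that("null-only configuration has p = 0.5 everywhere and balances", {
  cfg <- sim_config(seed = 9, n_genes = 80, imbalance_fraction = 0,
                    asb_only_fraction = 0, ase_only_fraction = 0,
                    overdispersion_rho = 0)
  sim <- simulate_allele_depths(cfg)
  expect_true(all(sim$sites$p_chip == 0.5))
  expect_true(all(sim$sites$p_rna == 0.5))
  expect_length(sim$truth$true_rsnps, 0)
  # empirical major-allele fraction over many null draws ~ 0.5 within 3 SE
  tot <- sum(sim$depths$ref_count) + sum(sim$depths$alt_count)
  frac <- sum(sim$depths$ref_count) / tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("degenerate maf 1.0 with rho 0 leaves the minor allele unread", {
  cfg <- sim_config(seed = 6, n_genes = 40, imbalanced_maf = 1.0,
                    overdispersion_rho = 0)
  sim <- simulate_allele_depths(cfg)
  planted <- sim$sites[sim$sites$imb_chip & sim$sites$major_is_ref, ]
  chip <- sim$depths[sim$depths$assay != "RNA" &
                       sim$depths$pos %in% planted$pos, ]
  expect_true(nrow(chip) > 0)
  expect_true(all(chip$alt_count == 0))
})

test_that("ground truth is internally consistent", {
  cfg <- sim_config(seed = 12, n_genes = 60)
  sim <- simulate_allele_depths(cfg)
  tr <- sim$truth
  expect_true(all(tr$true_rsnps %in% tr$true_imbalanced_sites$H3K4me3))
  rsnp_genes <- sim$sites$gene_id[sim$sites$site_id %in% tr$true_rsnps]
  expect_true(all(rsnp_genes %in% tr$true_ase_genes))
})

test_that("naive counting inflates null asymmetry calls vs dual-genome", {
  cfg <- sim_config(seed = 21, n_genes = 120, imbalance_fraction = 0,
                    asb_only_fraction = 0, ase_only_fraction = 0,
                    ref_bias_delta = 0.08)
  naive <- simulate_allele_depths(cfg, mode = "naive")
  dual <- simulate_allele_depths(cfg, mode = "dual_genome")
  rate <- function(sim) {
    p <- binomial_asymmetry_p(sim$depths$ref_count, sim$depths$alt_count)
    mean(bh_adjust(p) < 0.1)
  }
  expect_gt(rate(naive), rate(dual) + 0.01)
  # the two modes share site structure; only the bias differs
  expect_identical(naive$sites$pos, dual$sites$pos)
})

test_that("catalog generator plants enrichment and trait-size spread", {
  cfg <- sim_config(seed = 8, n_genes = 120)
  sim <- simulate_allele_depths(cfg)
  cat <- simulate_catalogs(cfg, sim)
  sizes <- table(cat$label[cat$catalog == "GWAS"])
  expect_true(any(sizes < 100) && any(sizes >= 100))
  # planted enrichment recovered as OR > 1 by the exact Fisher oracle
  rsnp_pos <- as.integer(sub(".*:", "", sim$truth$true_rsnps))
  other_pos <- setdiff(sim$sites$pos, rsnp_pos)
  gw <- unique(cat$pos[cat$catalog == "GWAS"])
  a <- sum(rsnp_pos %in% gw); b <- length(rsnp_pos) - a
  c <- sum(other_pos %in% gw); d <- length(other_pos) - c
  expect_gt((a * d) / max(1, b * c), 1)
  expect_lt(oracle_fisher_p(a, b, c, d), 0.05)
})

test_that("no planted catalog enrichment when the multiplier is 1", {
  cfg <- sim_config(seed = 8, n_genes = 120, catalog_overlap_enrichment = 1)
  sim <- simulate_allele_depths(cfg)
  cat <- simulate_catalogs(cfg, sim)
  rsnp_pos <- as.integer(sub(".*:", "", sim$truth$true_rsnps))
  other_pos <- setdiff(sim$sites$pos, rsnp_pos)
  gw <- unique(cat$pos[cat$catalog == "GWAS"])
  a <- sum(rsnp_pos %in% gw); b <- length(rsnp_pos) - a
  c <- sum(other_pos %in% gw); d <- length(other_pos) - c
  expect_gt(oracle_fisher_p(a, b, c, d), 0.05)
})

test_that("count simulation respects de_fraction and the Poisson limit", {
  cfg0 <- sim_config(seed = 3, n_genes = 50, de_fraction = 0)
  expect_true(all(simulate_counts(cfg0)$truth$log2fc == 0))
  # dispersion -> 0 with large means: empirical log2 ratio ~ planted beta
  cfg <- sim_config(seed = 3, n_genes = 200, de_fraction = 0.2,
                    de_log2fc = 1, nb_dispersion = 0,
                    n_samples_per_group = 50L)
  sc <- simulate_counts(cfg)
  norm <- sweep(sc$counts, 2, sc$size_factors, "/")
  grp <- sc$labels$condition
  lfc <- log2(rowMeans(norm[, grp == "case"]) /
                rowMeans(norm[, grp == "control"]))
  planted <- sc$truth$log2fc != 0
  expect_lt(median(abs(lfc[planted] - sc$truth$log2fc[planted])), 0.1)
  expect_lt(median(abs(lfc[!planted])), 0.1)
})

test_that("ppi generator plants cliques on a clean background", {
  cfg <- sim_config(seed = 10, background_edge_p = 0, n_modules = 2,
                    module_size = 6, n_network_nodes = 40)
  net <- simulate_ppi(cfg)
  # background 0: the graph is exactly the planted cliques
  expect_equal(nrow(net$edges), 2 * choose(6, 2))
  for (mod in net$true_modules) {
    sub <- net$edges[net$edges$from %in% mod & net$edges$to %in% mod, ]
    expect_equal(nrow(sub), choose(6, 2)) # density 1
  }
  # simple graph: no loops, no duplicates
  expect_true(all(net$edges$from != net$edges$to))
  key <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(imbalanced_maf = 0.5), "imbalanced_maf")
  expect_error(sim_config(overdispersion_rho = 1), "overdispersion_rho")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(imbalance_fraction = 0.9, asb_only_fraction = 0.2),
               "sum")
})
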