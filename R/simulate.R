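#' Simulate a transcript annotation on one synthetic chromosome
#'
#' Lays out non-overlapping genes separated by intergenic gaps of at least
#' 2000 bp (so a +/-1000 bp promoter never spans a neighbouring gene), each
#' with one or more transcripts. Extra transcripts receive a distinct,
#' alternative TSS with probability 0.7, guaranteeing a substantial share of
#' multi-TSS genes. Strand is assigned per gene; the TSS of a transcript is
#' its `start` on the plus strand and its `end` on the minus strand.
#'
#' @param cfg A [sim_config()] object.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss` (1-based inclusive coordinates).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "annotation"), {
    n <- cfg$n_genes
    lens <- sample(2000:6000, n, replace = TRUE)
    gaps <- 2000L + sample(0:3000, n, replace = TRUE)
    starts <- cumsum(gaps) + cumsum(c(0L, lens[-n]))
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ntx <- sample(cfg$n_transcripts_per_gene, n, replace = TRUE)

    purrr::pmap(
      list(seq_len(n), starts, ends, strands, ntx),
      function(i, s, e, str, k) {
        gid <- sprintf("G%04d", i)
        # first transcript spans the whole gene; extras may shift the TSS
        tx_start <- rep(s, k)
        tx_end <- rep(e, k)
        if (k > 1) {
          for (j in 2:k) {
            if (runif(1) < 0.7) {
              off <- sample(100:800, 1)
              if (str == "+") tx_start[j] <- s + off else tx_end[j] <- e - off
            }
          }
        }
        tibble(
          gene_id = gid,
          transcript_id = sprintf("%s.t%d", gid, seq_len(k)),
          chrom = SIM_CHROM,
          strand = str,
          start = as.integer(tx_start),
          end = as.integer(tx_end)
        )
      }
    ) |>
      bind_rows() |>
      mutate(tss = if_else(.data$strand == "+", .data$start, .data$end))
  })
}

# draw beta-binomial counts: k successes out of `size` with mean prob p and
# intra-class correlation rho (rho = 0 reduces to binomial)
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate per-individual allele-depth tables with known ground truth
#'
#' Generates candidate heterozygous sites for every gene (promoter sites,
#' covered by the two ChIP marks, and gene-body sites, covered by RNA) and
#' draws read counts per donor, assay and site. Depth is Poisson with mean
#' `cfg$mean_depth`; the split between reference and alternative reads is
#' beta-binomial with intra-class correlation `cfg$overdispersion_rho` and
#' success probability 0.5 at null sites or `cfg$imbalanced_maf` (toward a
#' randomly chosen major allele) at planted sites. Genes are planted as
#' regulatory (imbalance in ChIP and RNA: their promoter sites are the true
#' rSNPs), ASB-only, ASE-only, or null.
#'
#' In `mode = "naive"` an additive reference-mapping bias
#' `cfg$ref_bias_delta` shifts the read-level reference probability upward
#' at every site, emulating alignment against the reference genome only; in
#' `mode = "dual_genome"` (default) counts are unbiased, emulating the
#' protocol that re-aligns against a personalised alternative genome.
#'
#' @param cfg A [sim_config()] object.
#' @param annotation Optional annotation tibble from [simulate_annotation()];
#'   generated from `cfg` if missing.
#' @param mode Counting protocol, `"dual_genome"` or `"naive"`.
#' @return A list with elements `depths` (tibble: `individual_id`, `assay`,
#'   `chrom`, `pos`, `ref_base`, `alt_base`, `ref_count`, `alt_count`),
#'   `sites` (per-site metadata: `site_id`, `gene_id`, `role`, `gene_class`,
#'   `major_is_ref`, true per-assay-class success probabilities), and
#'   `truth` (list: `true_imbalanced_sites` per assay, `true_ase_genes`,
#'   `true_rsnps`).
#' @export
simulate_allele_depths <- function(cfg, annotation = NULL,
                                   mode = c("dual_genome", "naive")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  if (is.null(annotation)) annotation <- simulate_annotation(cfg)

  withr::with_seed(stage_seed(cfg$seed, "depths"), {
    genes <- annotation |>
      group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                start = min(.data$start), end = max(.data$end),
                tss = .data$tss[1], .groups = "drop")

    ng <- nrow(genes)
    classes <- sample(c(
      rep("regulatory", round(cfg$imbalance_fraction * ng)),
      rep("asb_only", round(cfg$asb_only_fraction * ng)),
      rep("ase_only", round(cfg$ase_only_fraction * ng)),
      rep("null", ng)
    )[seq_len(ng)])
    genes$gene_class <- classes

    sites <- purrr::pmap(
      list(genes$gene_id, genes$start, genes$end, genes$tss,
           genes$gene_class),
      function(gid, s, e, tss, cls) {
        np <- 1L + rpois(1, cfg$n_het_sites_per_promoter - 1)
        nb <- 1L + rpois(1, cfg$n_het_sites_per_gene_body - 1)
        prom_lo <- max(1L, tss - 1000L)
        pp <- sample(prom_lo:(tss + 1000L), np)
        bp <- sample(s:e, nb)
        tibble(
          gene_id = gid, gene_class = cls,
          pos = as.integer(c(pp, bp)),
          role = rep(c("promoter", "gene_body"), c(np, nb))
        )
      }
    ) |>
      bind_rows() |>
      distinct(.data$pos, .keep_all = TRUE) |>
      arrange(.data$pos)

    nsite <- nrow(sites)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nsite, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))

    sites <- sites |>
      mutate(
        chrom = SIM_CHROM,
        site_id = paste0(SIM_CHROM, ":", .data$pos),
        ref_base = ref, alt_base = alt,
        major_is_ref = runif(nsite) < 0.5,
        imb_chip = (.data$gene_class %in% c("regulatory", "asb_only")) &
          .data$role == "promoter",
        imb_rna = (.data$gene_class %in% c("regulatory", "ase_only")) &
          .data$role == "gene_body"
      )

    # true probability that a read carries the REFERENCE allele
    p_of <- function(imb) {
      p <- ifelse(imb,
                  ifelse(sites$major_is_ref, cfg$imbalanced_maf,
                         1 - cfg$imbalanced_maf),
                  0.5)
      if (mode == "naive") p <- pmin(p + cfg$ref_bias_delta, 0.999)
      p
    }
    sites$p_chip <- p_of(sites$imb_chip)
    sites$p_rna <- p_of(sites$imb_rna)

    assays <- c("H3K4me3", "H3K27ac", "RNA")
    depths <- purrr::map(seq_len(cfg$n_individuals), function(ind) {
      het <- runif(nsite) < cfg$het_prob
      purrr::map(assays, function(a) {
        covered <- het & (if (a == "RNA") sites$role == "gene_body"
                          else sites$role == "promoter")
        if (!any(covered)) return(NULL)
        sub <- sites[covered, ]
        dp <- rpois(nrow(sub), cfg$mean_depth)
        keep <- dp > 0
        sub <- sub[keep, ]; dp <- dp[keep]
        p <- if (a == "RNA") sub$p_rna else sub$p_chip
        rc <- rbetabinom(length(dp), dp, p, cfg$overdispersion_rho)
        tibble(
          individual_id = sprintf("ind%02d", ind), assay = a,
          chrom = sub$chrom, pos = sub$pos,
          ref_base = sub$ref_base, alt_base = sub$alt_base,
          ref_count = as.integer(rc), alt_count = as.integer(dp - rc)
        )
      }) |> bind_rows()
    }) |> bind_rows()

    chip_imb <- sites$site_id[sites$imb_chip]
    truth <- list(
      true_imbalanced_sites = list(
        H3K4me3 = chip_imb, H3K27ac = chip_imb,
        RNA = sites$site_id[sites$imb_rna]
      ),
      true_ase_genes = unique(
        sites$gene_id[sites$gene_class %in% c("regulatory", "ase_only")]),
      true_rsnps = sites$site_id[sites$gene_class == "regulatory" &
                                   sites$role == "promoter"]
    )
    list(depths = depths, sites = sites, truth = truth)
  })
}

#' Simulate variant catalogs (GWAS-like, eQTL-like, TF-ASB-like)
#'
#' Draws catalog membership from a pool of candidate positions (every
#' simulated het site plus random background positions) in which true rSNP
#' positions carry sampling weight `cfg$catalog_overlap_enrichment` and all
#' other positions weight 1, planting a recoverable overlap enrichment.
#' GWAS-like entries are labelled with traits whose catalog sizes are given
#' by `cfg$trait_sizes` (straddling the 100-variant trait filter); eQTL-like
#' entries with tissues; TF-ASB-like entries with transcription-factor names
#' and an `fdr` column.
#'
#' @param cfg A [sim_config()] object.
#' @param sim Output of [simulate_allele_depths()] (for site positions and
#'   ground truth).
#' @return A tibble with columns `catalog` (`"GWAS"`, `"eQTL"`, `"TF_ASB"`),
#'   `rs_id`, `chrom`, `pos`, `label`, `fdr` (NA outside TF_ASB).
#' @export
simulate_catalogs <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "catalogs"), {
    site_pos <- sort(unique(sim$sites$pos))
    chrom_end <- max(site_pos) + 5000L
    bg_pos <- sample(setdiff(seq_len(chrom_end), site_pos),
                     cfg$catalog_background_n)
    pool <- sort(c(site_pos, bg_pos))
    rsnp_pos <- as.integer(sub(".*:", "", sim$truth$true_rsnps))
    w <- ifelse(pool %in% rsnp_pos, cfg$catalog_overlap_enrichment, 1)

    draw <- function(size) sort(sample(pool, min(size, length(pool)),
                                       prob = w))
    gwas <- purrr::imap(cfg$trait_sizes, function(sz, trait) {
      tibble(catalog = "GWAS", pos = draw(sz), label = trait)
    }) |> bind_rows()
    tissues <- c(whole_blood = 300, liver = 150, muscle = 150,
                 adipose = 100)
    eqtl <- purrr::imap(tissues, function(sz, tis) {
      tibble(catalog = "eQTL", pos = draw(sz), label = tis)
    }) |> bind_rows()
    tfs <- c(CTCF = 200, STAT1 = 120, YY1 = 80)
    tf <- purrr::imap(tfs, function(sz, f) {
      tibble(catalog = "TF_ASB", pos = draw(sz), label = f)
    }) |> bind_rows()

    bind_rows(gwas, eqtl, tf) |>
      mutate(
        chrom = SIM_CHROM,
        rs_id = paste0("rs", .data$pos),
        fdr = if_else(.data$catalog == "TF_ASB",
                      runif(dplyr::n(), 0, 0.1), NA_real_)
      ) |>
      select("catalog", "rs_id", "chrom", "pos", "label", "fdr")
  })
}

#' Simulate an rs-identifier lookup map
#'
#' Maps a random subset of simulated site positions to dbSNP-style
#' identifiers (`rs<pos>`); the remainder stay unmapped so that downstream
#' identifier assignment must fall back to deterministic synthetic IDs.
#'
#' @param sim Output of [simulate_allele_depths()].
#' @param coverage Fraction of sites included in the map.
#' @param seed Integer seed.
#' @return A tibble with columns `chrom`, `pos`, `rs_id`.
#' @export
simulate_id_map <- function(sim, coverage = 0.8, seed = 1L) {
  withr::with_seed(seed, {
    sites <- sim$sites
    keep <- runif(nrow(sites)) < coverage
    tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
           rs_id = paste0("rs", sites$pos[keep]))
  })
}

#' Simulate a negative-binomial expression count matrix
#'
#' Counts follow `NB(mean = mu_g * s_j * 2^(x_j * beta_g), size =
#' 1/nb_dispersion)` with gene baselines `mu_g` log-normal, sample-specific
#' size factors `s_j` log-uniform in `[0.7, 1/0.7]`, group indicator `x_j`,
#' and `beta_g = 0` except for a planted `de_fraction` of genes with
#' `|beta_g| = de_log2fc` (sign random). `nb_dispersion = 0` gives Poisson
#' counts.
#'
#' @param cfg A [sim_config()] object.
#' @param gene_ids Optional character vector of gene identifiers (defaults
#'   to `G0001 ...` matching [simulate_annotation()]).
#' @return A list: `counts` (integer matrix, genes x samples), `labels`
#'   (tibble `sample_id`, `condition`), `truth` (tibble `gene_id`,
#'   `log2fc`), `size_factors` (true simulated factors).
#' @export
simulate_counts <- function(cfg, gene_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "counts"), {
    if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    ng <- length(gene_ids)
    nper <- cfg$n_samples_per_group
    ns <- 2L * nper
    mu <- exp(rnorm(ng, log(100), 1))
    sf <- exp(runif(ns, log(0.7), log(1 / 0.7)))
    x <- rep(c(0, 1), each = nper)
    beta <- numeric(ng)
    nde <- round(cfg$de_fraction * ng)
    if (nde > 0) {
      idx <- sample(ng, nde)
      beta[idx] <- cfg$de_log2fc * sample(c(-1, 1), nde, replace = TRUE)
    }
    mean_mat <- outer(mu, sf) * 2^(outer(beta, x))
    counts <- if (cfg$nb_dispersion <= 0) {
      matrix(rpois(ng * ns, mean_mat), ng, ns)
    } else {
      matrix(rnbinom(ng * ns, mu = mean_mat, size = 1 / cfg$nb_dispersion),
             ng, ns)
    }
    dimnames(counts) <- list(gene_ids, sprintf("s%02d", seq_len(ns)))
    list(
      counts = counts,
      labels = tibble(sample_id = colnames(counts),
                      condition = rep(c("control", "case"), each = nper)),
      truth = tibble(gene_id = gene_ids, log2fc = beta),
      size_factors = sf
    )
  })
}

#' Simulate a protein-protein interaction network with planted modules
#'
#' Plants `n_modules` disjoint cliques of `module_size` nodes on top of an
#' Erdos-Renyi background over `n_network_nodes` nodes at edge probability
#' `background_edge_p`. The result is a simple undirected graph (no
#' self-loops, no duplicate edges).
#'
#' @param cfg A [sim_config()] object.
#' @param node_ids Optional character vector of node (gene) names.
#' @return A list: `edges` (tibble `from`, `to`), `nodes` (character),
#'   `true_modules` (list of character vectors).
#' @export
simulate_ppi <- function(cfg, node_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "ppi"), {
    if (is.null(node_ids))
      node_ids <- sprintf("G%04d", seq_len(cfg$n_network_nodes))
    n <- length(node_ids)
    g <- igraph::sample_gnp(n, cfg$background_edge_p, directed = FALSE)
    modules <- list()
    if (cfg$n_modules > 0) {
      picks <- sample(n, cfg$n_modules * cfg$module_size)
      for (m in seq_len(cfg$n_modules)) {
        mem <- picks[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)]
        g <- igraph::add_edges(g, as.vector(utils::combn(mem, 2)))
        modules[[m]] <- sort(node_ids[mem])
      }
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    list(
      edges = tibble(from = node_ids[el[, 1]], to = node_ids[el[, 2]]),
      nodes = node_ids,
      true_modules = modules
    )
  })
}

#' Simulate every input the rSNP pipeline consumes
#'
#' Convenience wrapper running all generators under one configuration and
#' collecting their ground truths.
#'
#' @param cfg A [sim_config()] object.
#' @return A list: `annotation`, `depths`, `sites`, `catalogs`, `id_map`,
#'   `expression` (counts/labels/truth), `ppi`, `truth` (merged ground
#'   truth).
#' @export
simulate_all <- function(cfg) {
  annotation <- simulate_annotation(cfg)
  ad <- simulate_allele_depths(cfg, annotation)
  catalogs <- simulate_catalogs(cfg, ad)
  id_map <- simulate_id_map(ad, seed = stage_seed(cfg$seed, "ase"))
  expr <- simulate_counts(cfg)
  ppi <- simulate_ppi(cfg)
  truth <- c(ad$truth,
             list(true_de_genes = expr$truth$log2fc |>
                    setNames(expr$truth$gene_id),
                  true_modules = ppi$true_modules))
  list(annotation = annotation, depths = ad$depths, sites = ad$sites,
       catalogs = catalogs, id_map = id_map, expression = expr, ppi = ppi,
       truth = truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the allele-depth table, annotation (TSV and BED6), catalogs,
#' count matrix, condition labels, PPI edge list and identifier map as TSV,
#' and the ground truth as JSON.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$depths, p("allele_depths.tsv"))
  readr::write_tsv(sim$annotation, p("annotation.tsv"))
  bed <- sim$annotation |>
    mutate(bed_start = .data$start - 1L, score = 0L) |>
    select("chrom", "bed_start", "end", "transcript_id", "score", "strand")
  readr::write_tsv(bed, p("annotation.bed"), col_names = FALSE)
  readr::write_tsv(sim$catalogs, p("catalogs.tsv"))
  readr::write_tsv(sim$id_map, p("id_map.tsv"))
  counts <- as_tibble(sim$expression$counts, rownames = "gene_id")
  readr::write_tsv(counts, p("counts.tsv"))
  readr::write_tsv(sim$expression$labels, p("labels.tsv"))
  readr::write_tsv(sim$ppi$edges, p("ppi_edges.tsv"))
  jsonlite::write_json(sim$truth, p("ground_truth.json"))
  invisible(list.files(dir, full.names = TRUE))
}
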