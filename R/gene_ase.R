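#' Assign SNVs to gene bodies
#'
#' Assigns each site to every gene whose span (1-based, inclusive at both
#' ends) contains its position; a site inside two overlapping genes is
#' assigned to both.
#'
#' @param sites Tibble with columns `chrom`, `pos` (plus any others, kept).
#' @param gene_models Tibble with `gene_id`, `chrom`, `start`, `end`; a
#'   transcript table is aggregated to gene spans first.
#' @return `sites` joined with `gene_id`, one row per (site, gene) pair;
#'   sites outside every gene are dropped.
#' @export
snvs_in_gene <- function(sites, gene_models) {
  genes <- gene_models |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$start, genes$end),
    function(gid, chr, s, e) {
      sites |>
        filter(.data$chrom == chr, .data$pos >= s, .data$pos <= e) |>
        mutate(gene_id = gid)
    }
  ) |> bind_rows()
}

#' Gene-level ASE by pseudo-phasing Monte Carlo ("MBASED-lite")
#'
#' Aggregates allelic imbalance over the SNVs of one gene when true
#' haplotype phase is unknown. Each SNV's major allele (larger count,
#' reference on ties) is assigned to a nominal haplotype (pseudo-phasing)
#' and the gene-level statistic is the count-weighted aggregate
#' major-haplotype frequency `T = sum(major_i) / sum(total_i)`. Because
#' taking the per-SNV maximum inflates `T` even under balance, the null
#' distribution is built by Monte Carlo with the same pseudo-phasing:
#' each replicate draws `k_i ~ Binomial(total_i, 1/2)` (beta-binomial when
#' `rho > 0`), re-applies `max(k_i, total_i - k_i)` and recomputes the
#' statistic. The p-value is `(1 + #\{T* >= T\}) / (n_sim + 1)`, hence
#' floored at `1/(n_sim + 1)`.
#'
#' @param ref_counts,alt_counts Integer vectors, one entry per SNV of the
#'   gene; each total must be positive.
#' @param n_sim Number of null replicates (default 9999; fewer than 999
#'   triggers a warning).
#' @param seed Integer seed; results are bit-identical under a fixed seed.
#' @param rho Optional beta-binomial intra-class correlation folded into
#'   the null (default 0 = binomial null).
#' @return An object of class `mbased_ase`: a list with `aggregate_maf`,
#'   `p_value`, `n_snvs`, `n_sim`.
#' @export
#' @examples
#' mbased_gene_ase(c(20, 0), c(0, 20), n_sim = 999, seed = 1)$p_value
mbased_gene_ase <- function(ref_counts, alt_counts, n_sim = 9999,
                            seed = 1L, rho = 0) {
  m <- length(ref_counts)
  stop_if_not(m >= 1 && length(alt_counts) == m,
              "need matching non-empty count vectors")
  tot <- ref_counts + alt_counts
  stop_if_not(all(tot >= 1), "each SNV needs at least one read")
  if (n_sim < 999) warn("n_sim < 999 gives a coarse p-value floor")

  major <- pmax(ref_counts, alt_counts)
  t_obs <- sum(major) / sum(tot)

  t_null <- withr::with_seed(seed, {
    k <- rbetabinom(m * n_sim, rep(tot, n_sim), 0.5, rho)
    km <- matrix(pmax(k, rep(tot, n_sim) - k), nrow = m)
    colSums(km) / sum(tot)
  })
  p <- (1 + sum(t_null >= t_obs - 1e-12)) / (n_sim + 1)

  structure(list(aggregate_maf = t_obs, p_value = p, n_snvs = m,
                 n_sim = n_sim),
            class = "mbased_ase")
}

#' @export
print.mbased_ase <- function(x, ...) {
  cat(sprintf(
    "<mbased_ase> %d SNV(s): aggregate MAF %.3f, p = %.4g (%d sims)\n",
    x$n_snvs, x$aggregate_maf, x$p_value, x$n_sim))
  invisible(x)
}

#' @rdname mbased_gene_ase
#' @param x An `mbased_ase` object.
#' @param ... Unused.
#' @method tidy mbased_ase
#' @export
tidy.mbased_ase <- function(x, ...) {
  tibble(n_snvs = x$n_snvs, aggregate_maf = x$aggregate_maf,
         p_value = x$p_value, n_sim = x$n_sim)
}

#' Gene-level ASE from a single SNV
#'
#' A gene with exactly one RNA-covered het SNV inherits that SNP's ASE
#' decision: the gene-level aggregate major-allele frequency is
#' `max(ref, alt)/total` and the p-values are the SNP's.
#'
#' @param ref_count,alt_count The SNV's read counts.
#' @param p_value,p_adj,significant The SNV-level test results.
#' @return A one-row tibble: `n_snvs`, `aggregate_maf`, `p_value`,
#'   `p_adj`, `is_ase`.
#' @export
gene_ase_single <- function(ref_count, alt_count, p_value, p_adj,
                            significant) {
  stop_if_not(ref_count + alt_count >= 1, "SNV needs at least one read")
  tibble(n_snvs = 1L,
         aggregate_maf = max(ref_count, alt_count) / (ref_count + alt_count),
         p_value = p_value, p_adj = p_adj, is_ase = significant)
}

#' Call allele-specifically expressed genes
#'
#' Combines SNP-level ASE evidence into gene-level calls per individual.
#' A gene with a single RNA-covered het SNV inherits that SNP's (already
#' BH-adjusted) decision; its aggregate major-allele frequency is
#' `max(ref, alt)/total`. Genes with two or more SNVs are tested with
#' [mbased_gene_ase()] and their Monte-Carlo p-values are BH-adjusted
#' across multi-SNV genes within the individual; a gene is ASE when
#' `p_adj < alpha`. With `rule = "any_snv"`, a multi-SNV gene is instead
#' called ASE when any of its SNVs is individually significant.
#'
#' @param gene_sites Output of [snvs_in_gene()] on RNA het sites: columns
#'   `gene_id`, `chrom`, `pos`.
#' @param rna_calls RNA rows of [call_events()] output.
#' @param alpha Gene-level significance threshold, default 0.1.
#' @param n_sim,rho Passed to [mbased_gene_ase()].
#' @param seed Base seed; each gene gets a deterministic sub-seed so the
#'   result is invariant to row order.
#' @param rule `"mbased"` (default) or `"any_snv"` for multi-SNV genes.
#' @return A tibble: `gene_id`, `individual_id`, `n_snvs`, `aggregate_maf`,
#'   `p_value`, `p_adj`, `is_ase`.
#' @export
call_ase_genes <- function(gene_sites, rna_calls, alpha = 0.1,
                           n_sim = 9999, seed = 1L, rho = 0,
                           rule = c("mbased", "any_snv")) {
  rule <- match.arg(rule)
  df <- rna_calls |>
    filter(.data$assay == "RNA") |>
    inner_join(gene_sites |> distinct(.data$gene_id, .data$chrom, .data$pos),
               by = c("chrom", "pos"), relationship = "many-to-many")
  if (nrow(df) == 0) {
    return(tibble(gene_id = character(), individual_id = character(),
                  n_snvs = integer(), aggregate_maf = numeric(),
                  p_value = numeric(), p_adj = numeric(), is_ase = logical()))
  }
  gene_levels <- sort(unique(df$gene_id))

  res <- df |>
    arrange(.data$individual_id, .data$gene_id, .data$pos) |>
    group_by(.data$individual_id, .data$gene_id) |>
    summarise(
      n_snvs = dplyr::n(),
      single_maf = max(.data$ref_count[1], .data$alt_count[1]) /
        (.data$ref_count[1] + .data$alt_count[1]),
      single_p = .data$p_value[1],
      single_padj = .data$p_adj[1],
      any_sig = any(.data$significant),
      refs = list(.data$ref_count), alts = list(.data$alt_count),
      .groups = "drop"
    )

  multi <- res |> filter(.data$n_snvs >= 2)
  if (nrow(multi) > 0 && rule == "mbased") {
    fits <- purrr::pmap(
      list(multi$refs, multi$alts, multi$gene_id),
      function(r, a, gid) {
        sub_seed <- (as.integer(seed) + 7L * match(gid, gene_levels)) %%
          2147483647L
        mbased_gene_ase(r, a, n_sim = n_sim, seed = sub_seed, rho = rho)
      }
    )
    multi$aggregate_maf <- purrr::map_dbl(fits, "aggregate_maf")
    multi$p_value <- purrr::map_dbl(fits, "p_value")
    multi <- multi |>
      group_by(.data$individual_id) |>
      mutate(p_adj = bh_adjust(.data$p_value)) |>
      ungroup() |>
      mutate(is_ase = .data$p_adj < alpha)
  } else if (nrow(multi) > 0) {
    multi <- multi |>
      mutate(aggregate_maf = NA_real_, p_value = NA_real_,
             p_adj = NA_real_, is_ase = .data$any_sig)
  } else {
    multi <- multi |>
      mutate(aggregate_maf = numeric(), p_value = numeric(),
             p_adj = numeric(), is_ase = logical())
  }

  single <- res |>
    filter(.data$n_snvs == 1) |>
    mutate(aggregate_maf = .data$single_maf, p_value = .data$single_p,
           p_adj = .data$single_padj, is_ase = .data$any_sig)

  bind_rows(single, multi) |>
    select("gene_id", "individual_id", "n_snvs", "aggregate_maf",
           "p_value", "p_adj", "is_ase") |>
    arrange(.data$individual_id, .data$gene_id)
}
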