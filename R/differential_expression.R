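as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stop_if_not(is.data.frame(counts) && names(counts)[1] == "gene_id",
              "`counts` must be a matrix or a tibble with gene_id first")
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$gene_id
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of the ratio of the
#' sample's count to the gene's geometric mean.
#'
#' @param counts Genes x samples matrix of non-negative counts, or a tibble
#'   with a leading `gene_id` column.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  stop_if_not(all(m >= 0), "counts must be non-negative")
  log_gm <- rowMeans(log(m))           # -Inf for genes with any zero
  use <- is.finite(log_gm)
  stop_if_not(any(use), "no gene has all-positive counts")
  apply(m[use, , drop = FALSE], 2,
        function(col) exp(median(log(col) - log_gm[use])))
}

#' Negative-binomial Wald differential expression
#'
#' A documented NB-Wald core (not a DESeq2 replica): counts are normalised
#' by size factors; per gene, the group log2 fold change is estimated from
#' normalised group means, a method-of-moments dispersion is pooled over
#' the two groups (floored at 1e-8), and the Wald statistic `z = b/se(b)`
#' with `se` from the delta method on the NB mean-variance relation gives a
#' two-sided normal p-value. P-values are BH-adjusted over genes and genes
#' are flagged as differentially expressed when `|log2fc| > lfc` and
#' `p_adj < alpha`. All-zero genes are excluded (reported in the
#' `n_excluded` attribute).
#'
#' @param counts Genes x samples matrix (or tibble with `gene_id` first).
#' @param labels Tibble with `sample_id`, `condition` (two levels), or a
#'   vector of conditions in column order.
#' @param sf Optional size factors; computed with [size_factors()] when
#'   missing.
#' @param reference Reference condition level (default: first
#'   alphabetically); `log2fc > 0` means higher in the other group.
#' @param lfc Absolute log2-fold-change gate, default 0.2.
#' @param alpha Adjusted-p gate, default 0.05.
#' @return A tibble: `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p_value`, `p_adj`, `is_deg`, `direction` (`"up"`/`"down"`).
#' @export
nb_wald_test <- function(counts, labels, sf = NULL, reference = NULL,
                         lfc = 0.2, alpha = 0.05) {
  m <- as_count_matrix(counts)
  cond <- if (is.data.frame(labels)) {
    labels$condition[match(colnames(m), labels$sample_id)]
  } else as.character(labels)
  stop_if_not(length(cond) == ncol(m) && !anyNA(cond),
              "labels must cover every sample")
  lev <- sort(unique(cond))
  stop_if_not(length(lev) == 2, "exactly two condition groups required")
  if (!is.null(reference)) {
    stop_if_not(reference %in% lev, "unknown reference level")
    lev <- c(reference, setdiff(lev, reference))
  }
  g1 <- cond == lev[1]; g2 <- cond == lev[2]
  stop_if_not(sum(g1) >= 2 && sum(g2) >= 2, ">=2 samples per group required")

  nonzero <- rowSums(m) > 0
  n_excluded <- sum(!nonzero)
  m <- m[nonzero, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")

  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, var)

  # pooled method-of-moments NB dispersion: var = mu + alpha * mu^2
  disp_of <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  disp <- rowMeans(cbind(disp_of(m1, v1), disp_of(m2, v2)), na.rm = TRUE)
  disp <- ifelse(is.nan(disp), 1e-8, disp)
  # per-gene moment estimates are noisy at typical group sizes and a
  # spuriously small dispersion inflates the Wald statistic; floor at the
  # dataset's median moment dispersion (no gene-wise shrinkage beyond this)
  disp_common <- max(median(disp, na.rm = TRUE), 0)
  disp <- pmax(disp, disp_common, 1e-8)

  # continuity offset only where a group mean is zero
  eps <- 0.125
  m1a <- ifelse(m1 == 0, eps, m1)
  m2a <- ifelse(m2 == 0, eps, m2)
  log2fc <- log2(m2a / m1a)
  se <- sqrt((1 / m1a + disp) / n1 + (1 / m2a + disp) / n2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(p)

  out <- tibble(
    gene_id = rownames(m),
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, stat = z,
    p_value = p, p_adj = padj,
    is_deg = abs(log2fc) > lfc & padj < alpha,
    direction = if_else(log2fc > 0, "up", "down")
  )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "reference") <- lev[1]
  out
}

#' Intersect DEG promoters with the rSNP panel
#'
#' For each differentially expressed gene, lists the panel SNPs lying in
#' any of its promoter intervals, and tallies genes and rSNPs per
#' regulation direction.
#'
#' @param de_results [nb_wald_test()] output.
#' @param panel [assemble_panel()] output (`chrom`, `pos`).
#' @param promoter_tbl [promoters()] output.
#' @return A list: `hits` (tibble `gene_id`, `direction`, `chrom`, `pos`),
#'   one row per (DEG, promoter rSNP) pair, and `totals` (tibble with
#'   `n_genes_up`, `n_rsnps_up`, `n_genes_down`, `n_rsnps_down`,
#'   `n_genes_total`, `n_rsnps_total`).
#' @export
deg_rsnp_intersection <- function(de_results, panel, promoter_tbl) {
  degs <- de_results |> filter(.data$is_deg)
  proms <- promoter_tbl |>
    inner_join(degs |> select("gene_id", "direction"), by = "gene_id")
  hits <- purrr::pmap(
    list(proms$gene_id, proms$direction, proms$chrom, proms$start,
         proms$end),
    function(gid, dir, chr, s, e) {
      panel |>
        filter(.data$chrom == chr, .data$pos >= s, .data$pos <= e) |>
        mutate(gene_id = gid, direction = dir) |>
        select("gene_id", "direction", "chrom", "pos")
    }
  ) |>
    bind_rows() |>
    distinct()

  tally <- function(dir) {
    h <- hits |> filter(.data$direction == dir)
    c(genes = length(unique(h$gene_id)),
      rsnps = nrow(h |> distinct(.data$chrom, .data$pos)))
  }
  up <- tally("up"); down <- tally("down")
  # per-direction rSNP counts are distinct within direction and the grand
  # total is their sum, so totals stay additive over direction
  totals <- tibble(
    n_genes_up = up[["genes"]], n_rsnps_up = up[["rsnps"]],
    n_genes_down = down[["genes"]], n_rsnps_down = down[["rsnps"]],
    n_genes_total = length(unique(hits$gene_id)),
    n_rsnps_total = up[["rsnps"]] + down[["rsnps"]]
  )
  list(hits = hits, totals = totals)
}
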