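#' Match panel SNPs against a variant catalog
#'
#' Classifies each panel SNP as `direct` (identical `rs_id` or identical
#' `(chrom, pos)` in the catalog; identifier matches count as direct even
#' when the stored position differs), `proximal` (within `window` bp of a
#' catalog variant on the same chromosome, boundary inclusive), or `none`.
#' Direct takes precedence; `window = 0` reduces to direct-only matching.
#'
#' @param panel Tibble with `chrom`, `pos` (optionally `rs_id`).
#' @param catalog Tibble with `chrom`, `pos` (optionally `rs_id`), usually
#'   one catalog's rows.
#' @param window Matching half-window in bp, default 1000.
#' @return `panel` with a `match_status` factor column
#'   (`direct`/`proximal`/`none`) and `min_distance` to the nearest catalog
#'   variant on the same chromosome (NA when none).
#' @export
window_match <- function(panel, catalog, window = 1000) {
  id_direct <- if ("rs_id" %in% names(panel) && "rs_id" %in% names(catalog)) {
    panel$rs_id %in% catalog$rs_id
  } else rep(FALSE, nrow(panel))

  min_dist <- rep(NA_real_, nrow(panel))
  for (chr in unique(panel$chrom)) {
    cp <- sort(unique(catalog$pos[catalog$chrom == chr]))
    idx <- which(panel$chrom == chr)
    if (length(cp) == 0 || length(idx) == 0) next
    pp <- panel$pos[idx]
    right <- findInterval(pp, cp) # nearest catalog pos <= pp
    d_lo <- ifelse(right >= 1, pp - cp[pmax(right, 1)], Inf)
    d_hi <- ifelse(right < length(cp), cp[pmin(right + 1, length(cp))] - pp,
                   Inf)
    min_dist[idx] <- pmin(d_lo, d_hi)
  }
  panel |>
    mutate(
      min_distance = min_dist,
      match_status = factor(
        dplyr::case_when(
          id_direct | (!is.na(min_dist) & min_dist == 0) ~ "direct",
          !is.na(min_dist) & min_dist <= window ~ "proximal",
          TRUE ~ "none"
        ),
        levels = c("direct", "proximal", "none")
      )
    )
}

# OR, Woolf CI and p-values for a 2x2 table; Haldane 0.5 correction for the
# OR/CI whenever any cell is zero
or_woolf <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' 2x2 enrichment of a panel against a catalog
#'
#' Odds ratio `(a*d)/(b*c)` with Haldane's 0.5 correction when any cell is
#' zero, Woolf 95% confidence interval on the log scale, a two-sided exact
#' Fisher p-value (minimum-likelihood convention, via
#' [stats::fisher.test()]) and a 1-df Pearson chi-square p-value without
#' continuity correction.
#'
#' @param a,b,c,d Cell counts: panel-and-catalog, panel-only,
#'   background-and-catalog, background-only.
#' @return An object of class `enrich2x2` with fields `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_fisher`, `p_chi2`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' enrichment_2x2(20, 10, 10, 20)$odds_ratio # 4
enrichment_2x2 <- function(a, b, c, d) {
  stop_if_not(all(c(a, b, c, d) >= 0) && all(c(a, b, c, d) == floor(c(a, b, c, d))),
              "cells must be non-negative integers")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p_fisher <- stats::fisher.test(m)$p.value
  p_chi2 <- tryCatch(
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
    error = function(e) NA_real_
  )
  est <- or_woolf(a, b, c, d)
  structure(c(list(a = a, b = b, c = c, d = d), est,
              list(p_fisher = p_fisher, p_chi2 = p_chi2)),
            class = "enrich2x2")
}

#' @export
print.enrich2x2 <- function(x, ...) {
  cat(sprintf(
    "<enrich2x2> [%d %d; %d %d]  OR = %.3g (95%% CI %.3g-%.3g)\n  Fisher p = %.3g, chi-square p = %.3g\n",
    x$a, x$b, x$c, x$d, x$odds_ratio, x$ci_low, x$ci_high,
    x$p_fisher, x$p_chi2))
  invisible(x)
}

#' @rdname enrichment_2x2
#' @param x An `enrich2x2` object.
#' @param ... Unused.
#' @method tidy enrich2x2
#' @export
tidy.enrich2x2 <- function(x, ...) {
  tibble(estimate = x$odds_ratio, conf.low = x$ci_low,
         conf.high = x$ci_high, p.value = x$p_fisher,
         p.value.chisq = x$p_chi2, method = "fisher/chi-square 2x2")
}

#' @rdname enrichment_2x2
#' @method glance enrich2x2
#' @export
glance.enrich2x2 <- function(x, ...) {
  tibble(n = x$a + x$b + x$c + x$d, n_panel = x$a + x$b,
         n_catalog = x$a + x$c, odds_ratio = x$odds_ratio)
}

#' Per-trait enrichment of the panel in a GWAS-like catalog
#'
#' For each trait with at least `min_catalog` catalog variants, tests
#' direct panel membership in the trait's variant set against a background
#' of heterozygous non-panel sites (Fisher exact), adjusts across traits
#' with Benjamini-Hochberg, and ranks rows by the number of directly
#' matched panel SNPs.
#'
#' @param panel Tibble with `chrom`, `pos` (optionally `rs_id`).
#' @param gwas_catalog Catalog tibble with `chrom`, `pos`, `label` (trait).
#' @param background Tibble of background sites (`chrom`, `pos`): tested
#'   heterozygous sites not in the panel.
#' @param min_catalog Minimum catalog size per trait, default 100.
#' @param alpha Significance threshold on `p_adj`, default 0.1.
#' @return A tibble, one row per retained trait: `trait`,
#'   `n_catalog_total`, `n_rsnp_direct`, `n_background_direct`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `p_adj`, `significant`;
#'   sorted by `n_rsnp_direct` descending.
#' @export
trait_enrichment <- function(panel, gwas_catalog, background,
                             min_catalog = 100, alpha = 0.1) {
  sizes <- gwas_catalog |> count(.data$label, name = "n_catalog_total")
  traits <- sizes |> filter(.data$n_catalog_total >= min_catalog)
  if (nrow(traits) == 0) {
    return(tibble(trait = character(), n_catalog_total = integer(),
                  n_rsnp_direct = integer(), n_background_direct = integer(),
                  odds_ratio = numeric(), ci_low = numeric(),
                  ci_high = numeric(), p_value = numeric(),
                  p_adj = numeric(), significant = logical()))
  }
  key <- function(df) paste(df$chrom, df$pos)
  pk <- key(panel); bk <- key(background)
  rows <- purrr::pmap(
    list(traits$label, traits$n_catalog_total),
    function(tr, ntot) {
      tk <- key(gwas_catalog |> filter(.data$label == tr))
      a <- sum(pk %in% tk); b <- length(pk) - a
      c <- sum(bk %in% tk); d <- length(bk) - c
      est <- or_woolf(a, b, c, d)
      tibble(trait = tr, n_catalog_total = ntot, n_rsnp_direct = a,
             n_background_direct = c, odds_ratio = est$odds_ratio,
             ci_low = est$ci_low, ci_high = est$ci_high,
             p_value = stats::fisher.test(
               matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value)
    }
  ) |> bind_rows()
  rows |>
    mutate(p_adj = bh_adjust(.data$p_value),
           significant = .data$p_adj < alpha) |>
    arrange(desc(.data$n_rsnp_direct))
}

#' Percentage with half-up rounding to one decimal
#'
#' `100 * numerator / denominator`, rounded half-up at the first decimal
#' (so 7.48 prints as 7.5).
#'
#' @param numerator,denominator Numeric vectors (recycled).
#' @param as_label Return formatted strings like `"7.5%"` instead of
#'   numbers.
#' @return Numeric vector of percentages (or character labels).
#' @export
#' @examples
#' report_fractions(1107, 14796) # 7.5
report_fractions <- function(numerator, denominator, as_label = FALSE) {
  stop_if_not(all(denominator > 0), "denominator must be positive")
  pct <- floor(1000 * numerator / denominator + 0.5) / 10
  if (as_label) sprintf("%.1f%%", pct) else pct
}

#' Three-way catalog overlap (Venn regions)
#'
#' Partitions the panel by membership in the three catalogs into the seven
#' non-empty Venn regions plus the outside region; the eight counts always
#' sum to the panel size.
#'
#' @param flags Tibble/data frame of logicals with columns `gwas`, `eqtl`,
#'   `tf_asb`, one row per panel SNP.
#' @return A tibble: `gwas`, `eqtl`, `tf_asb` (logical region key),
#'   `region` (label like `"GWAS+eQTL"` or `"none"`), `n`.
#' @export
three_way_overlap <- function(flags) {
  stop_if_not(all(c("gwas", "eqtl", "tf_asb") %in% names(flags)),
              "`flags` needs logical columns gwas, eqtl, tf_asb")
  grid <- tidyr::expand_grid(gwas = c(TRUE, FALSE), eqtl = c(TRUE, FALSE),
                             tf_asb = c(TRUE, FALSE))
  grid |>
    mutate(
      region = purrr::pmap_chr(list(.data$gwas, .data$eqtl, .data$tf_asb),
        function(g, e, t) {
          lab <- c("GWAS", "eQTL", "TF_ASB")[c(g, e, t)]
          if (length(lab) == 0) "none" else paste(lab, collapse = "+")
        }),
      n = purrr::pmap_int(list(.data$gwas, .data$eqtl, .data$tf_asb),
        function(g, e, t) {
          sum(flags$gwas == g & flags$eqtl == e & flags$tf_asb == t)
        })
    )
}
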