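#' Pool assays and call heterozygous sites for one individual
#'
#' Sums reference and alternative read counts over all assays per site and
#' keeps sites that satisfy the heterozygote rule: pooled depth strictly
#' greater than 20 and pooled minor-allele fraction of at least 0.2.
#'
#' @param depths Allele-depth tibble (columns `individual_id`, `assay`,
#'   `chrom`, `pos`, `ref_base`, `alt_base`, `ref_count`, `alt_count`), all
#'   rows belonging to one individual.
#' @param min_depth Pooled depth must exceed this (strict), default 20.
#' @param min_minor_fraction Minimum pooled minor-allele fraction
#'   (inclusive), default 0.2.
#' @return A tibble of heterozygous sites: `individual_id`, `chrom`, `pos`,
#'   `ref_base`, `alt_base`, `pooled_depth`, `pooled_minor_fraction`.
#' @export
#' @examples
#' d <- tibble::tibble(individual_id = "i1",
#'                     assay = c("H3K4me3", "RNA"), chrom = "chr1",
#'                     pos = 100L, ref_base = "A", alt_base = "G",
#'                     ref_count = c(10L, 5L), alt_count = c(6L, 4L))
#' pool_and_call_het(d)
pool_and_call_het <- function(depths, min_depth = 20,
                              min_minor_fraction = 0.2) {
  stop_if_not(length(unique(depths$individual_id)) <= 1,
              "`depths` must contain a single individual")
  conflict <- depths |>
    group_by(.data$chrom, .data$pos) |>
    summarise(nb = dplyr::n_distinct(paste(.data$ref_base, .data$alt_base)),
              .groups = "drop") |>
    filter(.data$nb > 1)
  if (nrow(conflict) > 0) {
    abort(paste0("conflicting ref/alt annotations at ",
                 paste(conflict$chrom, conflict$pos, sep = ":",
                       collapse = ", ")), call = NULL)
  }
  depths |>
    group_by(.data$individual_id, .data$chrom, .data$pos,
             .data$ref_base, .data$alt_base) |>
    summarise(ref = sum(.data$ref_count), alt = sum(.data$alt_count),
              .groups = "drop") |>
    mutate(pooled_depth = .data$ref + .data$alt,
           pooled_minor_fraction = pmin(.data$ref, .data$alt) /
             .data$pooled_depth) |>
    filter(.data$pooled_depth > min_depth,
           .data$pooled_minor_fraction >= min_minor_fraction) |>
    select("individual_id", "chrom", "pos", "ref_base", "alt_base",
           "pooled_depth", "pooled_minor_fraction")
}

#' Exact two-sided binomial asymmetry p-value
#'
#' Tests the observed reference/alternative read split against equal
#' coverage (success probability 0.5) with the exact binomial test, using
#' the minimum-likelihood two-sided definition: the p-value is the sum of
#' `P(X = k)` over all outcomes whose probability does not exceed that of
#' the observed count. Symmetric in its arguments. Vectorised; pairs are
#' grouped by total to reuse each probability mass function.
#'
#' @param ref_count,alt_count Non-negative integer vectors (recycled to a
#'   common length); each pair must have a positive total.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' binomial_asymmetry_p(5, 5)     # 1
#' binomial_asymmetry_p(10, 0)    # 2 * 0.5^10
binomial_asymmetry_p <- function(ref_count, alt_count) {
  k <- pmax(ref_count, alt_count)   # symmetry: work on the major count
  n <- ref_count + alt_count
  stop_if_not(all(n >= 1), "each site needs at least one read")
  stop_if_not(all(ref_count >= 0 & alt_count >= 0), "counts must be >= 0")
  out <- numeric(length(n))
  for (tot in unique(n)) {
    idx <- which(n == tot)
    pmf <- dbinom(0:tot, tot, 0.5)
    obs <- pmf[k[idx] + 1L]
    # include all outcomes with pmf <= observed pmf (tolerance for ties)
    out[idx] <- vapply(obs, function(p0) {
      sum(pmf[pmf <= p0 * (1 + 1e-7)])
    }, numeric(1))
  }
  pmin(out, 1)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' ascending p-values are scaled by `n/rank`, the running minimum is taken
#' from the largest rank down, values are capped at 1, and the result is
#' returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stop_if_not(is.numeric(p) && all(!is.na(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call allele-specific binding and expression events
#'
#' For each heterozygous site of each individual, tests the assay-level
#' allele split (any assay with at least one read at the site) for
#' asymmetry with [binomial_asymmetry_p()], adjusts within a
#' family — per `(individual, assay)` by default, or one global
#' family — and flags significance at `p_adj < alpha`. ChIP assays yield
#' ASB events, RNA yields ASE events. The preferred allele is the one with
#' the larger count (`ref` on ties, with a tie flag).
#'
#' @param het_sites Output of [pool_and_call_het()] (may cover several
#'   individuals, bound by rows).
#' @param depths Full allele-depth tibble for the same individuals.
#' @param alpha Significance threshold on the adjusted p-value, default 0.1.
#' @param family `"per_individual_assay"` (default) or `"global"` BH family.
#' @return A tibble: `individual_id`, `assay`, `event_class` (`"ASB"` or
#'   `"ASE"`), `chrom`, `pos`, `ref_base`, `alt_base`, `ref_count`,
#'   `alt_count`, `p_value`, `p_adj`, `significant`, `preferred_allele`,
#'   `tie`.
#' @export
call_events <- function(het_sites, depths, alpha = 0.1,
                        family = c("per_individual_assay", "global")) {
  family <- match.arg(family)
  calls <- depths |>
    inner_join(het_sites |> select("individual_id", "chrom", "pos"),
               by = c("individual_id", "chrom", "pos")) |>
    filter(.data$ref_count + .data$alt_count >= 1) |>
    mutate(
      event_class = if_else(.data$assay == "RNA", "ASE", "ASB"),
      p_value = binomial_asymmetry_p(.data$ref_count, .data$alt_count),
      tie = .data$ref_count == .data$alt_count,
      preferred_allele = if_else(.data$alt_count > .data$ref_count,
                                 "alt", "ref")
    )
  calls <- if (family == "per_individual_assay") {
    calls |>
      group_by(.data$individual_id, .data$assay) |>
      mutate(p_adj = bh_adjust(.data$p_value)) |>
      ungroup()
  } else {
    calls |> mutate(p_adj = bh_adjust(.data$p_value))
  }
  calls |>
    mutate(significant = .data$p_adj < alpha) |>
    select("individual_id", "assay", "event_class", "chrom", "pos",
           "ref_base", "alt_base", "ref_count", "alt_count",
           "p_value", "p_adj", "significant", "preferred_allele", "tie")
}

#' Assign rs identifiers to called events
#'
#' Left-joins calls with a `(chrom, pos, rs_id)` lookup; positions missing
#' from the map receive the deterministic synthetic identifier
#' `novel_<chrom>_<pos>`. No rows are dropped.
#'
#' @param calls Event tibble with `chrom` and `pos` columns.
#' @param id_map Tibble with columns `chrom`, `pos`, `rs_id`.
#' @return `calls` with an `rs_id` column appended.
#' @export
assign_rs_ids <- function(calls, id_map) {
  calls |>
    left_join(id_map |> distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
                select("chrom", "pos", "rs_id"),
              by = c("chrom", "pos")) |>
    mutate(rs_id = if_else(is.na(.data$rs_id),
                           paste0("novel_", .data$chrom, "_", .data$pos),
                           .data$rs_id))
}
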