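#' Strand-aware promoter intervals
#'
#' Builds one +/-1000 bp promoter interval around every distinct
#' transcription start site of every gene (alternative TSSs included;
#' transcripts sharing a TSS are deduplicated to one interval). Intervals
#' are 1-based inclusive and clipped at position 1.
#'
#' @param transcripts Tibble with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (and optionally a precomputed `tss`).
#' @param flank Half-width of the promoter, default 1000 bp.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `source_tss`.
#' @export
#' @examples
#' tx <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-",
#'                      start = 2000L, end = 5000L)
#' promoters(tx) # promoter [4000, 6000] around the minus-strand TSS
promoters <- function(transcripts, flank = 1000L) {
  stop_if_not(all(transcripts$strand %in% c("+", "-")),
              "strand must be '+' or '-'")
  stop_if_not(all(transcripts$start <= transcripts$end),
              "transcript start must be <= end")
  tx <- transcripts
  if (!"tss" %in% names(tx)) {
    tx <- tx |> mutate(tss = if_else(.data$strand == "+",
                                     .data$start, .data$end))
  }
  tx |>
    distinct(.data$gene_id, .data$chrom, .data$tss) |>
    mutate(start = pmax(1L, as.integer(.data$tss) - as.integer(flank)),
           end = as.integer(.data$tss) + as.integer(flank),
           source_tss = as.integer(.data$tss)) |>
    select("gene_id", "chrom", "start", "end", "source_tss")
}

#' Promoter ASB hits
#'
#' Intersects significant allele-specific-binding calls with promoter
#' intervals (both ends inclusive). A SNP inside the promoters of two genes
#' yields two hit rows.
#'
#' @param asb_calls [call_events()] output; only rows with
#'   `event_class == "ASB"` and `significant == TRUE` are used.
#' @param promoter_tbl [promoters()] output.
#' @return The significant ASB rows joined with `gene_id` and
#'   `source_tss` of each containing promoter.
#' @export
promoter_asb <- function(asb_calls, promoter_tbl) {
  hits <- asb_calls |>
    filter(.data$event_class == "ASB", .data$significant)
  purrr::pmap(
    list(promoter_tbl$gene_id, promoter_tbl$chrom, promoter_tbl$start,
         promoter_tbl$end, promoter_tbl$source_tss),
    function(gid, chr, s, e, tss) {
      hits |>
        filter(.data$chrom == chr, .data$pos >= s, .data$pos <= e) |>
        mutate(gene_id = gid, source_tss = tss)
    }
  ) |>
    bind_rows() |>
    distinct(.data$individual_id, .data$assay, .data$chrom, .data$pos,
             .data$gene_id, .keep_all = TRUE)
}

#' Assemble the regulatory-SNP panel
#'
#' A promoter ASB SNP becomes a regulatory SNP (rSNP) when its target gene
#' is expressed allele-specifically. By default the ASB and ASE evidence
#' must come from the same individual; `same_individual = FALSE` accepts
#' ASE evidence from any individual. Hits are merged across individuals by
#' position: a site is in the panel when supported in at least
#' `min_individuals` individuals.
#'
#' @param hits [promoter_asb()] output.
#' @param gene_ase [call_ase_genes()] output.
#' @param same_individual Require ASB and ASE in the same individual
#'   (default TRUE).
#' @param min_individuals Minimum number of supporting individuals,
#'   default 1.
#' @return A tibble, one row per panel SNP: `chrom`, `pos`, `ref_base`,
#'   `alt_base`, `target_genes` (list column), `n_target_genes`,
#'   `individuals` (list column), `n_individuals`, `assays` (list column).
#' @export
assemble_panel <- function(hits, gene_ase, same_individual = TRUE,
                           min_individuals = 1L) {
  ase <- gene_ase |> filter(.data$is_ase)
  paired <- if (same_individual) {
    hits |> inner_join(ase |> select("gene_id", "individual_id"),
                       by = c("gene_id", "individual_id"))
  } else {
    hits |> inner_join(ase |> distinct(.data$gene_id), by = "gene_id")
  }
  paired |>
    arrange(.data$chrom, .data$pos, .data$individual_id, .data$gene_id) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      ref_base = .data$ref_base[1], alt_base = .data$alt_base[1],
      target_genes = list(sort(unique(.data$gene_id))),
      n_target_genes = length(unique(.data$gene_id)),
      individuals = list(sort(unique(.data$individual_id))),
      n_individuals = length(unique(.data$individual_id)),
      assays = list(sort(unique(.data$assay))),
      .groups = "drop"
    ) |>
    filter(.data$n_individuals >= min_individuals) |>
    arrange(.data$chrom, .data$pos)
}

#' Export a panel as BED (0-based, half-open)
#'
#' @param panel [assemble_panel()] output (optionally with `rs_id`).
#' @param path Output file.
#' @return Invisibly, the BED tibble written.
#' @export
panel_to_bed <- function(panel, path) {
  bed <- tibble(
    chrom = panel$chrom,
    start = panel$pos - 1L,
    end = panel$pos,
    name = if ("rs_id" %in% names(panel)) panel$rs_id
           else paste0(panel$chrom, ":", panel$pos),
    score = panel$n_individuals,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(bed)
}
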