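# Candidate ranking and run summaries: joins calls and scores across
# datasets into the decision logic that proved predictive of validation —
# reciprocal bias with depth (the imprinting score), agreement among
# neighbouring SNPs, and recurrence across samples/tissues.

#' Rank candidate imprinted genes across datasets
#'
#' @param gene_calls Named list of per-dataset gene call tibbles
#'   ([call_genes()] output).
#' @param snp_calls Optional named list (same names) of per-SNP call
#'   tibbles carrying `gene_id`, used for the supporting-SNP count (SNPs
#'   individually reciprocal at p < 0.05).
#' @param models Gene models (exon-level tibble) for gene coordinates.
#' @param catalog Known-imprinted catalog for the distance feature.
#' @param recurrence_score Absolute imprinting score above which a dataset
#'   counts toward recurrence (default 4, i.e. p < 1e-4).
#' @return Tibble sorted by (recurrence, best |score|, supporting SNPs),
#'   gene_id lexicographic as final tie-break: `gene_id`, `best_score`,
#'   `n_supporting_snps`, `n_samples_recurrent`, `distance_to_known`
#'   (bp; NA when no catalog gene shares the chromosome), `proximity`.
#' @export
rank_candidates <- function(gene_calls, snp_calls = NULL, models = NULL,
                            catalog = NULL, recurrence_score = 4) {
  stopifnot(length(gene_calls) >= 1)
  long <- dplyr::bind_rows(gene_calls, .id = "dataset")
  per_gene <- long |>
    dplyr::summarise(
      best_score = if (all(is.na(.data$score))) NA_real_
        else .data$score[which.max(abs(.data$score))],
      n_samples_recurrent = sum(abs(.data$score) > recurrence_score,
                                na.rm = TRUE),
      .by = "id") |>
    dplyr::rename(gene_id = "id")
  supp <- if (!is.null(snp_calls)) {
    dplyr::bind_rows(snp_calls, .id = "dataset") |>
      dplyr::filter(.data$status == "imprinted") |>
      dplyr::summarise(n_supporting_snps = dplyr::n_distinct(.data$id),
                       .by = "gene_id")
  } else {
    tibble::tibble(gene_id = character(), n_supporting_snps = integer())
  }
  out <- dplyr::left_join(per_gene, supp, by = "gene_id")
  out$n_supporting_snps[is.na(out$n_supporting_snps)] <- 0L
  out$distance_to_known <- NA_real_
  if (!is.null(models) && !is.null(catalog) && nrow(catalog)) {
    spans <- models |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .by = c("gene_id", "chrom"))
    out <- dplyr::left_join(out, spans, by = "gene_id")
    out$distance_to_known <- vapply(seq_len(nrow(out)), function(i) {
      if (is.na(out$chrom[i])) return(NA_real_)
      cat_chr <- catalog[catalog$chrom == out$chrom[i] &
                           catalog$gene_id != out$gene_id[i], ]
      if (!nrow(cat_chr)) return(NA_real_)
      # interval gap; 0 when overlapping/adjacent
      min(pmax(0, pmax(cat_chr$start - out$end[i],
                       out$start[i] - cat_chr$end)))
    }, numeric(1))
    out$start <- out$end <- out$chrom <- NULL
  }
  out$proximity <- proximity_flag(out$distance_to_known)
  out[order(-out$n_samples_recurrent,
            -abs(dplyr::coalesce(out$best_score, -Inf)),
            -out$n_supporting_snps, out$gene_id), ]
}

#' Classify a candidate by distance to the nearest known imprinted gene
#'
#' @param distance_bp Distance(s) in bp (0 = overlap/adjacency; NA = no
#'   known gene on the chromosome).
#' @param window Cluster window in bp (default 1 Mb).
#' @return `"extension_candidate"` (distance 0), `"cluster_associated"`
#'   (< window), else `"novel"`.
#' @export
proximity_flag <- function(distance_bp, window = 1e6) {
  dplyr::case_when(
    is.na(distance_bp) ~ "novel",
    distance_bp == 0 ~ "extension_candidate",
    distance_bp < window ~ "cluster_associated",
    .default = "novel"
  )
}
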