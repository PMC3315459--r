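# Reciprocal-cross imprinting calls at SNP and gene level.
#
# The decision rule, applied identically at any unit (a SNP or a gene's
# summed counts): imprinted iff depth >= min_reads in BOTH samples, the
# chi-square ASE p-value is < alpha in BOTH, and the maternal read fraction
# is on the same side of 0.5 in both (reciprocal parent-of-origin bias).
# Either depth below min_reads makes the unit underpowered.

#' Call criteria for reciprocal imprinting calls
#'
#' @param min_reads Minimum allelic depth per sample for a unit to be
#'   powered (default 10).
#' @param alpha Per-sample chi-square significance threshold, strict `<`.
#'   0.05 is the SNP-level replication mode; 1e-4 the gene-aggregate
#'   discovery mode (empirical FDR < 0.05).
#' @return A `call_criteria` list.
#' @export
call_criteria <- function(min_reads = 10L, alpha = 0.05) {
  stopifnot(min_reads >= 1, alpha > 0, alpha < 1)
  structure(list(min_reads = as.integer(min_reads), alpha = alpha),
            class = "call_criteria")
}

#' Reciprocal imprinting calls for a table of units
#'
#' Vectorized core caller: one row per unit (SNP or gene) with the allelic
#' counts of the two compared samples.
#'
#' @param units Tibble with columns `id`, `count_B1`, `count_C1`,
#'   `count_B2`, `count_C2`.
#' @param cross1,cross2 Cross labels of sample 1 and sample 2. For a mock
#'   comparison pass the pretend labels (e.g. both samples BxC, one labelled
#'   `"CxB"`): the reciprocity rule then runs on the pretend design.
#' @param criteria A [call_criteria()] object.
#' @return Tibble: `id`, depths `n1`/`n2`, `p_1`, `p_2`, `status`
#'   (`imprinted` / `not_imprinted` / `underpowered`), `direction`
#'   (`maternal`/`paternal`/`none`), `score` (signed -log10 of the less
#'   significant p; NA when not reciprocal).
#' @export
call_units <- function(units, cross1, cross2, criteria = call_criteria()) {
  stopifnot(inherits(criteria, "call_criteria"))
  n1 <- units$count_B1 + units$count_C1
  n2 <- units$count_B2 + units$count_C2
  powered <- n1 >= criteria$min_reads & n2 >= criteria$min_reads
  # depth-0 units are underpowered by definition; keep the test defined
  safe <- function(b, c) ase_chisq(ifelse(b + c == 0, 1L, b), c)
  t1 <- safe(units$count_B1, units$count_C1)
  t2 <- safe(units$count_B2, units$count_C2)
  m1 <- ifelse(n1 > 0,
               ifelse(rep(cross1 == "BxC", nrow(units)),
                      units$count_B1, units$count_C1) / pmax(n1, 1), 0.5)
  m2 <- ifelse(n2 > 0,
               ifelse(rep(cross2 == "BxC", nrow(units)),
                      units$count_B2, units$count_C2) / pmax(n2, 1), 0.5)
  reciprocal <- (m1 > 0.5 & m2 > 0.5) | (m1 < 0.5 & m2 < 0.5)
  sig <- t1$p < criteria$alpha & t2$p < criteria$alpha
  status <- dplyr::case_when(
    !powered ~ "underpowered",
    sig & reciprocal ~ "imprinted",
    .default = "not_imprinted"
  )
  direction <- dplyr::case_when(
    status == "imprinted" & m1 > 0.5 ~ "maternal",
    status == "imprinted" & m1 < 0.5 ~ "paternal",
    .default = "none"
  )
  p_used <- pmax(t1$p, t2$p)
  score <- ifelse(reciprocal & powered,
                  ifelse(m1 > 0.5, 1, -1) * -log10(p_used), NA_real_)
  tibble::tibble(id = units$id, n1 = n1, n2 = n2,
                 p_1 = t1$p, p_2 = t2$p, status = status,
                 direction = direction, score = score)
}

#' Call one SNP from its two reciprocal samples
#'
#' @param count_B1,count_C1 Allelic counts in the first-cross sample.
#' @param count_B2,count_C2 Allelic counts in the second-cross sample.
#' @inheritParams call_units
#' @return One-row call tibble (see [call_units()]).
#' @export
call_snp <- function(count_B1, count_C1, count_B2, count_C2,
                     cross1 = "BxC", cross2 = "CxB",
                     criteria = call_criteria()) {
  call_units(tibble::tibble(id = "snp", count_B1 = count_B1,
                            count_C1 = count_C1, count_B2 = count_B2,
                            count_C2 = count_C2),
             cross1, cross2, criteria)
}

#' Sum allelic counts over the SNPs of each gene
#'
#' Allele-specific counts are summed over all SNPs assigned to a gene,
#' per sample. Genes with no assigned SNP are absent from the output.
#' A read spanning two SNPs contributes to both; the aggregate accepts
#' that double-counting because only count tables are available.
#'
#' @param counts Allelic count tibble (`snp_id`, `sample_id`, `count_B`,
#'   `count_C`).
#' @param snp_map SNP tibble with `snp_id` and `gene_id` (one row per
#'   assignment; SNPs with `NA` gene are dropped).
#' @return Tibble: `gene_id`, `sample_id`, `count_B`, `count_C`, `n_snps`.
#' @export
aggregate_gene_counts <- function(counts, snp_map) {
  map <- dplyr::filter(snp_map, !is.na(.data$gene_id))
  counts |>
    dplyr::inner_join(map[c("snp_id", "gene_id")], by = "snp_id",
                      relationship = "many-to-many") |>
    dplyr::summarise(count_B = sum(.data$count_B),
                     count_C = sum(.data$count_C),
                     n_snps = dplyr::n(),
                     .by = c("gene_id", "sample_id"))
}

#' Build the two-sample unit table for a comparison
#'
#' @param counts Long count tibble (`snp_id` or `gene_id` as unit column,
#'   `sample_id`, `count_B`, `count_C`).
#' @param sample1,sample2 The two sample ids being compared.
#' @param unit_col Name of the unit id column (`"snp_id"` or `"gene_id"`).
#' @return Wide tibble (`id`, `count_B1`, `count_C1`, `count_B2`,
#'   `count_C2`); units absent from a sample get zero counts (underpowered).
#' @export
pair_counts <- function(counts, sample1, sample2, unit_col = "gene_id") {
  a <- counts[counts$sample_id == sample1, c(unit_col, "count_B", "count_C")]
  b <- counts[counts$sample_id == sample2, c(unit_col, "count_B", "count_C")]
  names(a) <- c("id", "count_B1", "count_C1")
  names(b) <- c("id", "count_B2", "count_C2")
  out <- dplyr::full_join(a, b, by = "id")
  out[is.na(out)] <- 0L
  out
}

#' Gene-level reciprocal calls from aggregated counts
#'
#' Applies the reciprocal rule to per-gene summed counts at the discovery
#' threshold (alpha = 1e-4 by default) and attaches the signed imprinting
#' score.
#'
#' @param gene_counts Output of [aggregate_gene_counts()].
#' @param sample1,sample2 Sample ids of the two crosses compared.
#' @param cross1,cross2 Their (possibly pretend) cross labels.
#' @param criteria [call_criteria()]; default `alpha = 1e-4`.
#' @return Call tibble as from [call_units()], unit = gene.
#' @export
call_genes <- function(gene_counts, sample1, sample2,
                       cross1 = "BxC", cross2 = "CxB",
                       criteria = call_criteria(alpha = 1e-4)) {
  units <- pair_counts(gene_counts, sample1, sample2, "gene_id")
  call_units(units, cross1, cross2, criteria)
}

#' Gene calls by SNP-level replication
#'
#' A gene is imprinted iff it contains at least one imprinted SNP
#' (SNP-level rule at alpha = 0.05). Gene direction is taken from the most
#' significant imprinted SNP; ties break to the lowest genomic coordinate.
#' Genes whose SNPs are all underpowered are underpowered.
#'
#' @param snp_calls Per-SNP call tibble ([call_units()] with `id` = snp_id)
#'   joined with `gene_id` and `pos` columns.
#' @return Per-gene tibble: `gene_id`, `status`, `direction`,
#'   `n_imprinted_snps`, `n_powered_snps`.
#' @export
call_genes_via_snps <- function(snp_calls) {
  stopifnot(all(c("gene_id", "pos") %in% names(snp_calls)))
  snp_calls |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      imp <- d[d$status == "imprinted", ]
      status <- if (nrow(imp)) "imprinted"
        else if (any(d$status == "not_imprinted")) "not_imprinted"
        else "underpowered"
      direction <- "none"
      if (nrow(imp)) {
        best <- imp[order(pmax(imp$p_1, imp$p_2), imp$pos), ][1, ]
        direction <- best$direction
      }
      tibble::tibble(status = status, direction = direction,
                     n_imprinted_snps = nrow(imp),
                     n_powered_snps = sum(d$status != "underpowered"))
    }) |>
    dplyr::ungroup()
}

#' Sex-specific imprinting assessment
#'
#' Joins the reciprocal comparison of one sex against the other. A unit is
#' sex-specific only when imprinted in one sex's comparison and powered but
#' not imprinted in the other; if the non-significant sex lacks coverage
#' the unit stays `underpowered` (never claimed sex-specific).
#'
#' @param calls_sexA,calls_sexB Call tibbles (same unit ids) for the two
#'   within-sex reciprocal comparisons.
#' @param labels Names of the two sexes, used in the returned enum.
#' @return Tibble: `id`, `class` in `{<A>_specific, <B>_specific, both,
#'   neither, underpowered}`.
#' @export
call_sex_specific <- function(calls_sexA, calls_sexB,
                              labels = c("sexA", "sexB")) {
  j <- dplyr::full_join(calls_sexA[c("id", "status")],
                        calls_sexB[c("id", "status")],
                        by = "id", suffix = c("_A", "_B"))
  j$status_A[is.na(j$status_A)] <- "underpowered"
  j$status_B[is.na(j$status_B)] <- "underpowered"
  cls <- dplyr::case_when(
    j$status_A == "imprinted" & j$status_B == "imprinted" ~ "both",
    j$status_A == "imprinted" & j$status_B == "not_imprinted" ~
      paste0(labels[1], "_specific"),
    j$status_B == "imprinted" & j$status_A == "not_imprinted" ~
      paste0(labels[2], "_specific"),
    j$status_A == "underpowered" | j$status_B == "underpowered" ~
      "underpowered",
    .default = "neither"
  )
  tibble::tibble(id = j$id, class = cls)
}

#' Extrapolate the total number of imprinted genes
#'
#' Generic estimator: (confirmed + confirmation_rate * untested) /
#' sensitivity. Treats the validated candidates plus the expected yield of
#' the untested ones as a sensitivity-limited sample of the genome-wide
#' total. The estimator is provided generically; published applications of
#' this arithmetic are not always reconstructible from their printed
#' operands.
#'
#' @param confirmed Validated novel genes.
#' @param untested Candidates not yet tested.
#' @param confirmation_rate Expected fraction of untested candidates that
#'   would validate (in \[0, 1\]).
#' @param sensitivity Detection sensitivity of the screen (in (0, 1\]).
#' @return Point estimate (numeric scalar).
#' @export
extrapolate_total <- function(confirmed, untested, confirmation_rate,
                              sensitivity) {
  stopifnot(confirmation_rate >= 0, confirmation_rate <= 1)
  if (sensitivity <= 0 || sensitivity > 1) {
    stop("sensitivity must lie in (0, 1]")
  }
  (confirmed + confirmation_rate * untested) / sensitivity
}
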