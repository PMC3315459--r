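# Mock-cross negative controls and empirical false-discovery estimation.
#
# A mock comparison treats two samples of the SAME cross as if they were
# reciprocal. Any "imprinting" signal there cannot be parent-of-origin and
# measures the technical + biological variance of the assay; the ratio of
# significant units in mock vs genuinely reciprocal comparisons is the
# empirical FDR.

#' Build a comparison scheme
#'
#' @param pairs Tibble with columns `sample1`, `sample2`, `label`
#'   (`"reciprocal"` or `"mock"`).
#' @param samples Sample metadata, used to check that mock pairs share a
#'   cross direction and reciprocal pairs differ.
#' @return Validated `comparison_scheme` tibble.
#' @export
comparison_scheme <- function(pairs, samples) {
  stopifnot(all(c("sample1", "sample2", "label") %in% names(pairs)))
  stopifnot(all(pairs$label %in% c("reciprocal", "mock")))
  cr <- stats::setNames(samples$cross, samples$sample_id)
  c1 <- cr[pairs$sample1]
  c2 <- cr[pairs$sample2]
  if (any(is.na(c1)) || any(is.na(c2))) stop("scheme names unknown samples")
  bad_mock <- pairs$label == "mock" & c1 != c2
  bad_rec <- pairs$label == "reciprocal" & c1 == c2
  if (any(bad_mock)) stop("mock pairs must share a cross direction")
  if (any(bad_rec)) stop("reciprocal pairs must have opposite crosses")
  structure(tibble::as_tibble(pairs), class = c("comparison_scheme",
                                                class(tibble::tibble())))
}

#' Default comparison scheme for a 2x2 (cross x sex) design
#'
#' Reciprocal pairs are same-sex across crosses when both sexes are present
#' in both crosses, otherwise any cross-direction pairing; mock pairs are
#' within-cross (same sex preferred, else mixed).
#'
#' @param samples Sample metadata tibble.
#' @return A [comparison_scheme()].
#' @export
default_scheme <- function(samples) {
  pair_up <- function(a, b, label) {
    n <- min(nrow(a), nrow(b))
    if (!n) return(NULL)
    tibble::tibble(sample1 = a$sample_id[seq_len(n)],
                   sample2 = b$sample_id[seq_len(n)], label = label)
  }
  bxc <- samples[samples$cross == "BxC", ]
  cxb <- samples[samples$cross == "CxB", ]
  rec <- dplyr::bind_rows(lapply(unique(samples$sex), function(s) {
    pair_up(bxc[bxc$sex == s, ], cxb[cxb$sex == s, ], "reciprocal")
  }))
  if (is.null(rec) || !nrow(rec)) rec <- pair_up(bxc, cxb, "reciprocal")
  mock <- dplyr::bind_rows(
    if (nrow(bxc) >= 2)
      tibble::tibble(sample1 = bxc$sample_id[1], sample2 = bxc$sample_id[2],
                     label = "mock"),
    if (nrow(cxb) >= 2)
      tibble::tibble(sample1 = cxb$sample_id[1], sample2 = cxb$sample_id[2],
                     label = "mock")
  )
  comparison_scheme(dplyr::bind_rows(rec, mock), samples)
}

# multivariate hypergeometric draw: sample `size` reads without replacement
# from a vector of per-cell counts (sequential conditional rhyper)
rmvhyper <- function(counts, size) {
  counts <- as.integer(counts)
  total <- sum(counts)
  stopifnot(size <= total)
  out <- integer(length(counts))
  remaining <- total
  left <- size
  for (i in seq_along(counts)) {
    if (left == 0L) break
    out[i] <- stats::rhyper(1, counts[i], remaining - counts[i], left)
    left <- left - out[i]
    remaining <- remaining - counts[i]
  }
  out
}

#' Normalize samples to equal allelic read depth
#'
#' Drops SNPs on excluded chromosomes (chrX and chrM by default, where
#' allelic sampling is confounded), then randomly thins every sample's
#' allelic counts, without replacement, down to the total of the
#' smallest-total sample — the count-level equivalent of removing aligned
#' reads at random.
#'
#' @param counts Allelic count tibble.
#' @param snps SNP tibble carrying `chrom` (used for the exclusion only).
#' @param exclude_chroms Chromosomes to drop (default `c("chrX", "chrM")`).
#' @return Count tibble with equal per-sample totals. Uses the R RNG;
#'   seed with [set.seed()] for reproducibility.
#' @export
normalize_depth <- function(counts, snps,
                            exclude_chroms = c("chrX", "chrM")) {
  drop <- snps$snp_id[snps$chrom %in% exclude_chroms]
  counts <- counts[!counts$snp_id %in% drop, ]
  totals <- counts |>
    dplyr::summarise(total = sum(.data$count_B + .data$count_C),
                     .by = "sample_id")
  if (!nrow(totals) || any(totals$total == 0)) {
    stop("a sample has no reads left after chromosome exclusion")
  }
  target <- min(totals$total)
  thinned <- lapply(split(counts, counts$sample_id), function(d) {
    tot <- sum(d$count_B + d$count_C)
    if (tot == target) return(d)
    v <- rmvhyper(c(d$count_B, d$count_C), target)
    d$count_B <- v[seq_len(nrow(d))]
    d$count_C <- v[nrow(d) + seq_len(nrow(d))]
    d
  })
  dplyr::bind_rows(thinned)
}

#' Thin every sample's counts to a fraction of its depth
#'
#' @param counts Allelic count tibble.
#' @param fraction Fraction of each sample's reads to retain, in (0, 1].
#' @return Thinned count tibble (hypergeometric, without replacement).
#' @export
thin_counts <- function(counts, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(counts)
  thinned <- lapply(split(counts, counts$sample_id), function(d) {
    tot <- sum(d$count_B + d$count_C)
    v <- rmvhyper(c(d$count_B, d$count_C), round(fraction * tot))
    d$count_B <- v[seq_len(nrow(d))]
    d$count_C <- v[nrow(d) + seq_len(nrow(d))]
    d
  })
  dplyr::bind_rows(thinned)
}

#' Run one labelled two-sample comparison
#'
#' Treats `sample1` as cross 1 and `sample2` as cross 2 — for mock pairs the
#' second sample is assigned the pretend opposite cross label so the
#' reciprocity rule runs on the pretend design.
#'
#' @param gene_counts Aggregated per-gene counts (or per-SNP counts with
#'   `unit_col = "snp_id"`).
#' @param samples Sample metadata.
#' @param sample1,sample2 The pair.
#' @param label `"reciprocal"` or `"mock"`.
#' @param criteria [call_criteria()].
#' @param unit_col Unit id column name.
#' @return List: `calls` (call tibble), `n_significant`, `significant_ids`.
#' @export
run_comparison <- function(gene_counts, samples, sample1, sample2,
                           label = "reciprocal",
                           criteria = call_criteria(alpha = 1e-4),
                           unit_col = "gene_id") {
  cr <- stats::setNames(samples$cross, samples$sample_id)
  ti <- stats::setNames(samples$tissue, samples$sample_id)
  if (!is.na(ti[sample1]) && !is.na(ti[sample2]) &&
      ti[sample1] != ti[sample2]) {
    warning("comparing samples from different tissues: ",
            sample1, " vs ", sample2)
  }
  cross1 <- cr[[sample1]]
  cross2 <- if (label == "mock") setdiff(c("BxC", "CxB"), cross1)[1]
            else cr[[sample2]]
  units <- pair_counts(gene_counts, sample1, sample2, unit_col)
  calls <- call_units(units, cross1, cross2, criteria)
  sig <- calls$id[calls$status == "imprinted"]
  list(calls = calls, n_significant = length(sig), significant_ids = sig)
}

# per-pair unit table with everything needed to re-threshold cheaply
comparison_table <- function(gene_counts, samples, scheme,
                             min_reads = 10L, unit_col = "gene_id") {
  cr <- stats::setNames(samples$cross, samples$sample_id)
  dplyr::bind_rows(lapply(seq_len(nrow(scheme)), function(i) {
    s1 <- scheme$sample1[i]; s2 <- scheme$sample2[i]
    cross1 <- cr[[s1]]
    cross2 <- if (scheme$label[i] == "mock")
      setdiff(c("BxC", "CxB"), cross1)[1] else cr[[s2]]
    units <- pair_counts(gene_counts, s1, s2, unit_col)
    # alpha value irrelevant here: we keep p-values and re-threshold
    calls <- call_units(units, cross1, cross2,
                        call_criteria(min_reads = min_reads, alpha = 0.5))
    calls$pair <- paste(s1, s2, sep = "|")
    calls$label <- scheme$label[i]
    calls
  }))
}

# significant under the reciprocal rule at threshold t: powered, reciprocal
# (score is non-NA exactly then) and both p-values below t
sig_at <- function(tab, t) {
  !is.na(tab$score) & tab$p_1 < t & tab$p_2 < t &
    tab$status != "underpowered"
}

#' Empirical FDR as a function of p-value threshold
#'
#' For each threshold, counts units significant under the full reciprocal
#' rule in the mock arm and in the reciprocal arm of the scheme (pooled by
#' summing counts over pairs, or by set union with `pooling = "union"`),
#' and reports their ratio. Mock and reciprocal arms must be computed from
#' the same normalized counts — this function takes a single count table,
#' which enforces that.
#'
#' @param gene_counts Aggregated (and depth-normalized) per-unit counts.
#' @param samples Sample metadata.
#' @param scheme A [comparison_scheme()] with >= 1 mock and >= 1 reciprocal
#'   pair.
#' @param thresholds Decreasing or arbitrary vector of p-value thresholds.
#' @param min_reads Powering rule per sample.
#' @param pooling `"sum"` (default) or `"union"`.
#' @param unit_col Unit id column.
#' @return Tibble: `threshold`, `n_mock`, `n_reciprocal`, `fdr` (NA when
#'   the reciprocal arm has no significant units).
#' @export
fdr_curve <- function(gene_counts, samples, scheme, thresholds,
                      min_reads = 10L, pooling = c("sum", "union"),
                      unit_col = "gene_id") {
  pooling <- match.arg(pooling)
  stopifnot(any(scheme$label == "mock"), any(scheme$label == "reciprocal"))
  tab <- comparison_table(gene_counts, samples, scheme, min_reads, unit_col)
  dplyr::bind_rows(lapply(thresholds, function(t) {
    s <- sig_at(tab, t)
    count_arm <- function(lab) {
      if (pooling == "sum") sum(s & tab$label == lab)
      else length(unique(tab$id[s & tab$label == lab]))
    }
    n_mock <- count_arm("mock")
    n_rec <- count_arm("reciprocal")
    tibble::tibble(threshold = t, n_mock = n_mock, n_reciprocal = n_rec,
                   fdr = if (n_rec > 0) n_mock / n_rec else NA_real_)
  }))
}

#' Sensitivity for known imprinted genes vs p-value threshold
#'
#' Sensitivity at a threshold = known imprinted genes called significant in
#' the reciprocal comparison / known genes powered for detection (depth >=
#' `min_reads` in both samples of the comparison).
#'
#' @param gene_counts Aggregated per-gene counts.
#' @param samples Sample metadata.
#' @param scheme Scheme; only its reciprocal pairs are used.
#' @param catalog Known-imprinted catalog tibble (`gene_id` column).
#' @param thresholds P-value thresholds.
#' @param min_reads Powering rule.
#' @return Tibble: `threshold`, `n_detected`, `n_powered`, `sensitivity`
#'   (NA when no known gene is powered). Detection and powering are pooled
#'   over reciprocal pairs by set union (a gene counts once).
#' @export
sensitivity_curve <- function(gene_counts, samples, scheme, catalog,
                              thresholds, min_reads = 10L) {
  rec <- scheme[scheme$label == "reciprocal", ]
  stopifnot(nrow(rec) >= 1)
  tab <- comparison_table(gene_counts, samples, rec, min_reads)
  known <- tab[tab$id %in% catalog$gene_id, ]
  powered_ids <- unique(known$id[known$status != "underpowered"])
  dplyr::bind_rows(lapply(thresholds, function(t) {
    det <- unique(known$id[sig_at(known, t)])
    tibble::tibble(threshold = t, n_detected = length(det),
                   n_powered = length(powered_ids),
                   sensitivity = if (length(powered_ids))
                     length(det) / length(powered_ids) else NA_real_)
  }))
}

#' Downsampling sensitivity curve
#'
#' For each read fraction and iteration, thins every sample's counts
#' without replacement, re-runs the reciprocal caller and counts significant
#' units; reports mean and standard error over iterations. At fraction 1
#' thinning is a no-op, so the count equals the full-data count with SE 0.
#'
#' @param gene_counts Aggregated per-unit counts.
#' @param samples Sample metadata.
#' @param scheme Scheme; reciprocal pairs are evaluated (pass a mock-only
#'   scheme to downsample the negative control instead).
#' @param fractions Ascending vector of read fractions in (0, 1].
#' @param iterations Sampling iterations per fraction (default 100).
#' @param criteria [call_criteria()].
#' @param unit_col Unit id column. Seed via [set.seed()].
#' @return Tibble: `fraction`, `mean_significant`, `se`, `iterations`.
#' @export
downsample_curve <- function(gene_counts, samples, scheme, fractions,
                             iterations = 100L,
                             criteria = call_criteria(alpha = 1e-4),
                             unit_col = "gene_id") {
  stopifnot(!is.unsorted(fractions), all(fractions > 0), all(fractions <= 1))
  rec <- scheme[scheme$label == "reciprocal", ]
  if (!nrow(rec)) rec <- scheme
  count_sig <- function(cnt) {
    tab <- comparison_table(cnt, samples, rec, criteria$min_reads, unit_col)
    sum(sig_at(tab, criteria$alpha))
  }
  dplyr::bind_rows(lapply(fractions, function(f) {
    iters <- if (f == 1) 1L else iterations
    ns <- vapply(seq_len(iters), function(i) {
      count_sig(thin_counts(gene_counts, f))
    }, numeric(1))
    tibble::tibble(fraction = f, mean_significant = mean(ns),
                   se = if (iters > 1) stats::sd(ns) / sqrt(iters) else 0,
                   iterations = iters)
  }))
}

#' False-positive proportion among novel genes vs read depth
#'
#' At each read fraction, thins the counts, restricts calls to units absent
#' from the known-imprinted catalog ("novel"), and computes the mock /
#' reciprocal significant-count ratio at the calling threshold; mean and SE
#' over iterations.
#'
#' @inheritParams downsample_curve
#' @param catalog Known-imprinted catalog (`gene_id`).
#' @return Tibble: `fraction`, `mean_fdr`, `se`, `mean_n_mock`,
#'   `mean_n_reciprocal`. `mean_fdr` is NA at fractions where no iteration
#'   produced a significant novel reciprocal call.
#' @export
fp_proportion_curve <- function(gene_counts, samples, scheme, catalog,
                                fractions, iterations = 100L,
                                criteria = call_criteria(alpha = 1e-4),
                                unit_col = "gene_id") {
  stopifnot(any(scheme$label == "mock"), any(scheme$label == "reciprocal"))
  one <- function(cnt) {
    tab <- comparison_table(cnt, samples, scheme, criteria$min_reads,
                            unit_col)
    tab <- tab[!tab$id %in% catalog$gene_id, ]
    s <- sig_at(tab, criteria$alpha)
    c(mock = sum(s & tab$label == "mock"),
      rec = sum(s & tab$label == "reciprocal"))
  }
  dplyr::bind_rows(lapply(fractions, function(f) {
    iters <- if (f == 1) 1L else iterations
    m <- t(vapply(seq_len(iters), function(i) {
      one(thin_counts(gene_counts, f))
    }, numeric(2)))
    fdrs <- ifelse(m[, "rec"] > 0, m[, "mock"] / m[, "rec"], NA_real_)
    tibble::tibble(
      fraction = f,
      mean_fdr = if (all(is.na(fdrs))) NA_real_ else mean(fdrs, na.rm = TRUE),
      se = if (iters > 1 && sum(!is.na(fdrs)) > 1)
        stats::sd(fdrs, na.rm = TRUE) / sqrt(sum(!is.na(fdrs))) else 0,
      mean_n_mock = mean(m[, "mock"]),
      mean_n_reciprocal = mean(m[, "rec"])
    )
  }))
}
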