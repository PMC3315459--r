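# Within-exon SNP-pair concordance diagnostic.
#
# True allele-specific expression is a property of the transcript, so two
# SNPs inside one coding exon must agree on the direction of allelic bias.
# The rate at which they disagree, as a function of how significant both
# SNPs are, measures systematic error; its expectation under pure random
# sampling (binomial counting noise only) is reconstructed by replacing one
# SNP of each pair with partner-derived expected counts perturbed through
# the Pearson chi-square quadratic.

#' Resolve overlapping coding exons to the longest
#'
#' Where more than one coding exon overlaps in the genome, only the longest
#' is kept (ties break to the lower start coordinate), so that no SNP can be
#' sampled through two retained exons. Non-coding exons are excluded.
#'
#' @param models Exon-level tibble (`exon_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `coding`).
#' @return Exon tibble restricted to non-redundant coding exons.
#' @export
select_nonredundant_exons <- function(models) {
  ex <- models[models$coding, , drop = FALSE]
  if (!nrow(ex)) return(ex)
  gr <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end))
  cl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr),
                                    ignore.strand = TRUE)
  ex$cluster <- S4Vectors::subjectHits(cl)[order(S4Vectors::queryHits(cl))]
  ex |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$end - .data$start), .data$start,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Enumerate testable SNP pairs within exons
#'
#' All unordered pairs of SNPs inside each retained exon, excluding pairs
#' separated by `min_separation` bp or less (strictly greater than the
#' longest read length is required so the two SNPs are sampled by disjoint
#' reads). Pairs where either SNP has an exactly tied count (direction
#' "none") are dropped from concordance and tallied in the
#' `dropped_direction_none` attribute.
#'
#' @param exons Non-redundant exon tibble ([select_nonredundant_exons()]).
#' @param snps Assigned SNP tibble (`snp_id`, `pos`, `exon_id`).
#' @param counts One sample's allelic counts (`snp_id`, `count_B`,
#'   `count_C`).
#' @param min_separation Minimum bp separation, strict `>` (default 40).
#' @return Pair tibble: exon/snp ids, positions, `separation`, both count
#'   pairs, `p1`, `p2`, `dir1`, `dir2`, `p_pair` (= max(p1, p2), the less
#'   significant), `concordant`.
#' @export
enumerate_snp_pairs <- function(exons, snps, counts, min_separation = 40L) {
  sn <- snps[!is.na(snps$exon_id) & snps$exon_id %in% exons$exon_id, ]
  sn <- dplyr::inner_join(sn, counts[c("snp_id", "count_B", "count_C")],
                          by = "snp_id")
  sn <- sn[sn$count_B + sn$count_C > 0, ]
  tst <- ase_chisq(sn$count_B, sn$count_C)
  sn$p <- tst$p
  sn$direction <- tst$direction
  dropped <- 0L
  pairs <- lapply(split(sn, sn$exon_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$pos), ]
    idx <- utils::combn(nrow(d), 2)
    i <- idx[1, ]; j <- idx[2, ]
    sep <- abs(d$pos[j] - d$pos[i])
    keep <- sep > min_separation
    i <- i[keep]; j <- j[keep]; sep <- sep[keep]
    if (!length(i)) return(NULL)
    tibble::tibble(
      exon_id = d$exon_id[1],
      snp1 = d$snp_id[i], snp2 = d$snp_id[j],
      pos1 = d$pos[i], pos2 = d$pos[j], separation = sep,
      count_B1 = d$count_B[i], count_C1 = d$count_C[i],
      count_B2 = d$count_B[j], count_C2 = d$count_C[j],
      p1 = d$p[i], p2 = d$p[j],
      dir1 = d$direction[i], dir2 = d$direction[j]
    )
  })
  out <- dplyr::bind_rows(pairs)
  if (!nrow(out)) {
    out <- tibble::tibble(exon_id = character(), snp1 = character(),
                          snp2 = character(), pos1 = integer(),
                          pos2 = integer(), separation = integer(),
                          count_B1 = integer(), count_C1 = integer(),
                          count_B2 = integer(), count_C2 = integer(),
                          p1 = numeric(), p2 = numeric(),
                          dir1 = character(), dir2 = character())
  }
  has_dir <- out$dir1 != "none" & out$dir2 != "none"
  dropped <- sum(!has_dir)
  out <- out[has_dir, , drop = FALSE]
  out$p_pair <- pmax(out$p1, out$p2)
  out$concordant <- out$dir1 == out$dir2
  attr(out, "dropped_direction_none") <- dropped
  out
}

#' Discordance as a function of significance threshold
#'
#' At each threshold t the pairs where the less significant p-value is
#' below t are retained and the discordant fraction reported.
#'
#' @param pairs Pair tibble from [enumerate_snp_pairs()] (or the simulated
#'   equivalent).
#' @param thresholds P-value thresholds.
#' @return Tibble: `threshold`, `n_pairs`, `n_discordant`, `fraction`
#'   (NA when no pair passes).
#' @export
discordance_curve <- function(pairs, thresholds) {
  dplyr::bind_rows(lapply(thresholds, function(t) {
    sel <- pairs$p_pair < t
    n <- sum(sel)
    nd <- sum(sel & !pairs$concordant)
    tibble::tibble(threshold = t, n_pairs = n, n_discordant = nd,
                   fraction = if (n > 0) nd / n else NA_real_)
  }))
}

#' Expected counts for one SNP from its partner's allelic ratio
#'
#' The partner's allelic ratio scaled to the replaced SNP's own total
#' depth: partner (30, 20) at total 100 gives (60, 40).
#'
#' @param partner_B,partner_C Partner SNP's allelic counts.
#' @param total Depth of the SNP being replaced.
#' @return Numeric matrix with columns `e_B`, `e_C` (reals, not rounded).
#' @export
expected_counts_from_partner <- function(partner_B, partner_C, total) {
  n <- partner_B + partner_C
  stopifnot(all(n >= 1), all(total >= 1))
  ratio <- partner_B / n
  cbind(e_B = ratio * total, e_C = (1 - ratio) * total)
}

#' Solve Pearson's chi-square formula for simulated counts
#'
#' Given expected counts (e_B, e_C) with fixed total n = e_B + e_C and a
#' chi-square deviate, solves
#' \deqn{(x - e_B)^2 (1/e_B + 1/e_C) = \chi^2}
#' for the simulated B count x. Both roots are returned; callers round to
#' integers and clamp to \[0, n\]. With expected (60, 40) and chi2 = 1 the
#' roots are 64.9 and 55.1 — simulated counts of 65 or 55 (and 35 or 45).
#'
#' @param e_B,e_C Positive expected counts (vectors).
#' @param chi2_draw Non-negative chi-square deviates.
#' @return Matrix with columns `root_hi`, `root_lo` (the B-count roots).
#' @export
solve_pearson_counts <- function(e_B, e_C, chi2_draw) {
  stopifnot(all(e_B > 0), all(e_C > 0), all(chi2_draw >= 0))
  delta <- sqrt(chi2_draw / (1 / e_B + 1 / e_C))
  cbind(root_hi = e_B + delta, root_lo = e_B - delta)
}

#' Random-sampling null for the discordance curve
#'
#' Reconstructs the discordance expected if allelic counts were pure
#' binomial sampling around a shared exon-level ratio. Per pair and
#' iteration: the MORE significant SNP's counts are replaced by the
#' partner's ratio scaled to the replaced SNP's own depth, perturbed by a
#' chi-square(1) draw through the Pearson quadratic (one of the two roots
#' chosen uniformly at random), rounded and clamped; its test is recomputed
#' and the curve rebuilt. Replacing the more significant member keeps the
#' pair's thresholding p-value (the less significant one) comparable with
#' the observed data; `replace = "less_significant"` is the alternate mode,
#' which yields still lower expected discordance.
#'
#' @param pairs Observed pair tibble ([enumerate_snp_pairs()]).
#' @param thresholds P-value thresholds for the curve.
#' @param iterations Simulation iterations (default 100).
#' @param replace Which member to regenerate.
#' @param round_counts Round simulated counts to integers (default TRUE;
#'   FALSE keeps exact reals).
#' @return List: `curve` (tibble: `threshold`, `mean_fraction`, `sd_fraction`,
#'   `mean_n_pairs`), `dropped_direction_none` (mean per-iteration tally of
#'   regenerated SNPs landing on an exact tie). Seed via [set.seed()].
#' @export
simulate_null_discordance <- function(pairs, thresholds, iterations = 100L,
                                      replace = c("more_significant",
                                                  "less_significant"),
                                      round_counts = TRUE) {
  replace <- match.arg(replace)
  np <- nrow(pairs)
  if (!np) stop("no pairs to simulate")
  # which member gets replaced (ties -> first)
  more_sig <- pairs$p1 <= pairs$p2
  repl_first <- if (replace == "more_significant") more_sig else !more_sig
  rb <- ifelse(repl_first, pairs$count_B1, pairs$count_B2)
  rc <- ifelse(repl_first, pairs$count_C1, pairs$count_C2)
  pb <- ifelse(repl_first, pairs$count_B2, pairs$count_B1)
  pc <- ifelse(repl_first, pairs$count_C2, pairs$count_C1)
  keep_p <- ifelse(repl_first, pairs$p2, pairs$p1)
  keep_dir <- ifelse(repl_first, pairs$dir2, pairs$dir1)
  total <- rb + rc
  e <- expected_counts_from_partner(pb, pc, total)
  # degenerate expectation (partner monoallelic): nudge inside (0, n)
  eB <- pmin(pmax(e[, "e_B"], 0.5), total - 0.5)
  eC <- total - eB
  dropped <- numeric(iterations)
  fracs <- matrix(NA_real_, iterations, length(thresholds))
  npairs <- matrix(0L, iterations, length(thresholds))
  for (it in seq_len(iterations)) {
    chi2 <- stats::rchisq(np, df = 1)
    roots <- solve_pearson_counts(eB, eC, chi2)
    pick_hi <- stats::runif(np) < 0.5
    x <- ifelse(pick_hi, roots[, "root_hi"], roots[, "root_lo"])
    if (round_counts) x <- round(x)
    x <- pmin(pmax(x, 0), total)
    sim_t <- ase_chisq(x, total - x)
    ok <- sim_t$direction != "none" & keep_dir != "none"
    dropped[it] <- sum(!ok)
    p_pair <- pmax(sim_t$p, keep_p)
    conc <- sim_t$direction == keep_dir
    for (k in seq_along(thresholds)) {
      sel <- ok & p_pair < thresholds[k]
      npairs[it, k] <- sum(sel)
      fracs[it, k] <- if (any(sel)) sum(sel & !conc) / sum(sel) else NA_real_
    }
  }
  curve <- tibble::tibble(
    threshold = thresholds,
    mean_fraction = colMeans(fracs, na.rm = TRUE),
    sd_fraction = apply(fracs, 2, stats::sd, na.rm = TRUE),
    mean_n_pairs = colMeans(npairs)
  )
  list(curve = curve, dropped_direction_none = mean(dropped))
}
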