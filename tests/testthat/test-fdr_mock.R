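test_that("depth normalization drops excluded chromosomes and equalizes totals", {
  set.seed(2)
  snps <- tibble::tibble(chrom = c("chr1", "chr1", "chrX", "chrM"),
                         pos = c(10L, 60L, 5L, 5L),
                         snp_id = c("a", "b", "x", "m"),
                         allele_B = "A", allele_C = "G")
  counts <- tidyr::expand_grid(snp_id = snps$snp_id,
                               sample_id = c("s1", "s2", "s3"))
  counts$count_B <- c(30L, 40L, 10L, 5L, 20L, 30L, 8L, 2L, 40L, 50L, 9L, 1L)
  counts$count_C <- c(20L, 10L, 10L, 5L, 30L, 40L, 2L, 8L, 10L, 20L, 1L, 9L)
  out <- normalize_depth(counts, snps)
  expect_false(any(out$snp_id %in% c("x", "m")))
  totals <- tapply(out$count_B + out$count_C, out$sample_id, sum)
  expect_true(all(totals == min(tapply(
    counts$count_B[counts$snp_id %in% c("a", "b")] +
      counts$count_C[counts$snp_id %in% c("a", "b")],
    counts$sample_id[counts$snp_id %in% c("a", "b")], sum))))
})

test_that("hypergeometric thinning preserves totals exactly and means proportionally", {
  set.seed(8)
  counts <- tibble::tibble(snp_id = sprintf("s%02d", 1:20),
                           sample_id = "s1",
                           count_B = rpois(20, 50), count_C = rpois(20, 50))
  total <- sum(counts$count_B + counts$count_C)
  target_frac <- 0.4
  draws <- replicate(300, {
    th <- thin_counts(counts, target_frac)
    stopifnot(sum(th$count_B + th$count_C) == round(target_frac * total))
    th$count_B[1]
  })
  # per-cell mean matches the hypergeometric expectation n*K/N
  expect_equal(mean(draws),
               round(target_frac * total) * counts$count_B[1] / total,
               tolerance = 0.05)
  # fraction 1 is a no-op
  expect_identical(thin_counts(counts, 1), counts)
})

test_that("a sample compared against itself yields no significant units", {
  d <- simulate_reciprocal_dataset(synthetic_config(n_genes = 40, seed = 5))
  gc <- aggregate_gene_counts(d$counts, d$snps)
  dup <- gc[gc$sample_id == "BxC_M1", ]
  dup2 <- dup
  dup2$sample_id <- "copy"
  both <- dplyr::bind_rows(dup, dup2)
  samples <- tibble::tibble(sample_id = c("BxC_M1", "copy"),
                            cross = "BxC", sex = "M", tissue = "brain",
                            replicate = 1:2)
  res <- run_comparison(both, samples, "BxC_M1", "copy", label = "mock")
  expect_equal(res$n_significant, 0)
})

test_that("mock comparisons see overdispersed replicates but not binomial ones", {
  base <- synthetic_config(n_genes = 150, frac_imprinted = 0,
                           strain_effect_sd = 0, snp_bias_sd = 0,
                           bio_sd = 0, rho = 0,
                           depth = list(meanlog = log(150), sdlog = 0.5),
                           seed = 17)
  d0 <- simulate_reciprocal_dataset(base)
  over <- base
  over$bio_sd <- 0.4
  over$rho <- 0.02
  d1 <- simulate_reciprocal_dataset(over)   # paired seed, same layout
  n_sig <- function(d) {
    gc <- aggregate_gene_counts(d$counts, d$snps)
    run_comparison(gc, d$samples, "BxC_M1", "BxC_F1", label = "mock",
                   criteria = call_criteria(alpha = 1e-3))$n_significant
  }
  expect_lte(n_sig(d0), 1)
  expect_gt(n_sig(d1), n_sig(d0) + 3)
})

test_that("fdr curve is the mock/reciprocal ratio with sum pooling", {
  # constructed table: genes 1-5 reciprocally imprinted in (b1, c1);
  # gene 10 flips direction between the two BxC replicates, so the mock
  # pair (b1, b2) sees exactly one pretend-reciprocal hit
  mk <- function(sid, b) tibble::tibble(gene_id = paste0("g", 1:10),
                                        sample_id = sid,
                                        count_B = b, count_C = 100L - b)
  gc <- dplyr::bind_rows(
    mk("b1", c(rep(95L, 5), rep(50L, 4), 5L)),
    mk("c1", c(rep(5L, 5), rep(50L, 5))),
    mk("b2", c(rep(95L, 5), rep(50L, 4), 95L)))
  samples <- tibble::tibble(sample_id = c("b1", "b2", "c1"),
                            cross = c("BxC", "BxC", "CxB"),
                            sex = "M", tissue = "t", replicate = c(1:2, 1L))
  scheme <- comparison_scheme(
    tibble::tibble(sample1 = c("b1", "b1"), sample2 = c("c1", "b2"),
                   label = c("reciprocal", "mock")), samples)
  fc <- fdr_curve(gc, samples, scheme, thresholds = 1e-4)
  expect_equal(fc$n_reciprocal, 5L)
  expect_equal(fc$n_mock, 1L)
  expect_equal(fc$fdr, 0.2)
  # zero mock hits gives fdr 0
  fc2 <- fdr_curve(gc[gc$gene_id != "g10", ], samples, scheme,
                   thresholds = 1e-4)
  expect_equal(fc2$fdr, 0)
})

test_that("fdr is about 1 under an exchangeable imprinting-free null", {
  cfg <- synthetic_config(n_genes = 400, frac_imprinted = 0,
                          strain_effect_sd = 0.3, snp_bias_sd = 0.3,
                          bio_sd = 0.35, rho = 0.02,
                          depth = list(meanlog = log(120), sdlog = 0.6),
                          seed = 23)
  d <- simulate_reciprocal_dataset(cfg)
  gc <- aggregate_gene_counts(d$counts, d$snps)
  fc <- fdr_curve(gc, d$samples, default_scheme(d$samples),
                  thresholds = c(0.01, 1e-3))
  expect_true(all(fc$n_reciprocal > 10))
  # mock and reciprocal arms are exchangeable: ratio near 1
  for (i in seq_len(nrow(fc))) {
    n <- fc$n_mock[i] + fc$n_reciprocal[i]
    # binomial band for the mock share around 1/2
    band <- 3 * sqrt(0.25 / n)
    expect_lt(abs(fc$n_mock[i] / n - 0.5), band + 0.05)
  }
})

test_that("sensitivity curve counts detected over powered known genes", {
  mk <- function(sid, b, c) tibble::tibble(gene_id = paste0("g", 1:6),
                                           sample_id = sid,
                                           count_B = b, count_C = c)
  gc <- dplyr::bind_rows(
    mk("b1", c(95L, 95L, 60L, 50L, 3L, 95L), c(5L, 5L, 40L, 50L, 3L, 5L)),
    mk("c1", c(5L, 5L, 40L, 50L, 3L, 5L), c(95L, 95L, 60L, 50L, 3L, 95L)))
  samples <- tibble::tibble(sample_id = c("b1", "c1", "b2"),
                            cross = c("BxC", "CxB", "BxC"), sex = "M",
                            tissue = "t", replicate = 1L)
  scheme <- tibble::tibble(sample1 = "b1", sample2 = "c1",
                           label = "reciprocal")
  catalog <- tibble::tibble(gene_id = c("g1", "g3", "g5"),
                            name = c("g1", "g3", "g5"), chrom = "chr1",
                            start = 0, end = 1, expressed_allele = "maternal")
  sc <- sensitivity_curve(gc, samples, scheme, catalog,
                          thresholds = c(1e-4, 0.05))
  # g5 underpowered (6 reads); powered known = g1, g3; g1 detected at
  # 1e-4 and g3 (60/40 reciprocal, p ~ 0.046) only at 0.05
  expect_equal(sc$n_powered, c(2L, 2L))
  expect_equal(sc$n_detected, c(1L, 2L))
  expect_equal(sc$sensitivity, c(0.5, 1))
  # catalog disjoint from the data: estimate absent
  none <- sensitivity_curve(gc, samples, scheme,
                            catalog = tibble::tibble(gene_id = "nope"),
                            thresholds = 0.05)
  expect_true(is.na(none$sensitivity))
})

test_that("downsampling is a no-op at fraction 1 and non-decreasing within SE", {
  cfg <- synthetic_config(n_genes = 120, frac_imprinted = 0.25,
                          beta_imprint = c(2.5, 0.3),
                          strain_effect_sd = 0.3, snp_bias_sd = 0,
                          bio_sd = 0, rho = 0,
                          depth = list(meanlog = log(40), sdlog = 0.8),
                          seed = 31)
  d <- simulate_reciprocal_dataset(cfg)
  gc <- aggregate_gene_counts(d$counts, d$snps)
  scheme <- default_scheme(d$samples)
  set.seed(100)
  dc <- downsample_curve(gc, d$samples, scheme,
                         fractions = c(0.2, 0.5, 1), iterations = 30)
  full <- dc$mean_significant[dc$fraction == 1]
  expect_equal(dc$se[dc$fraction == 1], 0)
  # fraction 1 equals the un-thinned recount exactly
  tab <- comparison_table(gc, d$samples,
                          scheme[scheme$label == "reciprocal", ])
  expect_equal(full, sum(sig_at(tab, 1e-4)))
  # power monotone in depth, within 3 SE
  expect_lte(dc$mean_significant[1], dc$mean_significant[2] + 3 * dc$se[2])
  expect_lte(dc$mean_significant[2], full + 3 * dc$se[2])
  expect_gt(full, dc$mean_significant[1])
})

test_that("novel-restricted false-positive proportion behaves under set restriction", {
  cfg <- synthetic_config(n_genes = 250, frac_imprinted = 0.15,
                          bio_sd = 0.3, rho = 0.02,
                          depth = list(meanlog = log(100), sdlog = 0.6),
                          seed = 37)
  d <- simulate_reciprocal_dataset(cfg)
  gc <- aggregate_gene_counts(d$counts, d$snps)
  scheme <- default_scheme(d$samples)
  # catalog = the true imprinted genes: all real signal is "known"
  catalog <- d$truth$genes[d$truth$genes$imprinted, c("gene_id")]
  set.seed(7)
  fp <- fp_proportion_curve(gc, d$samples, scheme, catalog,
                            fractions = c(0.5, 1), iterations = 10,
                            criteria = call_criteria(alpha = 0.01))
  ov <- fdr_curve(gc, d$samples, scheme, thresholds = 0.01)
  # restricting to novel units removes true positives from the
  # denominator only, so the novel FDR >= the overall FDR
  expect_gte(fp$mean_fdr[fp$fraction == 1] + 1e-9, ov$fdr)
})

test_that("mock pairs must share a cross and reciprocal pairs must not", {
  samples <- fixture_samples()
  expect_error(comparison_scheme(
    tibble::tibble(sample1 = "BxC_M1", sample2 = "CxB_M1", label = "mock"),
    samples), "share a cross")
  expect_error(comparison_scheme(
    tibble::tibble(sample1 = "BxC_M1", sample2 = "BxC_F1",
                   label = "reciprocal"), samples), "opposite")
})
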