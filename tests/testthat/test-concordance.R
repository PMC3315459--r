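test_that("overlapping coding exons resolve to the longest", {
  models <- tibble::tibble(
    exon_id = paste0("e", 1:4),
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "chr1",
    start = c(0L, 50L, 300L, 500L), end = c(100L, 120L, 400L, 600L),
    coding = c(TRUE, TRUE, TRUE, FALSE))
  out <- select_nonredundant_exons(models)
  # e1 (len 100) beats overlapping e2 (len 70); e3 disjoint kept;
  # e4 non-coding excluded
  expect_setequal(out$exon_id, c("e1", "e3"))
  # equal lengths: lower start coordinate wins
  tie <- tibble::tibble(exon_id = c("a", "b"), gene_id = c("g1", "g2"),
                        chrom = "chr1", start = c(0L, 50L),
                        end = c(100L, 150L), coding = TRUE)
  expect_identical(select_nonredundant_exons(tie)$exon_id, "a")
})

test_that("pair enumeration follows the strict 40 bp separation rule", {
  exons <- tibble::tibble(exon_id = "e1", gene_id = "g", chrom = "chr1",
                          start = 0L, end = 1000L, coding = TRUE)
  mk_snps <- function(pos) {
    tibble::tibble(chrom = "chr1", pos = pos,
                   snp_id = paste0("s", seq_along(pos)),
                   allele_B = "A", allele_C = "G", gene_id = "g",
                   exon_id = "e1")
  }
  counts <- function(snps) tibble::tibble(snp_id = snps$snp_id,
                                          sample_id = "x",
                                          count_B = 30L, count_C = 10L)
  # three SNPs pairwise > 40 bp apart -> three comparisons
  s3 <- mk_snps(c(0L, 100L, 200L))
  p3 <- enumerate_snp_pairs(exons, s3, counts(s3))
  expect_equal(nrow(p3), 3)
  # exactly 40 bp apart -> excluded (strict >)
  s2 <- mk_snps(c(0L, 40L))
  expect_equal(nrow(enumerate_snp_pairs(exons, s2, counts(s2))), 0)
  s2b <- mk_snps(c(0L, 41L))
  expect_equal(nrow(enumerate_snp_pairs(exons, s2b, counts(s2b))), 1)
})

test_that("pair enumeration matches a brute-force filter on random layouts", {
  set.seed(13)
  exons <- tibble::tibble(exon_id = "e1", gene_id = "g", chrom = "chr1",
                          start = 0L, end = 2000L, coding = TRUE)
  for (rep in 1:5) {
    pos <- sort(sample(0:2000, 8))
    snps <- tibble::tibble(chrom = "chr1", pos = pos,
                           snp_id = sprintf("s%02d", seq_along(pos)),
                           allele_B = "A", allele_C = "G", gene_id = "g",
                           exon_id = "e1")
    cnt <- tibble::tibble(snp_id = snps$snp_id, sample_id = "x",
                          count_B = rpois(8, 30) + 1L,
                          count_C = rpois(8, 20) + 1L)
    got <- enumerate_snp_pairs(exons, snps, cnt)
    idx <- utils::combn(length(pos), 2)
    sep <- abs(pos[idx[2, ]] - pos[idx[1, ]])
    t_all <- ase_chisq(cnt$count_B, cnt$count_C)
    both_dir <- t_all$direction[idx[1, ]] != "none" &
      t_all$direction[idx[2, ]] != "none"
    expect_equal(nrow(got), sum(sep > 40 & both_dir))
  }
})

test_that("ties in direction are dropped and tallied", {
  exons <- tibble::tibble(exon_id = "e1", gene_id = "g", chrom = "chr1",
                          start = 0L, end = 1000L, coding = TRUE)
  snps <- tibble::tibble(chrom = "chr1", pos = c(0L, 100L),
                         snp_id = c("s1", "s2"), allele_B = "A",
                         allele_C = "G", gene_id = "g", exon_id = "e1")
  cnt <- tibble::tibble(snp_id = c("s1", "s2"), sample_id = "x",
                        count_B = c(20L, 30L), count_C = c(20L, 10L))
  out <- enumerate_snp_pairs(exons, snps, cnt)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped_direction_none"), 1L)
})

test_that("discordance curve recounts pairs at each threshold", {
  pairs <- make_pairs(b1 = c(80L, 80L, 80L, 10L, 60L),
                      c1 = c(20L, 20L, 20L, 90L, 40L),
                      b2 = c(75L, 75L, 20L, 15L, 55L),
                      c2 = c(25L, 25L, 80L, 85L, 45L))
  # all pairs significant at 0.05 except the (60,40)/(55,45) one
  dc <- discordance_curve(pairs, thresholds = c(1, 1e-4))
  expect_equal(dc$n_pairs[dc$threshold == 1], 5L)
  expect_equal(dc$n_discordant[dc$threshold == 1], 1L)
  expect_equal(dc$fraction[dc$threshold == 1], 0.2)
  # brute-force recount at a stringent threshold
  sel <- pairs$p_pair < 1e-4
  expect_equal(dc$n_pairs[dc$threshold == 1e-4], sum(sel))
  expect_equal(dc$fraction[dc$threshold == 1e-4],
               sum(sel & !pairs$concordant) / sum(sel))
  # all concordant -> 0; empty -> NA
  conc <- make_pairs(c(80L, 70L), c(20L, 30L), c(75L, 65L), c(25L, 35L))
  expect_equal(discordance_curve(conc, 1)$fraction, 0)
  expect_true(is.na(discordance_curve(conc, 1e-20)$fraction))
})

test_that("partner-derived expected counts reproduce the worked example", {
  # partner 30/20 scaled to total 100 -> 60/40
  e <- expected_counts_from_partner(30, 20, 100)
  expect_equal(unname(e[1, ]), c(60, 40))
  expect_equal(unname(expected_counts_from_partner(25, 25, 80)[1, ]),
               c(40, 40))
  expect_equal(unname(expected_counts_from_partner(10, 30, 60)[1, ]),
               c(15, 45))
})

test_that("the Pearson quadratic yields the printed simulated counts", {
  # expected (60, 40), chi2 = 1: roots 64.9 / 55.1 -> 65 or 55 (and 35/45)
  r <- solve_pearson_counts(60, 40, 1)
  expect_equal(round(unname(r[1, "root_hi"])), 65)
  expect_equal(round(unname(r[1, "root_lo"])), 55)
  # chi2 = 0 returns the expectation itself
  r0 <- solve_pearson_counts(60, 40, 0)
  expect_equal(unname(r0[1, ]), c(60, 60))
  # symmetric expectation: (50, 50) with chi2 = 4 -> 60 or 40
  r4 <- solve_pearson_counts(50, 50, 4)
  expect_equal(unname(r4[1, ]), c(60, 40))
})

test_that("the random-sampling null matches observed discordance for binomial pairs", {
  set.seed(19)
  obs <- make_null_pairs(4000, ratio_range = c(0.5, 0.75))
  th <- c(0.5, 0.05, 1e-3)
  oc <- discordance_curve(obs, th)
  sim <- simulate_null_discordance(obs, th, iterations = 40)
  for (k in seq_along(th)) {
    band <- 3 * max(sim$curve$sd_fraction[k], 0.005)
    expect_lt(abs(oc$fraction[k] - sim$curve$mean_fraction[k]), band + 0.02)
  }
})

test_that("per-SNP systematic bias lifts observed discordance above the null", {
  cfg <- synthetic_config(n_genes = 250, frac_imprinted = 0,
                          strain_effect_sd = 0.3, snp_bias_sd = 0.8,
                          bio_sd = 0, rho = 0,
                          snps_per_gene = list(mean = 4, max = 8),
                          depth = list(meanlog = log(200), sdlog = 0.7),
                          seed = 29)
  d <- simulate_reciprocal_dataset(cfg)
  ex <- select_nonredundant_exons(d$genes)
  pr <- enumerate_snp_pairs(ex, d$snps,
                            d$counts[d$counts$sample_id == "BxC_M1", ])
  th <- c(0.05, 1e-3, 1e-4)
  oc <- discordance_curve(pr, th)
  set.seed(1)
  sim <- simulate_null_discordance(pr, th, iterations = 30)
  # observed discordance exceeds the reconstructed sampling null at every
  # threshold, and tightening the threshold does not increase it
  expect_true(all(oc$fraction > sim$curve$mean_fraction))
  expect_true(all(diff(oc$fraction) <= 0.05))
  expect_gt(oc$fraction[th == 1e-4], 0.02)
})

test_that("replacing the less significant SNP lowers expected discordance", {
  set.seed(41)
  obs <- make_null_pairs(3000, ratio_range = c(0.5, 0.6),
                         depth_meanlog = log(60), depth_sdlog = 0.5)
  sim_more <- simulate_null_discordance(obs, 1, iterations = 30)
  set.seed(41)
  sim_less <- simulate_null_discordance(obs, 1, iterations = 30,
                                        replace = "less_significant")
  expect_lt(sim_less$curve$mean_fraction, sim_more$curve$mean_fraction)
})

test_that("null simulation estimator is consistent across iteration counts", {
  set.seed(55)
  obs <- make_null_pairs(1500, ratio_range = c(0.5, 0.7))
  s1 <- simulate_null_discordance(obs, 0.05, iterations = 1)
  s100 <- simulate_null_discordance(obs, 0.05, iterations = 100)
  band <- 3 * max(s100$curve$sd_fraction, 0.002)
  expect_lt(abs(s1$curve$mean_fraction - s100$curve$mean_fraction), band)
})
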