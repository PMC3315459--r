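#!/usr/bin/env Rscript
# Empirical false-discovery estimation: depth-normalize the four samples
# (chrX/chrM excluded), run the mock (within-cross) and reciprocal
# comparisons over a p-value threshold grid, and compare the mock/
# reciprocal FDR estimate with the truth-table FDR. Then the downsampling
# sensitivity curve and the false-positive proportion among novel genes.

suppressPackageStartupMessages(library(recimprint))
set.seed(20260928)

samples <- read_sample_metadata("results/samples.tsv")
counts <- read_allelic_counts("results/counts.tsv", samples)
snps <- readr::read_tsv("results/snps.tsv", show_col_types = FALSE)
truth <- readr::read_tsv("results/truth_genes.tsv", show_col_types = FALSE)

norm <- normalize_depth(counts, snps)
gene_counts <- aggregate_gene_counts(norm, snps)
scheme <- default_scheme(samples)
readr::write_tsv(scheme, "results/comparison_scheme.tsv")

thresholds <- 10^seq(-2, -6, by = -1)
fdr <- fdr_curve(gene_counts, samples, scheme, thresholds)
readr::write_tsv(fdr, "results/fdr_curve.tsv")

# truth-table FDR for the first reciprocal pair, same thresholds
rec <- scheme[scheme$label == "reciprocal", ][1, ]
tab <- call_genes(gene_counts, rec$sample1, rec$sample2,
                  criteria = call_criteria(alpha = 0.5))
tru <- truth_eval(tab, truth, thresholds)
readr::write_tsv(tru, "results/truth_fdr.tsv")

# sensitivity against the "known" catalog = the true imprinted genes
spans <- readr::read_tsv("results/gene_models.tsv",
                         show_col_types = FALSE) |>
  dplyr::summarise(start = min(start), end = max(end),
                   .by = c("gene_id", "chrom"))
catalog <- truth[truth$imprinted, "gene_id"] |>
  dplyr::inner_join(spans, by = "gene_id") |>
  dplyr::mutate(name = gene_id, expressed_allele = "unknown")
sens <- sensitivity_curve(gene_counts, samples, scheme, catalog, thresholds)
readr::write_tsv(sens, "results/sensitivity_curve.tsv")

down <- downsample_curve(gene_counts, samples, scheme,
                         fractions = c(0.25, 0.5, 0.75, 1),
                         iterations = 100)
readr::write_tsv(down, "results/downsample_curve.tsv")

fp <- fp_proportion_curve(gene_counts, samples, scheme, catalog,
                          fractions = c(0.5, 0.75, 1), iterations = 50)
readr::write_tsv(fp, "results/fp_proportion_curve.tsv")

msg <- sprintf("p<%g: mock %d vs reciprocal %d -> FDR %.3f (truth %.3f)",
               fdr$threshold, fdr$n_mock, fdr$n_reciprocal, fdr$fdr,
               tru$fdr)
message(paste(msg, collapse = "\n"))
message(sprintf("downsampling: mean significant %s at fractions %s",
                paste(round(down$mean_significant, 1), collapse = "/"),
                paste(down$fraction, collapse = "/")))
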