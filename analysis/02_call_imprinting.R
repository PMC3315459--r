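#!/usr/bin/env Rscript
# Gene-level imprinting calls from the reciprocal comparison: aggregate
# allelic counts over each gene's SNPs, apply the reciprocal chi-square
# rule at p < 1e-4 with the >= 10 read powering requirement, and attach
# signed imprinting scores. Also makes SNP-level replication-mode calls
# (p < 0.05) for the supporting-SNP feature.

suppressPackageStartupMessages(library(recimprint))

samples <- read_sample_metadata("results/samples.tsv")
counts <- read_allelic_counts("results/counts.tsv", samples)
snps <- readr::read_tsv("results/snps.tsv", show_col_types = FALSE)
truth <- readr::read_tsv("results/truth_genes.tsv", show_col_types = FALSE)

gene_counts <- aggregate_gene_counts(counts, snps)
gene_calls <- call_genes(gene_counts, "BxC_M1", "CxB_M1")
readr::write_tsv(gene_calls, "results/gene_calls.tsv")

snp_units <- pair_counts(counts, "BxC_M1", "CxB_M1", "snp_id")
snp_calls <- call_units(snp_units, "BxC", "CxB",
                        call_criteria(alpha = 0.05))
snp_calls <- dplyr::left_join(
  snp_calls, snps[c("snp_id", "gene_id", "pos")], by = c(id = "snp_id"))
readr::write_tsv(snp_calls, "results/snp_calls.tsv")

# sex-specific assessment across the two within-sex comparisons
males <- call_genes(gene_counts, "BxC_M1", "CxB_M1")
females <- call_genes(gene_counts, "BxC_F1", "CxB_F1")
sex_calls <- call_sex_specific(males, females, labels = c("M", "F"))
readr::write_tsv(sex_calls, "results/sex_specific_calls.tsv")

imp <- gene_calls[gene_calls$status == "imprinted", ]
hit <- dplyr::inner_join(imp, truth, by = c(id = "gene_id"))
message(sprintf("called %d/%d powered genes imprinted at p<1e-4; %d are true (directions agree for %d/%d)",
                nrow(imp), sum(gene_calls$status != "underpowered"),
                sum(hit$imprinted),
                sum(hit$direction.x == hit$direction.y & hit$imprinted),
                sum(hit$imprinted)))
message(sprintf("sex-specific classes: %s",
                paste(names(table(sex_calls$class)),
                      table(sex_calls$class), collapse = ", ")))
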