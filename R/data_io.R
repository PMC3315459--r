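# Readers/writers for the package's external formats and the interval
# plumbing around them. Coordinates are 0-based half-open internally (BED
# native); VCF POS is converted by -1 on ingest.

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `cross` (`BxC`/`CxB`, maternal
#'   strain listed first), `sex` (`M`/`F`/`unknown`), `tissue`, `replicate`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(replicate = "i",
                                               .default = "c"))
  validate_sample_metadata(x)
}

validate_sample_metadata <- function(x) {
  need <- c("sample_id", "cross", "sex", "tissue", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in metadata")
  if (!all(x$cross %in% c("BxC", "CxB"))) {
    stop("cross must be 'BxC' or 'CxB'")
  }
  if (!all(x$sex %in% c("M", "F", "unknown"))) {
    stop("sex must be 'M', 'F' or 'unknown'")
  }
  if (any(x$replicate < 1)) stop("replicate must be >= 1")
  tibble::as_tibble(x)
}

#' Read an allelic count table
#'
#' @param path TSV with header `snp_id`, `sample_id`, `count_B`, `count_C`.
#' @param samples Sample metadata tibble; every `sample_id` in the counts
#'   must be present here.
#' @return A validated tibble of per-SNP per-sample allelic counts.
#' @export
read_allelic_counts <- function(path, samples) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  need <- c("snp_id", "sample_id", "count_B", "count_C")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("count table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("count_B", "count_C")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop(col, " must contain non-negative integers")
    }
    x[[col]] <- as.integer(v)
  }
  unknown <- setdiff(x$sample_id, samples$sample_id)
  if (length(unknown)) {
    stop("count table references unknown sample_id(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  dup <- duplicated(x[c("snp_id", "sample_id")])
  if (any(dup)) {
    first <- x[which(dup)[1], ]
    stop("duplicated (snp_id, sample_id) pair: (",
         first$snp_id, ", ", first$sample_id, ")")
  }
  tibble::as_tibble(x[need])
}

#' Write an allelic count table
#' @param counts Tibble as returned by [read_allelic_counts()].
#' @param path Output TSV path.
#' @export
write_allelic_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a SNP table (flat TSV form)
#'
#' Columns: `chrom`, `pos` (1-based; stored 0-based), `snp_id`, `allele_B`,
#' `allele_C`. The two strain alleles must differ and be A/C/G/T.
#' @param path TSV path.
#' @return Tibble with 0-based `pos` and empty `gene_id`/`exon_id` columns.
#' @export
read_snp_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(pos = "d", .default = "c"))
  validate_snps(x)
}

validate_snps <- function(x, pos_is_one_based = TRUE) {
  need <- c("chrom", "pos", "snp_id", "allele_B", "allele_C")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("SNP table missing column(s): ",
                         paste(miss, collapse = ", "))
  nt <- c("A", "C", "G", "T")
  if (!all(x$allele_B %in% nt) || !all(x$allele_C %in% nt)) {
    stop("strain alleles must be A, C, G or T")
  }
  if (any(x$allele_B == x$allele_C)) {
    stop("allele_B and allele_C must differ at every SNP")
  }
  x <- tibble::as_tibble(x)
  if (pos_is_one_based) x$pos <- as.integer(x$pos) - 1L
  if (!"gene_id" %in% names(x)) x$gene_id <- NA_character_
  if (!"exon_id" %in% names(x)) x$exon_id <- NA_character_
  x
}

#' Read SNPs from a minimal VCF plus a strain-allele map
#'
#' Only CHROM, POS, ID, REF and ALT are consumed; genotype columns are
#' ignored. The map says which of REF/ALT belongs to each strain.
#'
#' @param path VCF path (plain text, may have `##` headers).
#' @param strain_map Two-column tibble or TSV path: `snp_id`,
#'   `B_is` (`"REF"` or `"ALT"`). SNPs absent from the map are dropped.
#' @return SNP tibble as from [read_snp_table()].
#' @export
read_snps_vcf <- function(path, strain_map) {
  if (is.character(strain_map)) {
    strain_map <- readr::read_tsv(strain_map, show_col_types = FALSE,
                                  col_types = readr::cols(.default = "c"))
  }
  stopifnot(all(c("snp_id", "B_is") %in% names(strain_map)))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no records in VCF")
  f <- strsplit(lines, "\t", fixed = TRUE)
  rec <- tibble::tibble(
    chrom = vapply(f, `[`, "", 1L),
    pos = as.numeric(vapply(f, `[`, "", 2L)),
    snp_id = vapply(f, `[`, "", 3L),
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L)
  )
  rec <- dplyr::inner_join(rec, strain_map, by = "snp_id")
  rec$allele_B <- ifelse(rec$B_is == "REF", rec$ref, rec$alt)
  rec$allele_C <- ifelse(rec$B_is == "REF", rec$alt, rec$ref)
  validate_snps(rec[c("chrom", "pos", "snp_id", "allele_B", "allele_C")],
                pos_is_one_based = TRUE)
}

#' Read gene models from BED12
#'
#' Each BED12 line is one transcript/model; blocks become exon intervals.
#' Use [collapse_gene_models()] afterwards to merge isoforms per gene.
#'
#' @param path BED12 path. The BED `name` field is taken as the gene (or
#'   transcript) identifier.
#' @return Exon-level tibble: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `coding` (TRUE when thickStart < thickEnd covers
#'   the exon at least partly; all TRUE when thick fields absent).
#' @export
read_gene_models_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  if (is.null(blocks)) {
    blocks <- IRanges::IRangesList(as.list(IRanges::ranges(gr)))
  }
  n_ex <- S4Vectors::elementNROWS(blocks)
  ex <- unlist(blocks, use.names = FALSE)
  # blocks are 1-based relative to the feature start
  feat_start0 <- rep(GenomicRanges::start(gr) - 1L, n_ex)
  tibble::tibble(
    gene_id = rep(gr$name, n_ex),
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), n_ex),
    strand = rep(as.character(GenomicRanges::strand(gr)), n_ex),
    start = feat_start0 + IRanges::start(ex) - 1L,
    end = feat_start0 + IRanges::end(ex),
    coding = TRUE
  )
}

#' Write gene models to BED12
#'
#' @param models Exon-level tibble (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`); one BED12 line is written per gene.
#' @param path Output path.
#' @export
write_gene_models_bed <- function(models, path) {
  by_gene <- split(models, models$gene_id)
  grl <- GenomicRanges::GRangesList(lapply(by_gene, function(m) {
    m <- m[order(m$start), ]
    GenomicRanges::GRanges(m$chrom,
                           IRanges::IRanges(m$start + 1L, m$end),
                           strand = ifelse(m$strand %in% c("+", "-"),
                                           m$strand, "*"))
  }))
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

#' Collapse transcript isoforms into one gene model per gene
#'
#' Takes the union of transcribed bases wherever isoforms of the same gene
#' overlap, so each gene ends with a set of disjoint, sorted exons.
#'
#' @param isoforms Exon-level tibble with `gene_id`, `chrom`, `strand`,
#'   `start`, `end` and optionally `coding` (0-based half-open intervals;
#'   one row per exon per isoform).
#' @return Exon-level tibble, one row per collapsed exon, with `exon_id`
#'   of the form `<gene_id>:e<k>`.
#' @export
collapse_gene_models <- function(isoforms) {
  if (any(isoforms$start >= isoforms$end)) {
    stop("exon interval with start >= end")
  }
  if (!"coding" %in% names(isoforms)) isoforms$coding <- TRUE
  out <- isoforms |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(m, key) {
      ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
      tibble::tibble(
        chrom = m$chrom[1], strand = m$strand[1],
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
        coding = any(m$coding)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
  out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon_id = paste0(.data$gene_id, ":e",
                                   dplyr::row_number())) |>
    dplyr::ungroup()
}

#' Assign SNPs to collapsed gene models
#'
#' A SNP is assigned to every gene whose collapsed exons contain its
#' position (0-based; half-open exon intervals). One output row per
#' (SNP, gene) assignment; a SNP in two overlapping genes appears twice and
#' is flagged `multi_gene`.
#'
#' @param snps SNP tibble (0-based `pos`).
#' @param models Collapsed exon-level tibble with `exon_id`.
#' @return SNP tibble with `gene_id`, `exon_id` and `multi_gene` filled;
#'   unassigned SNPs keep `gene_id = NA`.
#' @export
assign_snps <- function(snps, models) {
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos + 1L, width = 1L))
  ex_gr <- GenomicRanges::GRanges(models$chrom,
                                  IRanges::IRanges(models$start + 1L,
                                                   models$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, ex_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  assigned <- snps[qi, c("chrom", "pos", "snp_id", "allele_B", "allele_C")]
  assigned$gene_id <- models$gene_id[si]
  assigned$exon_id <- models$exon_id[si]
  # one row per (snp, gene): a SNP hitting 2 exons of one gene collapses
  assigned <- dplyr::distinct(assigned, .data$snp_id, .data$gene_id,
                              .keep_all = TRUE)
  n_genes <- table(assigned$snp_id)
  assigned$multi_gene <- as.vector(n_genes[assigned$snp_id]) > 1L
  un <- snps[!snps$snp_id %in% assigned$snp_id,
             c("chrom", "pos", "snp_id", "allele_B", "allele_C")]
  if (nrow(un)) {
    un$gene_id <- NA_character_
    un$exon_id <- NA_character_
    un$multi_gene <- FALSE
  }
  dplyr::arrange(dplyr::bind_rows(assigned, un), .data$chrom, .data$pos)
}

#' Read a known-imprinted-gene catalog
#'
#' @param path TSV with columns `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `expressed_allele` (`maternal`/`paternal`/`unknown`).
#' @return Tibble.
#' @export
read_known_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(start = "d", end = "d",
                                               .default = "c"))
  need <- c("gene_id", "name", "chrom", "start", "end", "expressed_allele")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  tibble::as_tibble(x)
}

#' Read pyrosequencing assay measurements
#'
#' @param path TSV with columns `assay_id`, `cross`, `replicate`, `material`
#'   (`RNA`/`DNA`), `pct_B` (percent of signal from the B allele, 0-100).
#' @return Tibble.
#' @export
read_pyro_assays <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(pct_B = "d", replicate = "i",
                                               .default = "c"))
  need <- c("assay_id", "cross", "replicate", "material", "pct_B")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pyro table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(x$material %in% c("RNA", "DNA"))) {
    stop("material must be 'RNA' or 'DNA'")
  }
  if (any(x$pct_B < 0 | x$pct_B > 100)) stop("pct_B must lie in [0, 100]")
  tibble::as_tibble(x)
}

#' Write a JSON run summary
#'
#' @param summary Named list (config echo, seeds, versions, headline counts).
#' @param path Output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
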