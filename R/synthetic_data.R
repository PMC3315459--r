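# Synthetic reciprocal-cross allelic count generator with known truth.
#
# Emulates the statistical structure of allele-specific RNA-Seq in
# reciprocal F1 hybrids on the logit scale: for SNP k of gene g in sample
# s whose mother is strain m,
#
#   logit theta_B = s_g + e_k + b_{g,s} + I_g * beta_g * u
#
# where s_g is a gene-level strain (cis-regulatory) effect, e_k a per-SNP
# systematic offset shared across ALL samples (sequence-dependent error:
# inflates same-exon discordance but, being cross-symmetric, cannot mimic
# imprinting), b_{g,s} a per-sample-by-gene biological deviation (the
# component that drives mock-cross false positives), and u = +1 when the
# expressed parental allele is B in that cross (-1 when C, 0 when the
# gene's sex-specificity excludes the sample). count_B is then
# beta-binomial with overdispersion rho (binomial at rho = 0).

#' Configuration for the synthetic reciprocal-cross generator
#'
#' Defaults describe a small but realistic embryonic-brain-like design:
#' four animals (both sexes of both crosses), SNP depths log-normal around
#' a median of 50 reads (spanning the 10-read powering rule), a tenth of
#' genes imprinted with strong logit effects, and modest systematic and
#' biological variance components.
#'
#' @param n_genes Number of genes.
#' @param snps_per_gene `list(mean =, max =)` of a truncated Poisson
#'   (minimum 1) for SNPs per gene.
#' @param spacing_bp `c(min, max)` uniform integer spacing between
#'   consecutive SNPs in an exon; the default straddles the 40 bp pair
#'   exclusion rule so both admissible and excluded pairs occur.
#' @param depth `list(meanlog =, sdlog =)` of the per-SNP log-normal read
#'   depth (truncated below at 1).
#' @param frac_imprinted Fraction of genes imprinted.
#' @param beta_imprint `c(mean, sd)` of the logit-scale imprinting effect
#'   (normal, truncated below at 0.5).
#' @param frac_sex_specific Fraction of imprinted genes whose effect is
#'   restricted to one sex.
#' @param strain_effect_sd SD of the gene-level strain effect (logit).
#' @param snp_bias_sd SD of the per-SNP systematic offset (logit).
#' @param bio_sd SD of the per-sample-by-gene biological deviation (logit).
#' @param rho Beta-binomial overdispersion in \[0, 1).
#' @param samples Sample metadata tibble; default is one animal of each sex
#'   in each cross direction.
#' @param chroms Chromosomes genes are laid out on (round-robin).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 200L,
                             snps_per_gene = list(mean = 3, max = 8),
                             spacing_bp = c(10L, 200L),
                             depth = list(meanlog = log(50), sdlog = 1),
                             frac_imprinted = 0.1,
                             beta_imprint = c(2, 0.5),
                             frac_sex_specific = 0.1,
                             strain_effect_sd = 0.5,
                             snp_bias_sd = 0.3,
                             bio_sd = 0.2,
                             rho = 0.01,
                             samples = NULL,
                             chroms = paste0("chr", 1:5),
                             seed = 1L) {
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = c("BxC_M1", "BxC_F1", "CxB_M1", "CxB_F1"),
      cross = c("BxC", "BxC", "CxB", "CxB"),
      sex = c("M", "F", "M", "F"),
      tissue = "brain", replicate = 1L
    )
  }
  cfg <- list(n_genes = as.integer(n_genes), snps_per_gene = snps_per_gene,
              spacing_bp = spacing_bp, depth = depth,
              frac_imprinted = frac_imprinted, beta_imprint = beta_imprint,
              frac_sex_specific = frac_sex_specific,
              strain_effect_sd = strain_effect_sd,
              snp_bias_sd = snp_bias_sd, bio_sd = bio_sd, rho = rho,
              samples = validate_sample_metadata(samples),
              chroms = chroms, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1,
            cfg$frac_imprinted >= 0, cfg$frac_imprinted <= 1,
            cfg$frac_sex_specific >= 0, cfg$frac_sex_specific <= 1,
            cfg$strain_effect_sd >= 0, cfg$snp_bias_sd >= 0,
            cfg$bio_sd >= 0, cfg$rho >= 0, cfg$rho < 1)
  structure(cfg, class = "synthetic_config")
}

rbetabinom <- function(n, size, theta, rho) {
  if (rho == 0) return(stats::rbinom(n, size, theta))
  nu <- (1 - rho) / rho
  p <- stats::rbeta(n, theta * nu, (1 - theta) * nu)
  stats::rbinom(n, size, p)
}

#' Generate a synthetic reciprocal-cross dataset
#'
#' @param config A [synthetic_config()].
#' @return List: `counts` (allelic count tibble), `snps` (assigned SNP
#'   tibble), `genes` (collapsed exon-level gene models), `samples`
#'   (metadata), `truth` (list of `genes`, `snps`, `bio` truth tables), and
#'   the `config`. Deterministic given `config$seed`.
#' @export
simulate_reciprocal_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  ng <- cfg$n_genes
  samples <- cfg$samples
  # --- gene-level truth
  imprinted <- stats::runif(ng) < cfg$frac_imprinted
  direction <- ifelse(imprinted,
                      ifelse(stats::runif(ng) < 0.5, "maternal", "paternal"),
                      "none")
  beta <- ifelse(imprinted,
                 pmax(stats::rnorm(ng, cfg$beta_imprint[1],
                                   cfg$beta_imprint[2]), 0.5), 0)
  sex_specific <- imprinted & stats::runif(ng) < cfg$frac_sex_specific
  imprint_sex <- ifelse(sex_specific,
                        ifelse(stats::runif(ng) < 0.5, "M", "F"), NA)
  strain <- stats::rnorm(ng, 0, cfg$strain_effect_sd)
  gene_id <- sprintf("g%04d", seq_len(ng))
  truth_genes <- tibble::tibble(
    gene_id = gene_id, strain_effect = strain, imprinted = imprinted,
    direction = direction, beta = beta, sex_specific = sex_specific,
    imprint_sex = imprint_sex
  )
  # --- layout: one coding exon per gene, SNPs at drawn spacings
  k <- pmin(pmax(stats::rpois(ng, cfg$snps_per_gene$mean), 1L),
            cfg$snps_per_gene$max)
  chrom <- rep(cfg$chroms, length.out = ng)
  gene_offset <- stats::ave(seq_len(ng), chrom, FUN = seq_along) * 10000L
  snp_rows <- lapply(seq_len(ng), function(g) {
    gid <- gene_id[g]
    gaps <- sample(cfg$spacing_bp[1]:cfg$spacing_bp[2], k[g], replace = TRUE)
    pos <- gene_offset[g] + cumsum(gaps)
    tibble::tibble(
      chrom = chrom[g], pos = pos,
      snp_id = sprintf("%s_s%02d", gid, seq_len(k[g])),
      allele_B = "A", allele_C = "G",
      gene_id = gid, exon_id = paste0(gid, ":e1"),
      multi_gene = FALSE
    )
  })
  snps <- dplyr::bind_rows(snp_rows)
  genes <- snps |>
    dplyr::summarise(start = min(.data$pos) - 10L, end = max(.data$pos) + 10L,
                     .by = c("gene_id", "chrom", "exon_id")) |>
    dplyr::mutate(strand = "+", coding = TRUE) |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end", "coding",
                  "exon_id")
  # --- per-SNP and per-sample x gene effects
  e_k <- stats::rnorm(nrow(snps), 0, cfg$snp_bias_sd)
  truth_snps <- tibble::tibble(snp_id = snps$snp_id,
                               gene_id = snps$gene_id, snp_bias = e_k)
  bio <- expand.grid(sample_id = samples$sample_id, gene_id = gene_id,
                     stringsAsFactors = FALSE)
  bio$deviation <- stats::rnorm(nrow(bio), 0, cfg$bio_sd)
  truth_bio <- tibble::as_tibble(bio)
  # --- counts
  counts <- dplyr::bind_rows(lapply(seq_len(nrow(samples)), function(si) {
    s <- samples[si, ]
    gi <- match(snps$gene_id, gene_id)
    b_gs <- truth_bio$deviation[match(paste(s$sample_id, snps$gene_id),
                                      paste(truth_bio$sample_id,
                                            truth_bio$gene_id))]
    # u: +1 when the expressed parental allele is B in this cross
    u <- ifelse(direction[gi] == "maternal",
                ifelse(s$cross == "BxC", 1, -1),
         ifelse(direction[gi] == "paternal",
                ifelse(s$cross == "BxC", -1, 1), 0))
    u <- ifelse(sex_specific[gi] & !is.na(imprint_sex[gi]) &
                  imprint_sex[gi] != s$sex, 0, u)
    eta <- strain[gi] + e_k + b_gs + beta[gi] * u
    theta <- stats::plogis(eta)
    depth <- pmax(1L, as.integer(round(stats::rlnorm(
      nrow(snps), cfg$depth$meanlog, cfg$depth$sdlog))))
    cb <- rbetabinom(nrow(snps), depth, theta, cfg$rho)
    tibble::tibble(snp_id = snps$snp_id, sample_id = s$sample_id,
                   count_B = cb, count_C = depth - cb)
  }))
  list(counts = counts, snps = snps, genes = genes, samples = samples,
       truth = list(genes = truth_genes, snps = truth_snps,
                    bio = truth_bio),
       config = cfg)
}

#' Confusion counts of calls against simulation truth
#'
#' Given a per-unit comparison table carrying both per-cross p-values
#' (e.g. from [call_genes()] or the internal threshold-free comparison
#' table) and the generator's gene truth, computes TP/FP/FN/TN, true FDR
#' and recall at each p-value threshold. A unit is predicted positive at
#' threshold t when it is powered, reciprocally biased, and both p-values
#' are below t.
#'
#' @param calls Call tibble with `id`, `p_1`, `p_2`, `status`, `score`.
#' @param truth_genes Truth tibble from the generator (`gene_id`,
#'   `imprinted`).
#' @param thresholds P-value thresholds.
#' @return Tibble: `threshold`, `tp`, `fp`, `fn`, `tn`, `fdr`, `recall`.
#' @export
truth_eval <- function(calls, truth_genes, thresholds) {
  unknown <- setdiff(calls$id, truth_genes$gene_id)
  if (length(unknown)) {
    stop("calls reference units absent from truth: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  is_imp <- calls$id %in% truth_genes$gene_id[truth_genes$imprinted]
  dplyr::bind_rows(lapply(thresholds, function(t) {
    pred <- sig_at(calls, t)
    tp <- sum(pred & is_imp); fp <- sum(pred & !is_imp)
    fn <- sum(!pred & is_imp); tn <- sum(!pred & !is_imp)
    tibble::tibble(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
                   fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
                   recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }))
}
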