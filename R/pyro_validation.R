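# Pyrosequencing-style validation caller.
#
# An independent allelic-ratio assay: percent B-allele signal measured in
# RNA from both reciprocal crosses and in F1 genomic DNA. The DNA, being a
# true 50:50 template, calibrates away assay bias; a transcript validates
# as imprinted only when the DNA-corrected biases of the two crosses point
# in opposite directions and differ by more than a threshold derived from
# biological-replicate variance (2 SD = 5.02 percentage points in the
# calibration this mirrors).

#' Replicate-derived imprinting threshold
#'
#' k standard deviations of the differences between paired biological
#' replicate measurements of percent allelic bias.
#'
#' @param rep1_pct,rep2_pct Paired replicate measurements (percent).
#' @param k SD multiplier (default 2).
#' @return Threshold in percentage points.
#' @export
replicate_threshold <- function(rep1_pct, rep2_pct, k = 2) {
  stopifnot(length(rep1_pct) == length(rep2_pct))
  if (length(rep1_pct) < 2) stop("need >= 2 replicate pairs")
  k * stats::sd(rep1_pct - rep2_pct)
}

#' DNA-calibrated allelic bias
#'
#' Corrected bias = RNA percent B minus the mean DNA percent B. The DNA
#' mean is the assay's empirical 50:50 point, so the sign of the corrected
#' value is the direction of bias relative to a true balanced template
#' (e.g. an assay reading 57:43 on hybrid DNA makes an RNA reading of 57
#' unbiased).
#'
#' @param rna_pct RNA percent B (vector).
#' @param dna_pcts DNA percent B measurements (averaged before correction).
#' @return Signed corrected bias in percentage points.
#' @export
dna_correct <- function(rna_pct, dna_pcts) {
  if (!length(dna_pcts)) stop("no DNA measurements to calibrate against")
  stopifnot(all(rna_pct >= 0 & rna_pct <= 100),
            all(dna_pcts >= 0 & dna_pcts <= 100))
  rna_pct - mean(dna_pcts)
}

#' Call one pyrosequencing assay
#'
#' Imprinted iff, for EVERY pairing of a BxC replicate with a CxB
#' replicate, the DNA-corrected biases have opposite signs (reciprocal
#' bias relative to the DNA ratio) and differ by more than `threshold_pct`.
#' `mode = "averaged"` instead applies the rule once to the
#' replicate-averaged corrected biases.
#'
#' @param assay Tibble for one assay: columns `cross` (`BxC`/`CxB`),
#'   `replicate`, `material` (`RNA`/`DNA`), `pct_B`.
#' @param threshold_pct Minimum absolute difference between the corrected
#'   biases (default 5.02, i.e. 2 SD of replicate variance).
#' @param mode `"per_replicate"` (default) or `"averaged"`.
#' @return One-row tibble: `status` (`imprinted`/`not_imprinted`),
#'   `delta_pct` (mean corrected-bias difference over pairings), `z_units`
#'   (delta relative to the 1-SD unit, i.e. `2 * delta / threshold`),
#'   `direction` (`maternal`/`paternal`/`none`).
#' @export
call_pyro <- function(assay, threshold_pct = 5.02,
                      mode = c("per_replicate", "averaged")) {
  mode <- match.arg(mode)
  dna <- assay$pct_B[assay$material == "DNA"]
  if (!length(dna)) stop("assay has no DNA measurement")
  rna <- assay[assay$material == "RNA", ]
  for (cr in c("BxC", "CxB")) {
    if (!any(rna$cross == cr)) stop("assay missing RNA for cross ", cr)
  }
  bxc <- dna_correct(rna$pct_B[rna$cross == "BxC"], dna)
  cxb <- dna_correct(rna$pct_B[rna$cross == "CxB"], dna)
  if (mode == "averaged") {
    bxc <- mean(bxc)
    cxb <- mean(cxb)
  }
  grid <- expand.grid(b = bxc, c = cxb)
  opposite <- sign(grid$b) * sign(grid$c) < 0
  delta <- abs(grid$b - grid$c)
  imprinted <- all(opposite) && all(delta > threshold_pct)
  mean_delta <- mean(abs(mean(bxc) - mean(cxb)))
  direction <- if (!imprinted) "none"
    # corrected bias is toward B; B is maternal in BxC
    else if (mean(bxc) > 0) "maternal" else "paternal"
  tibble::tibble(status = if (imprinted) "imprinted" else "not_imprinted",
                 delta_pct = mean_delta,
                 z_units = 2 * mean_delta / threshold_pct,
                 direction = direction)
}

#' Call every assay in a pyro measurement table
#'
#' @param assays Tibble from [read_pyro_assays()].
#' @inheritParams call_pyro
#' @return Tibble with one row per `assay_id`.
#' @export
call_pyro_all <- function(assays, threshold_pct = 5.02,
                          mode = c("per_replicate", "averaged")) {
  mode <- match.arg(mode)
  assays |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::group_modify(function(d, key) call_pyro(d, threshold_pct, mode)) |>
    dplyr::ungroup()
}
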