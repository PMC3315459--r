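#' Chi-square test of allele-specific expression at one SNP
#'
#' Pearson goodness-of-fit of the two allelic read counts against an expected
#' 50:50 split (df = 1, no continuity correction). This is the per-observation
#' statistic underlying every imprinting call in the package: for counts
#' \eqn{b} and \eqn{c} with depth \eqn{n = b + c},
#' \deqn{\chi^2 = (b - n/2)^2/(n/2) + (c - n/2)^2/(n/2) = (b - c)^2 / n,}
#' and the p-value is the upper chi-square tail with one degree of freedom.
#' The continuity correction is deliberately omitted: the uncorrected test is
#' what a 30/70 split must give (chi2 = 16, p = 6.3e-5).
#'
#' @param count_B,count_C Non-negative integer vectors of reads supporting the
#'   B (C57Bl/6J) and C (CAST/EiJ) allele. Recycled to a common length.
#' @return A tibble with one row per input: `count_B`, `count_C`, `n`,
#'   `chi2`, `p`, and `direction` (`"B"`, `"C"` or `"none"`; the allele with
#'   more than half the reads, `"none"` on an exact tie).
#' @examples
#' ase_chisq(30, 70)   # chi2 = 16, p ~ 6.3e-5, direction C
#' ase_chisq(30, 20)   # chi2 = 2,  p ~ 0.157,  direction B
#' @export
ase_chisq <- function(count_B, count_C) {
  stopifnot(is.numeric(count_B), is.numeric(count_C))
  k <- vctrs::vec_recycle_common(count_B = count_B, count_C = count_C)
  count_B <- k$count_B
  count_C <- k$count_C
  if (any(count_B < 0 | count_C < 0, na.rm = TRUE)) {
    stop("allelic counts must be non-negative")
  }
  n <- count_B + count_C
  if (any(n == 0, na.rm = TRUE)) {
    stop("chi-square ASE test undefined at depth 0")
  }
  chi2 <- (count_B - count_C)^2 / n
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- dplyr::case_when(
    count_B > count_C ~ "B",
    count_C > count_B ~ "C",
    .default = "none"
  )
  tibble::tibble(count_B = count_B, count_C = count_C, n = n,
                 chi2 = chi2, p = p, direction = direction)
}

#' Fraction of reads from the maternal allele
#'
#' The maternal strain is listed first in the cross label: under BxC the
#' mother is C57Bl/6J (allele B), under CxB she is CAST/EiJ (allele C).
#' A fraction above 0.5 in both reciprocal samples (or below 0.5 in both)
#' is the parent-of-origin agreement every imprinting call requires.
#'
#' @param count_B,count_C Allelic read counts (recycled).
#' @param cross Character vector of cross labels, `"BxC"` or `"CxB"`.
#' @return Numeric vector in \[0, 1\].
#' @export
maternal_fraction <- function(count_B, count_C, cross) {
  k <- vctrs::vec_recycle_common(count_B = count_B, count_C = count_C,
                                 cross = cross)
  if (!all(k$cross %in% c("BxC", "CxB"))) {
    stop("cross must be 'BxC' or 'CxB'")
  }
  n <- k$count_B + k$count_C
  if (any(n == 0, na.rm = TRUE)) stop("maternal fraction undefined at depth 0")
  maternal <- ifelse(k$cross == "BxC", k$count_B, k$count_C)
  maternal / n
}

#' Signed imprinting score for a reciprocal comparison
#'
#' The score is the signed negative log10 of the *less* significant of the
#' two per-cross chi-square p-values, defined only when both crosses are
#' biased toward the same parental sex. Positive scores are maternal-biased,
#' negative paternal (a fixed convention; the sign carries no significance
#' information).
#'
#' @param count_B1,count_C1 Counts in the first sample.
#' @param count_B2,count_C2 Counts in the second sample.
#' @param cross1,cross2 Cross labels of the two samples (`"BxC"`/`"CxB"`).
#' @return A tibble with `p_1`, `p_2`, `p_used` (= max of the two),
#'   `reciprocal` (logical: parent-of-origin agreement), `direction`
#'   (`"maternal"`, `"paternal"`, `"none"`), and `score` (signed
#'   \eqn{-\log_{10} p_{used}}; `NA` when not reciprocal).
#' @export
imprinting_score <- function(count_B1, count_C1, count_B2, count_C2,
                             cross1, cross2) {
  t1 <- ase_chisq(count_B1, count_C1)
  t2 <- ase_chisq(count_B2, count_C2)
  m1 <- maternal_fraction(t1$count_B, t1$count_C, cross1)
  m2 <- maternal_fraction(t2$count_B, t2$count_C, cross2)
  reciprocal <- (m1 > 0.5 & m2 > 0.5) | (m1 < 0.5 & m2 < 0.5)
  direction <- dplyr::case_when(
    reciprocal & m1 > 0.5 ~ "maternal",
    reciprocal & m1 < 0.5 ~ "paternal",
    .default = "none"
  )
  p_used <- pmax(t1$p, t2$p)
  score <- ifelse(reciprocal,
                  ifelse(direction == "maternal", 1, -1) * -log10(p_used),
                  NA_real_)
  tibble::tibble(p_1 = t1$p, p_2 = t2$p, p_used = p_used,
                 reciprocal = reciprocal, direction = direction, score = score)
}
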