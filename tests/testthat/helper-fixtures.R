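# In-code fixtures shared across test files.

fixture_samples <- function() {
  tibble::tibble(
    sample_id = c("BxC_M1", "BxC_F1", "CxB_M1", "CxB_F1"),
    cross = c("BxC", "BxC", "CxB", "CxB"),
    sex = c("M", "F", "M", "F"),
    tissue = "brain",
    replicate = 1L
  )
}

write_fixture_tsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, p)
  p
}

# brute-force union of 0-based half-open intervals via base-pair membership
brute_union_bases <- function(start, end) {
  covered <- unique(unlist(Map(function(s, e) seq(s, e - 1L), start, end)))
  sort(covered)
}

# pair tibble in the shape enumerate_snp_pairs() emits, built from raw
# counts of two SNPs per exon
make_pairs <- function(b1, c1, b2, c2) {
  t1 <- ase_chisq(b1, c1)
  t2 <- ase_chisq(b2, c2)
  out <- tibble::tibble(
    exon_id = sprintf("ex%05d", seq_along(b1)),
    snp1 = paste0("s", seq_along(b1), "a"),
    snp2 = paste0("s", seq_along(b1), "b"),
    pos1 = 0L, pos2 = 100L, separation = 100L,
    count_B1 = b1, count_C1 = c1, count_B2 = b2, count_C2 = c2,
    p1 = t1$p, p2 = t2$p, dir1 = t1$direction, dir2 = t2$direction
  )
  keep <- out$dir1 != "none" & out$dir2 != "none"
  out <- out[keep, ]
  out$p_pair <- pmax(out$p1, out$p2)
  out$concordant <- out$dir1 == out$dir2
  out
}

# binomial same-exon null pairs sharing a true per-exon ratio
make_null_pairs <- function(n, ratio_range = c(0.5, 0.9),
                            depth_meanlog = log(120), depth_sdlog = 1,
                            depth_min = 20, depth_max = 1000) {
  r <- stats::runif(n, ratio_range[1], ratio_range[2])
  draw_depth <- function() {
    pmin(pmax(round(stats::rlnorm(n, depth_meanlog, depth_sdlog)),
              depth_min), depth_max)
  }
  n1 <- draw_depth(); n2 <- draw_depth()
  b1 <- stats::rbinom(n, n1, r)
  b2 <- stats::rbinom(n, n2, r)
  make_pairs(b1, n1 - b1, b2, n2 - b2)
}
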