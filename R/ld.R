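#' Signed LD statistic r from phased haplotype counts
#'
#' Computes `r = (f11 f22 - f12 f21) / sqrt(f1. f2. f.1 f.2)` from the
#' four haplotype frequencies of a pair of biallelic loci, estimated from
#' phased haplotypes. Equals the Pearson correlation of allele indicators
#' across haplotypes. The sign is anchored by the simulator's allele-1
#' label, which is the same in both populations, so r values are
#' comparable between populations.
#'
#' @param n11,n12,n21,n22 Haplotype counts: first index is the allele (1 or
#'   2) at the first locus, second index at the second locus. Here allele
#'   "1" denotes the counted allele (coded 1) and allele "2" the other.
#' @return The signed r, or `NA` if either locus is monomorphic.
#' @examples
#' ld_r(50, 0, 0, 50)   # perfect coupling: 1
#' ld_r(25, 25, 25, 25) # independence: 0
#' @export
ld_r <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  stopifnot(n > 0)
  f11 <- n11 / n; f12 <- n12 / n; f21 <- n21 / n; f22 <- n22 / n
  f1. <- f11 + f12; f2. <- f21 + f22
  f.1 <- f11 + f21; f.2 <- f12 + f22
  d <- f1. * f2. * f.1 * f.2
  if (d <= 0) return(NA_real_)
  (f11 * f22 - f12 * f21) / sqrt(d)
}

# signed r between all column pairs of two 0/1 haplotype matrices
# (haplotypes x loci); columns monomorphic give NA
.r_matrix <- function(H1, H2) {
  s1 <- apply(H1, 2, stats::sd)
  s2 <- apply(H2, 2, stats::sd)
  suppressWarnings(R <- stats::cor(H1, H2))
  R[s1 == 0, ] <- NA_real_
  if (any(s2 == 0)) R[, s2 == 0] <- NA_real_
  R
}

#' LD decay and between-population consistency of LD phase
#'
#' For all causal-locus x marker pairs on the same chromosome closer than
#' `max_cM`, computes the signed LD statistic r in each population and
#' summarizes per distance bin (half-open bins of `bin_cM` centimorgan):
#' the mean r-squared per population and the correlation between the two
#' populations' r values over the pairs in the bin (the consistency of LD
#' phase). Pairs for which either locus is monomorphic in a population are
#' excluded from that population's statistics and, pairwise-complete, from
#' the consistency correlation.
#'
#' @param hap_A,hap_B Raw haplotype matrices of the two populations.
#' @param causal,markers 1-based locus indices.
#' @param map The [genome_map()].
#' @param max_cM Maximum pair distance (default 10).
#' @param bin_cM Bin width (default 0.1).
#' @return Data frame with `bin_start_cM`, `mean_r2_A`, `mean_r2_B`,
#'   `corr_r_AB`, `n_pairs` (pairs with r defined in both populations);
#'   bins without pairs are reported with `NA` summaries.
#' @export
ld_profiles <- function(hap_A, hap_B, causal, markers, map,
                        max_cM = 10, bin_cM = 0.1) {
  nb <- ceiling(max_cM / bin_cM)
  acc <- data.frame(bin = seq_len(nb) - 1L,
                    sum_r2_A = 0, n_A = 0, sum_r2_B = 0, n_B = 0)
  pairs_rA <- vector("list", nb); pairs_rB <- vector("list", nb)
  for (c in unique(map$chr[causal])) {
    ci <- causal[map$chr[causal] == c]
    mi <- markers[map$chr[markers] == c]
    if (!length(ci) || !length(mi)) next
    HA_c <- hap_alleles(hap_A, ci); HA_m <- hap_alleles(hap_A, mi)
    HB_c <- hap_alleles(hap_B, ci); HB_m <- hap_alleles(hap_B, mi)
    RA <- .r_matrix(HA_c, HA_m)
    RB <- .r_matrix(HB_c, HB_m)
    D <- abs(outer(map$pos_cM[ci], map$pos_cM[mi], "-"))
    keep <- D < max_cM & D > 0
    bin <- pmin(floor(D / bin_cM), nb - 1L)
    for (b in unique(bin[keep])) {
      sel <- keep & bin == b
      ra <- RA[sel]; rb <- RB[sel]
      acc$sum_r2_A[b + 1L] <- acc$sum_r2_A[b + 1L] + sum(ra^2, na.rm = TRUE)
      acc$n_A[b + 1L] <- acc$n_A[b + 1L] + sum(!is.na(ra))
      acc$sum_r2_B[b + 1L] <- acc$sum_r2_B[b + 1L] + sum(rb^2, na.rm = TRUE)
      acc$n_B[b + 1L] <- acc$n_B[b + 1L] + sum(!is.na(rb))
      ok <- !is.na(ra) & !is.na(rb)
      if (any(ok)) {
        pairs_rA[[b + 1L]] <- c(pairs_rA[[b + 1L]], ra[ok])
        pairs_rB[[b + 1L]] <- c(pairs_rB[[b + 1L]], rb[ok])
      }
    }
  }
  corr <- mapply(function(x, y) {
    if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_
  }, pairs_rA, pairs_rB)
  out <- data.frame(
    bin_start_cM = (seq_len(nb) - 1L) * bin_cM,
    mean_r2_A = ifelse(acc$n_A > 0, acc$sum_r2_A / acc$n_A, NA_real_),
    mean_r2_B = ifelse(acc$n_B > 0, acc$sum_r2_B / acc$n_B, NA_real_),
    corr_r_AB = as.numeric(corr),
    n_pairs = lengths(pairs_rA))
  if (all(out$n_pairs == 0)) warning("no valid locus pairs in any bin")
  out
}
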