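# Small in-code fixtures shared across test files.

# haplotype panel from a 0/1 matrix (loci x haplotypes)
as_hap <- function(m) matrix(as.raw(m), nrow = nrow(m))

# tiny two-population cohort: n individuals per population, m loci,
# independent alleles at the given frequencies
random_cohort <- function(n, m, p = rep(0.5, m)) {
  cnt <- function() {
    g <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
    g
  }
  list(A = cnt(), B = cnt())
}

# tiny genome map with evenly spread loci (deterministic positions)
tiny_map <- function(n_chr = 1, loci_per_chr = 100, chr_len_M = 1) {
  pos <- lapply(seq_len(n_chr), function(c)
    seq(0.001, chr_len_M - 0.001, length.out = loci_per_chr))
  map <- list(
    n_loci = n_chr * loci_per_chr,
    chr = rep(seq_len(n_chr), each = loci_per_chr),
    pos_M = unlist(pos),
    chr_len_M = rep(chr_len_M, n_chr),
    chr_start = c(0L, seq_len(n_chr) * loci_per_chr)
  )
  map$pos_cM <- 100 * map$pos_M
  class(map) <- "genome_map"
  map
}

# structured positive-definite blocked relationship matrix with a non-zero
# between-population block (low-rank ancestry + diagonal)
structured_G <- function(n_A, n_B, k = 8, ridge = 0.3) {
  n <- n_A + n_B
  Q <- matrix(stats::rnorm(n * k), n, k) / sqrt(k)
  M <- tcrossprod(Q) + diag(ridge, n)
  # normalize to mean diagonal 1
  M <- M / mean(diag(M))
  blocked_relmat(M, n_A, n_B, source = "synthetic")
}

# draw phenotypes from the bivariate GREML generative model
simulate_from_G <- function(G, pop, s2A, s2B, sAB, seA, seB, mu = c(0, 0)) {
  n <- nrow(G)
  iA <- pop == "A"
  S <- matrix(0, n, n)
  S[iA, iA] <- s2A * unclass(G)[iA, iA]
  S[!iA, !iA] <- s2B * unclass(G)[!iA, !iA]
  S[iA, !iA] <- sAB * unclass(G)[iA, !iA]
  S[!iA, iA] <- sAB * unclass(G)[!iA, iA]
  a <- drop(crossprod(chol(S + diag(1e-8, n)), stats::rnorm(n)))
  e <- stats::rnorm(n, 0, sqrt(ifelse(iA, seA, seB)))
  mu[ifelse(iA, 1, 2)] + a + e
}
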