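#' Genome map with randomly spaced loci
#'
#' Lays out biallelic loci uniformly at random along chromosomes of given
#' genetic length. Positions are sorted and de-duplicated within each
#' chromosome, so positions are strictly increasing per chromosome. The
#' default genome is 10 chromosomes of 1 Morgan; at full scale each carries
#' 300,000 loci.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_len_M Chromosome length in Morgan (recycled to `n_chr`).
#' @param loci_per_chr Number of loci per chromosome (recycled).
#' @return A list of class `genome_map` with `n_loci`, `chr` (chromosome
#'   index per locus), `pos_M` (position in Morgan within chromosome),
#'   `pos_cM`, `chr_len_M`, and `chr_start` (0-based offset of each
#'   chromosome's first locus, plus the total as last element; used by the
#'   simulation kernel).
#' @examples
#' map <- genome_map(n_chr = 2, loci_per_chr = 100)
#' map$n_loci
#' @export
genome_map <- function(n_chr = 10, chr_len_M = 1, loci_per_chr = 300000) {
  stopifnot(n_chr >= 1, all(chr_len_M > 0), all(loci_per_chr >= 1))
  chr_len_M <- rep_len(chr_len_M, n_chr)
  loci_per_chr <- rep_len(as.integer(loci_per_chr), n_chr)
  pos <- vector("list", n_chr)
  for (c in seq_len(n_chr)) {
    p <- sort(stats::runif(loci_per_chr[c], 0, chr_len_M[c]))
    p <- unique(p)
    while (length(p) < loci_per_chr[c]) {
      p <- sort(unique(c(p, stats::runif(loci_per_chr[c] - length(p),
                                         0, chr_len_M[c]))))
    }
    pos[[c]] <- p
  }
  n_per <- lengths(pos)
  map <- list(
    n_loci = sum(n_per),
    chr = rep(seq_len(n_chr), n_per),
    pos_M = unlist(pos, use.names = FALSE),
    chr_len_M = chr_len_M,
    chr_start = c(0L, cumsum(n_per))
  )
  map$pos_cM <- 100 * map$pos_M
  class(map) <- "genome_map"
  map
}
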