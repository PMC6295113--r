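#' Export genotypes in PLINK .ped/.map text format
#'
#' Writes one population's generation-50 genotypes. Alleles are coded 1/2
#' (allele code 0 becomes 1, code 1 becomes 2); the genetic-distance column
#' of the .map file carries the position in cM, the physical position is
#' the cM position times 10^4.
#'
#' @param hap Raw haplotype matrix of the cohort.
#' @param map A [genome_map()].
#' @param loci 1-based locus indices to export.
#' @param prefix Output path prefix (writes `<prefix>.ped`,
#'   `<prefix>.map`).
#' @param family Family identifier written to the .ped file.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(hap, map, loci, prefix, family = "POP") {
  loci <- as.integer(loci)
  H <- hap_alleles(hap, loci) + 1L  # haplotypes x loci, alleles 1/2
  n <- nrow(H) / 2
  al <- matrix(0L, n, 2L * length(loci))
  al[, seq(1, ncol(al), by = 2)] <- H[seq(1, nrow(H), by = 2), ]
  al[, seq(2, ncol(al), by = 2)] <- H[seq(2, nrow(H), by = 2), ]
  ped <- cbind(family, paste0(family, "_", seq_len(n)), 0, 0, 0, -9, al)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mp <- data.frame(chr = map$chr[loci],
                   id = paste0("locus", loci),
                   cM = map$pos_cM[loci],
                   bp = as.integer(round(map$pos_cM[loci] * 1e4)))
  utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Export a relationship matrix as GCTA-style lower-triangle text
#'
#' Tab-separated rows `i j n_loci value` over the lower triangle
#' (diagonal included), with 1-based indices.
#'
#' @param G A [blocked_relmat].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_grm_text <- function(G, file) {
  n <- nrow(G)
  idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  nl <- attr(G, "n_loci")
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   n_loci = if (is.na(nl)) 0L else nl,
                   value = unclass(G)[idx])
  utils::write.table(df, file, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a GCTA-style lower-triangle relationship matrix
#'
#' @param file Path written by [write_grm_text()].
#' @param n_A Number of population-A individuals (first block), for the
#'   block labels.
#' @return A [blocked_relmat].
#' @export
read_grm_text <- function(file, n_A) {
  df <- utils::read.table(file, col.names = c("i", "j", "n_loci", "value"))
  n <- max(df$i)
  M <- matrix(0, n, n)
  M[cbind(df$i, df$j)] <- df$value
  M[cbind(df$j, df$i)] <- df$value
  blocked_relmat(M, n_A = n_A, n_B = n - n_A, source = "file",
                 n_loci = df$n_loci[1])
}

#' Export a locus panel as CSV
#'
#' One row per selected locus with its role (panel membership or causal),
#' map position, and per-population allele frequencies.
#'
#' @param panel A `locus_panel` from [select_loci()].
#' @param map The [genome_map()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_panel_csv <- function(panel, map, file) {
  rows <- list()
  for (nm in names(panel$markers)) {
    i <- panel$markers[[nm]]
    rows[[nm]] <- data.frame(locus = i, role = nm)
  }
  rows$causal <- data.frame(locus = panel$causal, role = "causal")
  df <- do.call(rbind, rows)
  df$chr <- map$chr[df$locus]
  df$pos_cM <- map$pos_cM[df$locus]
  df$p_A <- panel$p_A[df$locus]
  df$p_B <- panel$p_B[df$locus]
  df$scenario <- panel$scenario
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
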