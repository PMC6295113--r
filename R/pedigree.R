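#' Pedigree numerator relationship matrix and inbreeding
#'
#' Computes the numerator relationship matrix A by the tabular method,
#' separately within each population (between-population pedigree
#' relationships are zero by construction, since the recorded pedigree
#' starts after the population split). Returns the blocked A restricted to
#' a chosen set of individuals (by default the last recorded generation,
#' i.e. the genotyped cohort) together with their inbreeding coefficients.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (0 =
#'   unknown), `generation`, `population`; parents must precede offspring
#'   within each population.
#' @param ids Individuals (by `id`) to keep in the returned matrix;
#'   defaults to the last generation of each population.
#' @return A [blocked_relmat] with source `"pedigree"` and attribute
#'   `F` (named vector of inbreeding coefficients, diag - 1) plus
#'   `F_bar` (mean inbreeding per population over the kept individuals).
#' @examples
#' ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
#'                   generation = c(1, 1, 2), population = "A")
#' A <- build_pedigree_A(ped, ids = 1:3)
#' unclass(A)[3, 1]  # offspring-parent relationship 0.5
#' @export
build_pedigree_A <- function(pedigree, ids = NULL) {
  stopifnot(all(c("id", "sire", "dam", "population") %in% names(pedigree)))
  pops <- sort(unique(pedigree$population))
  if (is.null(ids)) {
    ids <- unlist(lapply(pops, function(p) {
      pp <- pedigree[pedigree$population == p, ]
      pp$id[pp$generation == max(pp$generation)]
    }))
  }
  blocks <- list(); fbar <- numeric(0); keep_ids <- list(); fvals <- list()
  for (p in pops) {
    pp <- pedigree[pedigree$population == p, , drop = FALSE]
    pp <- pp[order(pp$generation, pp$id), , drop = FALSE]
    pos <- match(pp$id, pp$id)
    sire <- match(pp$sire, pp$id); sire[is.na(sire)] <- 0L
    dam <- match(pp$dam, pp$id); dam[is.na(dam)] <- 0L
    if (any(sire >= seq_along(sire) & sire > 0) ||
        any(dam >= seq_along(dam) & dam > 0))
      stop("pedigree not sorted: parents must precede offspring")
    A <- .amat_cpp(as.integer(sire), as.integer(dam))
    sel <- which(pp$id %in% ids)
    blocks[[p]] <- A[sel, sel, drop = FALSE]
    keep_ids[[p]] <- pp$id[sel]
    fvals[[p]] <- diag(A)[sel] - 1
    fbar[p] <- mean(fvals[[p]])
  }
  n <- vapply(blocks, nrow, 1L)
  M <- matrix(0, sum(n), sum(n))
  off <- c(0L, cumsum(n))
  for (k in seq_along(blocks)) {
    ix <- off[k] + seq_len(n[k])
    M[ix, ix] <- blocks[[k]]
  }
  out <- blocked_relmat(M, n_A = n[1], n_B = if (length(n) > 1) n[2] else 0L,
                        source = "pedigree",
                        ids = unlist(keep_ids, use.names = FALSE))
  attr(out, "F") <- unlist(fvals, use.names = FALSE)
  attr(out, "F_bar") <- fbar
  out
}

#' Write a pedigree to CSV
#'
#' Columns `id,sire,dam,generation,population,sex`; unknown parents are 0.
#'
#' @param pedigree Pedigree data frame.
#' @param file Output path.
#' @export
write_pedigree_csv <- function(pedigree, file) {
  cols <- intersect(c("id", "sire", "dam", "generation", "population", "sex"),
                    names(pedigree))
  utils::write.csv(pedigree[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
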