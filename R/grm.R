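#' Blocked relationship matrix
#'
#' A symmetric relationship matrix over the individuals of two populations,
#' A first then B, with block structure AA / AB / BB. Used for genomic
#' relationship matrices (at causal loci or marker panels), the pedigree
#' matrix, and their rescaled/regressed versions.
#'
#' @param M Symmetric numeric matrix, A individuals first.
#' @param n_A,n_B Numbers of individuals per population.
#' @param source Provenance tag, e.g. `"causal"`, `"HDP"`, `"pedigree"`.
#' @param n_loci Number of loci used to build the matrix (if genomic).
#' @param ids Optional individual identifiers.
#' @return The matrix with class `blocked_relmat` and the block metadata
#'   as attributes.
#' @export
blocked_relmat <- function(M, n_A, n_B, source = "unknown", n_loci = NA_integer_,
                           ids = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) == n_A + n_B)
  structure(M, class = c("blocked_relmat", "matrix"),
            n_A = as.integer(n_A), n_B = as.integer(n_B),
            source = source, n_loci = n_loci, ids = ids)
}

# logical index matrices for the three off-diagonal blocks / diagonal
.block_masks <- function(G) {
  nA <- attr(G, "n_A"); nB <- attr(G, "n_B"); n <- nA + nB
  ia <- seq_len(nA); ib <- nA + seq_len(nB)
  pop <- rep(c("A", "B"), c(nA, nB))
  within <- outer(pop, pop, "==")
  list(n_A = nA, n_B = nB, pop = pop,
       AA = outer(seq_len(n), seq_len(n),
                  function(i, j) i > j) & within & outer(pop == "A", pop == "A"),
       BB = outer(seq_len(n), seq_len(n),
                  function(i, j) i > j) & within & outer(pop == "B", pop == "B"),
       AB = !within & outer(seq_len(n), seq_len(n), function(i, j) i > j))
}

#' Cross-population genomic relationship matrix
#'
#' Builds the blocked genomic relationship matrix from allele counts of the
#' two populations at a common locus subset, centering each population's
#' counts by twice its own allele frequency. With `W_k` the centered counts
#' of population k and `s_k = sum(2 p_ki (1 - p_ki))`:
#' `G_AA = W_A W_A' / s_A`, `G_BB = W_B W_B' / s_B`, and
#' `G_AB = W_A W_B' / sqrt(s_A s_B)`. Loci monomorphic within a population
#' contribute zero centered counts and zero to that population's
#' denominator. Within a population this is the usual allele-frequency
#' weighted GRM (VanRaden method 1); the population-specific centering
#' makes between-population relationships average approximately zero.
#'
#' @param counts_A,counts_B Integer matrices of allele counts (individuals
#'   x loci, entries 0/1/2) at the same loci.
#' @param p_A,p_B Allele-1 frequencies used for centering; default is the
#'   sample frequency of each cohort.
#' @param source Provenance tag stored on the result.
#' @return A [blocked_relmat].
#' @export
build_grm <- function(counts_A, counts_B, p_A = colMeans(counts_A) / 2,
                      p_B = colMeans(counts_B) / 2, source = "G") {
  stopifnot(ncol(counts_A) == ncol(counts_B), ncol(counts_A) >= 1)
  sA <- sum(2 * p_A * (1 - p_A))
  sB <- sum(2 * p_B * (1 - p_B))
  if (sA <= 0 || sB <= 0)
    stop("all loci monomorphic in at least one population")
  WA <- sweep(counts_A, 2, 2 * p_A)
  WB <- sweep(counts_B, 2, 2 * p_B)
  GAA <- tcrossprod(WA) / sA
  GBB <- tcrossprod(WB) / sB
  GAB <- tcrossprod(WA, WB) / sqrt(sA * sB)
  M <- rbind(cbind(GAA, GAB), cbind(t(GAB), GBB))
  blocked_relmat(M, n_A = nrow(counts_A), n_B = nrow(counts_B),
                 source = source, n_loci = ncol(counts_A))
}

#' Rescale the inbreeding level of G to the pedigree level
#'
#' Applies `G* = (1 - Fbar_k) G + 2 Fbar_k J` within each population block,
#' where `Fbar_k` is the mean pedigree inbreeding of population k's
#' genotyped individuals and `J` is a matrix of ones. The between-population
#' block uses the geometric-mean form
#' `sqrt((1-Fbar_A)(1-Fbar_B)) G + 2 sqrt(Fbar_A Fbar_B) J`, which reduces
#' to the within-population formula when the two means are equal.
#'
#' @param G A genomic [blocked_relmat].
#' @param F_A,F_B Mean pedigree inbreeding per population, each in `[0, 1)`.
#' @return The rescaled [blocked_relmat] (source suffixed `"*"`).
#' @export
rescale_inbreeding <- function(G, F_A, F_B) {
  stopifnot(F_A >= 0, F_A < 1, F_B >= 0, F_B < 1)
  nA <- attr(G, "n_A"); nB <- attr(G, "n_B")
  ia <- seq_len(nA); ib <- nA + seq_len(nB)
  M <- unclass(G)
  M[ia, ia] <- (1 - F_A) * M[ia, ia] + 2 * F_A
  M[ib, ib] <- (1 - F_B) * M[ib, ib] + 2 * F_B
  M[ia, ib] <- sqrt((1 - F_A) * (1 - F_B)) * M[ia, ib] +
    2 * sqrt(F_A * F_B)
  M[ib, ia] <- t(M[ia, ib])
  blocked_relmat(M, nA, nB, source = paste0(attr(G, "source"), "*"),
                 n_loci = attr(G, "n_loci"), ids = attr(G, "ids"))
}

# sample variance of entries, guarding length-1 bins
.bin_var <- function(x) if (length(x) >= 2) stats::var(x) else 0

#' Regress G toward the pedigree relationship matrix
#'
#' Shrinks marker-based relationships toward their pedigree expectation to
#' account for marker sampling error: `Ghat = A + b (G* - A)` with
#' `b = Var(G* - A) / (Var(G* - A) + 1/n)`, n the number of markers. The
#' coefficient is computed separately for between-population entries and
#' for four bins of within-population pedigree relationships (< 0.10,
#' 0.10-0.25, 0.25-0.50, > 0.50). On the diagonal only the inbreeding
#' coefficients (diag - 1) are regressed. An empty bin falls back to the
#' pooled within-population coefficient.
#'
#' @param G_star Inbreeding-rescaled genomic [blocked_relmat].
#' @param A Pedigree [blocked_relmat] on the same individuals.
#' @param n_markers Number of markers behind `G_star`; defaults to its
#'   `n_loci` attribute.
#' @return The regressed [blocked_relmat]; attribute `b` holds the per-bin
#'   coefficients (between, the four within bins, diagonal).
#' @export
regress_to_A <- function(G_star, A, n_markers = attr(G_star, "n_loci")) {
  stopifnot(all(dim(G_star) == dim(A)), n_markers >= 1)
  m <- .block_masks(G_star)
  Gm <- unclass(G_star); Am <- unclass(A)
  D <- Gm - Am
  bfun <- function(d) {
    v <- .bin_var(d)
    v / (v + 1 / n_markers)
  }
  within <- m$AA | m$BB
  b_within_pooled <- bfun(D[within])
  edges <- c(-Inf, 0.10, 0.25, 0.50, Inf)
  bins <- .bin_cut(Am, edges)
  out <- Gm
  b <- c(between = bfun(D[m$AB]))
  out[m$AB] <- Am[m$AB] + b["between"] * D[m$AB]
  for (k in 1:4) {
    sel <- within & bins == k
    bk <- if (any(sel)) bfun(D[sel]) else b_within_pooled
    b[paste0("within", k)] <- bk
    out[sel] <- Am[sel] + bk * D[sel]
  }
  dg <- diag(Gm) - 1; da <- diag(Am) - 1
  b["diag"] <- bfun(dg - da)
  diag(out) <- 1 + da + b["diag"] * (dg - da)
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  res <- blocked_relmat(out, m$n_A, m$n_B,
                        source = paste0(attr(G_star, "source"), "-regressed"),
                        n_loci = attr(G_star, "n_loci"), ids = attr(G_star, "ids"))
  attr(res, "b") <- b
  res
}

# bin index matrix for values under half-open edges (<e1, [e1,e2), ...)
.bin_cut <- function(M, edges) {
  matrix(findInterval(M, edges[-c(1, length(edges))], left.open = FALSE) + 1L,
         nrow(M), ncol(M))
}

#' Rescale marker relationships using the causal-locus regression
#'
#' Rescales marker-based relationships toward pedigree relationships using
#' the regression of causal-locus relationships on marker relationships,
#' `b = Cov(G_causal - A, G_markers - A) / Var(G_markers - A)`, computed
#' per bin: 11 within-population bins of pedigree relationships (< 0.05,
#' then 0.05 steps to 0.40, 0.40-0.50, > 0.50, and self-relationships) and
#' 3 between-population bins of genomic relationships (< -0.10, -0.10-0.10,
#' > 0.10). Entries become `A + b (G_markers - A)`. A bin with zero marker
#' variance reverts to A. This requires knowing the causal loci, so it is a
#' diagnostic: it tests whether bias arises because marker relationships
#' mispredict causal-locus relationships.
#'
#' @param G_markers Marker-based [blocked_relmat] (typically inbreeding
#'   rescaled).
#' @param G_causal Causal-locus [blocked_relmat] on the same individuals.
#' @param A Pedigree [blocked_relmat].
#' @return The rescaled [blocked_relmat]; attribute `b` holds per-bin
#'   coefficients.
#' @export
oracle_rescale <- function(G_markers, G_causal, A) {
  stopifnot(all(dim(G_markers) == dim(A)), all(dim(G_causal) == dim(A)))
  m <- .block_masks(G_markers)
  Gm <- unclass(G_markers); Gc <- unclass(G_causal); Am <- unclass(A)
  Dm <- Gm - Am; Dc <- Gc - Am
  bfun <- function(sel) {
    v <- .bin_var(Dm[sel])
    if (v <= 0) return(0)
    stats::cov(Dc[sel], Dm[sel]) / v
  }
  out <- Gm
  within <- m$AA | m$BB
  wedges <- c(-Inf, seq(0.05, 0.40, by = 0.05), 0.50, Inf)
  wbins <- .bin_cut(Am, wedges)
  b <- numeric(0)
  for (k in seq_len(length(wedges) - 1L)) {
    sel <- within & wbins == k
    bk <- bfun(sel)
    b[paste0("within", k)] <- bk
    out[sel] <- Am[sel] + bk * Dm[sel]
  }
  bedges <- c(-Inf, -0.10, 0.10, Inf)
  bbins <- .bin_cut(Gm, bedges)
  for (k in 1:3) {
    sel <- m$AB & bbins == k
    bk <- bfun(sel)
    b[paste0("between", k)] <- bk
    out[sel] <- Am[sel] + bk * Dm[sel]
  }
  dsel <- diag(nrow(Gm)) == 1
  bd <- {
    v <- .bin_var(Dm[dsel])
    if (v <= 0) 0 else stats::cov(Dc[dsel], Dm[dsel]) / v
  }
  b["self"] <- bd
  out[dsel] <- Am[dsel] + bd * Dm[dsel]
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  res <- blocked_relmat(out, m$n_A, m$n_B,
                        source = paste0(attr(G_markers, "source"), "-oracle"),
                        n_loci = attr(G_markers, "n_loci"),
                        ids = attr(G_markers, "ids"))
  attr(res, "b") <- b
  res
}

#' Block-wise regression of causal-locus on marker relationships
#'
#' For each off-diagonal block (within A, within B, between populations)
#' computes the least-squares slope of causal-locus relationships on marker
#' relationships and their Pearson correlation. A slope below 1 means that
#' marker relationships over-predict the relationships at the causal loci,
#' which biases variance-component estimates.
#'
#' @param G_causal,G_markers [blocked_relmat] objects on the same
#'   individuals.
#' @return Data frame with columns `block`, `slope`, `correlation`,
#'   `n_pairs`.
#' @export
block_regression_diagnostics <- function(G_causal, G_markers) {
  stopifnot(all(dim(G_causal) == dim(G_markers)))
  m <- .block_masks(G_markers)
  Gc <- unclass(G_causal); Gm <- unclass(G_markers)
  one <- function(sel, name) {
    x <- Gm[sel]; y <- Gc[sel]
    if (.bin_var(x) <= 0)
      return(data.frame(block = name, slope = NA_real_,
                        correlation = NA_real_, n_pairs = sum(sel)))
    data.frame(block = name, slope = stats::cov(y, x) / stats::var(x),
               correlation = stats::cor(y, x), n_pairs = sum(sel))
  }
  rbind(one(m$AA, "within_A"), one(m$BB, "within_B"), one(m$AB, "between"))
}

#' Minimal diagonal augmentation to positive definiteness
#'
#' Adds `max(0, tol - smallest eigenvalue)` to the diagonal so the matrix
#' can be used as a covariance structure in REML.
#'
#' @param G A symmetric matrix (e.g. [blocked_relmat]).
#' @param tol Target smallest eigenvalue (default `1e-6`).
#' @return The (possibly) augmented matrix; attribute `pd_epsilon` records
#'   the added ridge.
#' @export
make_positive_definite <- function(G, tol = 1e-6) {
  ok <- tryCatch({ chol(unclass(G)); TRUE }, error = function(e) FALSE)
  eps <- 0
  if (!ok) {
    ev <- min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values)
    eps <- max(0, tol - ev)
    G <- G + diag(eps, nrow(G))
  }
  attr(G, "pd_epsilon") <- eps
  G
}
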