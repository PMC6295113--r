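#' Sample correlated allele substitution effects
#'
#' For every causal locus, draws the pair of allele substitution effects
#' (one per population) from a bivariate normal distribution with mean 0,
#' standard deviation 1, and correlation `rho`. Effects are sampled
#' independently of allele frequency, so the realized genetic correlation
#' between populations is close to the effect correlation.
#'
#' @param n_causal Number of causal loci.
#' @param rho True correlation between the populations' effects, in
#'   `[-1, 1]`.
#' @return Numeric matrix `n_causal x 2` with columns `alpha_A`, `alpha_B`.
#' @export
sample_effects <- function(n_causal, rho) {
  stopifnot(n_causal >= 1, abs(rho) <= 1)
  a <- stats::rnorm(n_causal)
  b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n_causal)
  cbind(alpha_A = a, alpha_B = b)
}

#' Additive genetic values and phenotypes for one replicate
#'
#' Each individual's additive genetic value (AGV) is the sum over causal
#' loci of its allele count (0/1/2) times its own population's allele
#' substitution effect. AGVs are scaled jointly to mean 0 and variance 1
#' across all individuals of both populations. An independent normal
#' environmental deviation is added per individual, with the environmental
#' variance chosen per population from that population's realized AGV
#' variance so that the heritability is `h2` in each population:
#' `var_e,k = var_k(AGV) (1 - h2) / h2`. Phenotype = AGV + e.
#'
#' @param counts_A,counts_B Allele counts at the causal loci (individuals
#'   x loci).
#' @param effects Effect matrix from [sample_effects()] (columns
#'   `alpha_A`, `alpha_B`), rows aligned with the causal loci.
#' @param h2 Per-population heritability (default 0.3).
#' @return A list of class `trait_replicate` with `agv` (scaled AGVs, A
#'   individuals then B), `y` (phenotypes), `pop` (factor `"A"`/`"B"`),
#'   `effects`, `h2`.
#' @export
compute_agv_and_phenotypes <- function(counts_A, counts_B, effects, h2 = 0.3) {
  stopifnot(ncol(counts_A) == nrow(effects), ncol(counts_B) == nrow(effects),
            h2 > 0, h2 <= 1)
  agv <- c(counts_A %*% effects[, 1], counts_B %*% effects[, 2])
  if (stats::sd(agv) == 0)
    stop("zero genetic variance: all causal loci monomorphic or no effects")
  agv <- (agv - mean(agv)) / stats::sd(agv)
  pop <- factor(rep(c("A", "B"), c(nrow(counts_A), nrow(counts_B))))
  e <- numeric(length(agv))
  for (p in levels(pop)) {
    sel <- pop == p
    v <- stats::var(agv[sel])
    if (v == 0) stop("zero within-population genetic variance in ", p)
    e[sel] <- stats::rnorm(sum(sel), 0, sqrt(v * (1 - h2) / h2))
  }
  structure(list(agv = agv, y = agv + e, pop = pop, effects = effects,
                 h2 = h2), class = "trait_replicate")
}
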