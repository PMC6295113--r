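# popgencor

When does a genome-wide marker panel give an *unbiased* estimate of the
additive genetic correlation between two populations?

A single genotype can have different additive genetic values in two
populations (genotype-by-environment interaction, non-additive effects,
population-specific causal loci). The correlation between those two
values, the additive genetic correlation `r_g`, is estimated in practice
from a cross-population genomic relationship matrix (GRM) and a
bivariate GREML model:

    [y_A]   [X_A   0 ] [mu_A]   [a_A]   [e_A]
    [y_B] = [ 0   X_B] [mu_B] + [a_B] + [e_B],

    var(a) = [sigma2_A * G_AA   sigma_AB * G_AB]
             [sigma_AB * G_BA   sigma2_B * G_BB],   r_g = sigma_AB / (sigma_A sigma_B)

with the blocked GRM built from population-centered allele counts,
`G_AA = W_A W_A' / sum 2 p_Ai (1 - p_Ai)` and
`G_AB = W_A W_B' / sqrt(sum 2 p_Ai q_Ai) sqrt(sum 2 p_Bi q_Bi)`.
The estimate is unbiased when G is built at the causal loci; with
markers it is biased exactly when marker relationships mispredict the
relationships at causal loci — which happens when the allele-frequency
*difference* between the populations differs between markers and causal
loci, far more than through differences in LD phase.

`popgencor` is a tested simulation pipeline for studying this: a
two-population Wright–Fisher forward simulator with recombination,
recurrent mutation and pedigree recording; marker/causal-locus
ascertainment under allele-frequency criteria; LD-decay and LD-phase
consistency profiles; cross-population GRMs and pedigree relationship
matrices; shrinkage of G toward the pedigree
(`b = Var(G*-A)/(Var(G*-A)+1/n)` per relationship bin); a causal-informed
rescaling diagnostic; and a bivariate average-information REML estimator
with an unconstrained log-Cholesky parameterization.

## Worked example

```r
library(popgencor)

sched <- build_demography("desk", 0.4)   # two populations, reduced scale
harmonic_mean_Ne(sched)                  # 32.0 at this scale (~79 at full)

set.seed(7)
map <- genome_map(n_chr = 10, chr_len_M = 1, loci_per_chr = 30000)
sim <- run_simulation(sched, map, mutation_rate = 5e-5, seed = 11)

panel <- select_loci(sim$freq_A, sim$freq_B, "similar-similar",
                     marker_sizes = c(HDP = 6000, MDP = 1500, LDP = 400),
                     n_causal = 400)

cc <- list(A = allele_counts(sim$hap_A, panel$causal),
           B = allele_counts(sim$hap_B, panel$causal))
G_causal <- build_grm(cc$A, cc$B, source = "causal")
ml <- panel$markers$LDP
G_ldp <- build_grm(allele_counts(sim$hap_A, ml),
                   allele_counts(sim$hap_B, ml), source = "LDP")

block_regression_diagnostics(G_causal, G_ldp)
#>      block     slope correlation n_pairs
#> 1 within_A 0.7917679   0.8199255   79800
#> 2 within_B 0.8257056   0.8375443   79800
#> 3  between 0.6069402   0.6717340  160000

set.seed(42)
eff <- sample_effects(400, rho = 0.8)
tr <- compute_agv_and_phenotypes(cc$A, cc$B, eff, h2 = 0.3)
fit_bivariate_reml(tr$y, tr$pop, G_causal)
#> Bivariate GREML variance components
#>   sigma2_A = 0.1775  sigma2_B = 0.1952  sigma_AB = 0.1607
#>   sigma2_eA = 0.5199  sigma2_eB = 0.5011
#>   r_g = 0.8634  h2_A = 0.255  h2_B = 0.280  (converged, 7 iter)
fit_bivariate_reml(tr$y, tr$pop, G_ldp)
#> Bivariate GREML variance components
#>   sigma2_A = 0.0692  sigma2_B = 0.1644  sigma_AB = 0.0742
#>   sigma2_eA = 0.6074  sigma2_eB = 0.5112
#>   r_g = 0.6958  h2_A = 0.102  h2_B = 0.243  (converged, 10 iter)
```

The between-population slope of 0.61 says the sparse panel's
between-population relationships over-predict the relationships at the
causal loci; the REML estimate with that panel is attenuated toward
0.70 on this draw, while the causal-locus GRM stays near the simulated
0.8 (single draws carry sampling noise of roughly +-0.1 at this scale;
`run_study()` averages over replicates).

The full study — scenarios x panels x correlations x replicates, with
bias and standard-error summaries — is `run_study(study_config("desk"))`
and the numbered drivers under `analysis/` walk through it
(`01` simulation and spectra, `02` LD and relationship diagnostics,
`03` the bias tables, `04` the causal-informed rescaling).

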