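---
title: "Marker properties and the bias of genetic correlations estimated between populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker properties and the bias of genetic correlations estimated between populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single genotype can have different additive genetic values in two
populations, because allele substitution effects differ with genetic
background and environment. The correlation between those two additive
genetic values -- the additive genetic correlation between populations,
$r_g$ -- governs how much two populations can learn from each other in
genomic prediction and association studies. With genome-wide markers,
$r_g$ can be estimated from a cross-population genomic relationship
matrix (GRM) and a bivariate GREML model. The estimate is unbiased when
the GRM is built from the causal loci themselves; with markers it can be
biased, because marker-based relationships predict the relationships at
causal loci imperfectly.

`popgencor` implements the full simulation pipeline needed to study this
bias: a two-population Wright-Fisher forward simulator, ascertainment of
markers and causal loci under allele-frequency criteria, LD and
relationship diagnostics, the cross-population GRM, pedigree
relationships, shrinkage of the GRM toward the pedigree, and a bivariate
average-information REML estimator.

## Simulated populations

The demography (`build_demography()`) is, at full scale: a historical
population of 300 that declines linearly to 50 over 100 generations
(building LD through drift), recovers to 300, holds for 10 generations,
and expands to 1800 in its final generation. That cohort is split at
random into populations A and B (900 each), which grow to 1800, stay
separated for 40 generations, contract over 9 generations to 120
breeding individuals (20 males, 100 females), and produce 1000 analyzed
offspring each in generation 50. Generations are discrete; mating is
random with a 1:5 male:female ratio (`N_m = round(N/6)`); each dam
offers a fixed litter to a pool from which the next generation is drawn
uniformly without replacement, so selected-offspring counts are
approximately Poisson. The per-generation effective size is
$1/N_e = 1/(4N_m) + 1/(4N_f)$; the harmonic mean over the 211 historical
generations is ~79.

The genome is 10 chromosomes of 1 Morgan with 300,000 uniformly placed
loci each at full scale. Meiosis follows the Haldane model (Poisson
crossovers, no interference). Recurrent biallelic mutation (allele flip,
rate 5e-5 per locus per gamete) operates only in the historical
population; with the bottleneck it produces the U-shaped
allele-frequency spectrum of segregating loci expected at mutation-drift
equilibrium. Founder haplotypes start from Bernoulli(0.5) alleles, so
211 generations of drift and mutation shape the final spectrum.

The pedigree of the final 10 generations is recorded; its numerator
relationship matrix `A` (tabular method) has a zero between-population
block by construction, and pedigree inbreeding is `diag(A) - 1`.

## Markers and causal loci

Loci are ascertained per replicate under three criteria on the two
populations' allele frequencies: segregation, the absolute frequency
difference (threshold 0.14), and the relative difference in explained
variance $|2p_Aq_A - 2p_Bq_B| / (2\bar p \bar q)$ (thresholds 2 for
"similar", 1 for "different"). Markers additionally pass through 50
average-frequency bins of width 0.02 with equal sampling per bin, giving
the roughly uniform frequency spectrum of commercial SNP chips;
underfilled extreme bins merge with their neighbours and remaining
shortfalls are re-spread over bins with spare loci (water filling).
Panels are nested (LDP within MDP within HDP), subsampled per bin.
Causal loci come from the same criteria but need to segregate in only
one population, and are drawn without binning, so they keep the U-shaped
spectrum -- this marker/causal asymmetry (uniform vs U-shaped) is part
of the design, not an artifact.

## Trait and estimation

Allele substitution effect pairs are bivariate normal with unit variance
and correlation $\rho \in \{1, 0.8, 0.6, 0.4, 0.2, 0\}$, independent of
allele frequency. Additive genetic values (allele counts times own
population's effects, summed) are scaled to zero mean and unit variance
across all individuals jointly; environmental noise is added per
population from that population's realized AGV variance so each
population's heritability is exactly 0.3. (The joint scaling leaves the
within-population variance replicate-dependent, since part of the unit
variance is absorbed by the between-population AGV mean difference;
population means are fixed effects in the model, so this is harmless.)

The GRM centers allele counts by twice the population-specific
frequency; within-population blocks are the usual VanRaden form,
between-population entries are scaled by the geometric mean of the two
denominators and average approximately zero. Before shrinkage toward the
pedigree, the inbreeding level of G is rescaled per within-population
block via $G^* = (1-\bar F_k)G + 2\bar F_k J$; for the between block we
use the geometric-mean analog (coefficients
$\sqrt{(1-\bar F_A)(1-\bar F_B)}$ and $2\sqrt{\bar F_A \bar F_B}$),
which reduces to the same form when the means are equal -- the treatment
of the between block is an interpretation, since only the
within-population form is standard. Shrinkage uses
$b = Var(G^*-A)/(Var(G^*-A) + 1/n)$ per bin: four pedigree bins within
populations (<0.10, 0.10-0.25, 0.25-0.50, >0.50), one between bin, and
the inbreeding coefficients on the diagonal; an empty bin falls back to
the pooled within-population coefficient. The causal-informed rescaling
(`oracle_rescale()`) instead uses $b = Cov(G_c - A, G_m - A)/Var(G_m - A)$
on 11 within-population pedigree bins (including self-relationships) and
3 between-population genomic bins; it requires knowing the causal loci
and is used purely as a diagnostic. It is defined for the scenario where
markers and causal loci have matched frequency differences; in
mismatched scenarios the between-population marker variance within a bin
can be near zero and the coefficient unstable, so `run_study()` applies
it only there.

The bivariate GREML (`fit_bivariate_reml()`) maximizes the restricted
likelihood of the stacked two-population model with average-information
updates. The 2x2 genetic covariance matrix is parameterized by its
Cholesky factor with log-diagonal and residual variances by their logs,
so the parameter space is unconstrained and $|r_g| \le 1$ holds by
construction. Non-improving AI steps are handled by step halving plus
ridge damping of the AI matrix (serving the role EM fallback steps play
in other implementations); convergence is a change in restricted
log-likelihood below 1e-6, with a 200-iteration cap and a Nelder-Mead
fallback for tiny instances. Starting values are half the phenotypic
variance for genetic and residual components and zero covariance. A GRM
that fails a Cholesky check is repaired by the minimal diagonal ridge
`max(0, 1e-6 - smallest eigenvalue)`. Note one asymmetry of the
Cholesky parameterization: when an estimate sits at the $|r_g| = 1$
boundary the positive-semidefiniteness constraint binds through the
second population's genetic variance; which population is "second" is
arbitrary but fixed (B).

## The desk preset

Full-scale replication (3 million loci, 2 x 1800 individuals over 261
generations, 50 phenotype replicates) is not a workstation job, so the
package's default study (`study_config("desk")`) is a calibrated
reduction. Naive proportional scaling fails in ways that matter for this
particular study, so the desk preset was designed around preserving the
quantities the study actually measures:

* **Census scale 0.4.** All census sizes are multiplied by 0.4 (800
  analyzed individuals). Below this the allele-frequency spectrum at the
  reduced historical $N_e$ becomes far more extreme than the design's
  (at scale 0.25, 57% of causal loci have MAF < 0.05 against ~33% in
  the full design), which distorts every quantity that depends on the
  causal spectrum.
* **Drift-matched split length.** Keeping 50 post-split generations at
  reduced $N_e$ would quadruple the cumulative post-split drift
  $\sum 1/(2N_e)$, swamping the shared ancestral LD that creates
  between-population relationships. The constant-size phase is shortened
  to `round(42 * scale - 2)` generations (15 at scale 0.4) so the
  post-split drift matches the full design; the final 10
  pedigree/bottleneck generations are kept in full.
* **Mutation rate unchanged.** Raising the mutation rate to recover
  segregating loci was rejected: recurrent mutation decouples
  identity-by-state from identity-by-descent along the deep pre-split
  branches and measurably destroys the between-population relationship
  signal.
* **Panels 6,000 / 1,500 / 400 markers, 400 causal loci.** Sized to the
  ~15-18k similar-qualifying loci available per desk replicate, keeping
  roughly the full design's margin between panel size and qualifying
  loci. The low-density panel keeps the role of the 2,000-marker panel:
  its ratio of true between-population relationship variance to marker
  sampling noise (which sets the shrinkage coefficient b and the
  attenuation of between-population relationships) is approximately
  preserved because relationship variance grows as census sizes shrink
  while sampling noise grows as marker counts shrink.
* **10 replicates, correlations 0.8 and 0.4**, against 50 replicates and
  six correlations at full scale.

What the desk preset does *not* preserve: the between-population block
has far fewer effective ancestral segments, so single-replicate
diagnostics (regression slopes of causal on marker relationships between
populations) fluctuate strongly across replicates and are reported as
means over replicates; the "different-different" scenario is infeasible
(only ~1-2k different-qualifying loci exist, fewer than any marker
panel); and per-cell standard errors are several times the full-scale
ones, so bias percentages carry sampling noise of a few points. The
mismatched-scenario between-population slope is also intrinsically
scale-dependent (its denominator, the marker relationship variance, is
much larger at desk scale), so its desk value sits well below the
full-scale one even though the qualitative contrast with the matched
scenario is preserved.

Passing desk-scale tests shows the machinery reproduces the design's
mechanisms at a calibrated reduction; it does not certify full-scale
magnitudes, nor behavior on real livestock data (real genomes have
uneven recombination, selection, and overlapping generations, all
excluded here).

## Problem sizes used by tests and scripts

The packaged study (tests and the acceptance script) runs the desk
preset: 10 replicates, 300,000 loci, 800 analyzed individuals, 14-16
REML fits per replicate; about 10-15 minutes on one core. Unit tests use
much smaller instances (tens of individuals, hundreds of loci) built in
code. The REML parameter-recovery check uses 400 individuals per
population over 20 simulated replicates against 3 Monte-Carlo standard
errors.

## Known limitations

* Estimates at the $|r_g| = 1$ boundary are clipped rather than profiled;
  cells whose true correlation is near 1 therefore inherit slight
  downward clipping bias at small sample sizes.
* When causal loci are population-specific (mismatched scenario), the
  causal-locus GRM's between block can carry almost no information at
  desk scale and the causal-panel estimate is then boundary-dominated;
  the full-scale design does not have this problem.
* The simulator is haploid-locus biallelic with fixed litter sizes and
  discrete generations; it is a study instrument, not a general breeding
  simulator.
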