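test_that("identical homozygous parents breed identical offspring", {
  map <- tiny_map(1, 50)
  hap <- as_hap(matrix(1, 50, 4))  # two individuals, all-1 haplotypes
  parents <- list(hap = hap, sex = c(1L, 2L))
  off <- breed_generation(parents, n_off = 6, n_off_m = 1, litter = 10,
                          map = map, mutation_rate = 0)
  expect_equal(dim(off$hap), c(50L, 12L))
  expect_true(all(as.integer(off$hap) == 1L))
  expect_true(all(off$sire == 1L))
  expect_true(all(off$dam == 2L))
})

test_that("recombination and mutation rates match their expectations", {
  set.seed(42)
  L <- 2000
  map <- tiny_map(1, L, chr_len_M = 1)
  # sire haplotypes all-0/all-0, dam all-1/all-1: offspring maternal gamete
  # is all 1 (no mutation), paternal all 0, so allele counts are exactly 1
  hap <- as_hap(cbind(matrix(0, L, 2), matrix(1, L, 2)))
  parents <- list(hap = hap, sex = c(1L, 2L))
  off <- breed_generation(parents, 200, 30, litter = 200, map = map,
                          mutation_rate = 0)
  expect_true(all(allele_counts(off$hap, 1:L) == 1L))

  # crossover count: parent with distinguishable haplotypes (0s and 1s);
  # switches along the gamete = crossovers; mean should be ~ 1 per Morgan
  hap2 <- as_hap(cbind(matrix(0, L, 1), matrix(1, L, 1),
                       matrix(0, L, 1), matrix(1, L, 1)))
  parents2 <- list(hap = hap2, sex = c(1L, 2L))
  off2 <- breed_generation(parents2, 400, 60, litter = 400, map = map,
                           mutation_rate = 0)
  gam <- matrix(as.integer(off2$hap), L)
  switches <- colSums(abs(apply(gam, 2, diff)))
  expect_equal(mean(switches), 1, tolerance = 0.1)

  # mutation count per gamete ~ Binomial(L, mu)
  off3 <- breed_generation(parents, 300, 40, litter = 300, map = map,
                           mutation_rate = 0.005)
  cnts <- allele_counts(off3$hap, 1:L)
  flips <- sum(cnts != 1L)  # each deviation from 1 is one flipped allele
  expect_equal(flips / (2 * 300), L * 0.005, tolerance = 0.15)
})

test_that("offspring demand beyond the dam pool is rejected", {
  map <- tiny_map(1, 10)
  parents <- list(hap = as_hap(matrix(0, 10, 4)), sex = c(1L, 2L))
  expect_error(breed_generation(parents, n_off = 30, litter = 10, map = map),
               "pool")
})

test_that("simulation is deterministic under a fixed seed and tracks freqs", {
  sched <- build_demography("desk", 0.1, n_constant = 2)
  set.seed(3)
  map <- genome_map(n_chr = 2, chr_len_M = 0.5, loci_per_chr = 300)
  sim1 <- run_simulation(sched, map, mutation_rate = 1e-3, seed = 9)
  sim2 <- run_simulation(sched, map, mutation_rate = 1e-3, seed = 9)
  expect_identical(sim1$hap_A, sim2$hap_A)
  expect_identical(sim1$freq_B, sim2$freq_B)
  expect_true(all(sim1$freq_A >= 0 & sim1$freq_A <= 1))
  # frequencies recomputed from haplotypes agree
  expect_equal(sim1$freq_A, allele_freq(sim1$hap_A))
  # pedigree covers the last 10 generations, founders unknown
  ped <- sim1$pedigree
  gmax <- max(ped$generation)
  expect_setequal(unique(ped$generation), (gmax - 9):gmax)
  founders <- ped[ped$generation == gmax - 9, ]
  expect_true(all(founders$sire == 0 & founders$dam == 0))
  later <- ped[ped$generation > gmax - 9, ]
  expect_true(all(later$sire != 0 & later$dam != 0))
  # parents precede offspring and sires are male, dams female
  sex_of <- stats::setNames(ped$sex, ped$id)
  expect_true(all(sex_of[as.character(later$sire)] == 1L))
  expect_true(all(sex_of[as.character(later$dam)] == 2L))
})

test_that("loci fixed after mutation stops stay fixed through the split", {
  sched <- build_demography("desk", 0.1, n_constant = 2)
  set.seed(4)
  map <- genome_map(n_chr = 1, chr_len_M = 0.5, loci_per_chr = 400)
  sim <- run_simulation(sched, map, mutation_rate = 0, seed = 5)
  # with zero mutation everywhere, founders at Bernoulli(0.5) drift and fix;
  # any locus monomorphic in A and B for different alleles is impossible
  # only if it segregated at the split -- here we just check codes stay 0/1
  expect_true(all(sim$freq_A >= 0 & sim$freq_A <= 1))
  both_fixed_same <- sim$freq_A %in% c(0, 1) & sim$freq_A == sim$freq_B
  expect_gt(mean(both_fixed_same), 0.4)  # heavy fixation without mutation
})

test_that("allele frequency drift is centred on zero over one generation", {
  set.seed(11)
  L <- 3000
  map <- tiny_map(1, L)
  p0 <- runif(L, 0.2, 0.8)
  hap <- as_hap(matrix(rbinom(L * 120, 1, rep(p0, 120)), L, 120))
  parents <- list(hap = hap, sex = rep(c(1L, 2L), c(10, 50)))
  off <- breed_generation(parents, 60, 10, litter = 10, map = map,
                          mutation_rate = 0)
  drift <- allele_freq(off$hap) - allele_freq(hap)
  expect_lt(abs(mean(drift)), 0.005)
})
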