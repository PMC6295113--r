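test_that("similar-frequency criteria follow the three printed rules", {
  # hand-evaluated: |0.3-0.4| = 0.10 < 0.14; variance ratio
  # |0.42-0.48|/0.455 = 0.132 < 2
  expect_true(criterion_similar(0.30, 0.40))
  # |0.5-0.7| = 0.20 >= 0.14
  expect_false(criterion_similar(0.50, 0.70))
  # not segregating in B
  expect_false(criterion_similar(0.50, 0.00))
  # relaxed segregation admits population-specific loci within thresholds
  expect_true(criterion_similar(0.05, 0.00, relax_segregation = TRUE))
  expect_false(criterion_similar(0.05, 0.00))
  expect_error(criterion_similar(-0.1, 0.5))
})

test_that("different-frequency criteria follow the three printed rules", {
  # hand-evaluated: |0.05-0.5| = 0.45 > 0.14; ratio 0.405/0.399 = 1.016 > 1
  expect_true(criterion_different(0.05, 0.50))
  expect_false(criterion_different(0.30, 0.40))  # diff 0.10 <= 0.14
  expect_false(criterion_different(0.00, 0.00))  # monomorphic everywhere
  # segregating in one population only, large difference
  expect_true(criterion_different(0.00, 0.60))
})

test_that("criteria partition loci and selections re-check cleanly", {
  set.seed(21)
  pA <- runif(5000); pB <- pmin(1, pmax(0, pA + rnorm(5000, 0, 0.12)))
  sim <- criterion_similar(pA, pB)
  dif <- criterion_different(pA, pB)
  expect_false(any(sim & dif))  # |pA-pB| thresholds make them disjoint
  expect_true(all(abs(pA[sim] - pB[sim]) < 0.14))
  expect_true(all(abs(pA[dif] - pB[dif]) > 0.14))
})

test_that("marker panels are nested, disjoint from causal, and re-checkable", {
  set.seed(8)
  n <- 20000
  # U-shaped candidates: mixture of uniform and edge-concentrated freqs
  pA <- c(runif(n / 2), rbeta(n / 2, 0.2, 0.2))
  pB <- pmin(1, pmax(0, pA + rnorm(n, 0, 0.05)))
  panel <- select_loci(pA, pB, "similar-similar",
                       marker_sizes = c(HDP = 400, MDP = 100, LDP = 20),
                       n_causal = 50)
  m <- panel$markers
  expect_length(m$HDP, 400)
  expect_true(all(m$MDP %in% m$HDP))
  expect_true(all(m$LDP %in% m$MDP))
  expect_length(intersect(panel$causal, m$HDP), 0)
  expect_true(all(criterion_similar(pA[m$HDP], pB[m$HDP])))
  expect_true(all(criterion_similar(pA[panel$causal], pB[panel$causal],
                                    relax_segregation = TRUE)))
  # nesting contract at minimal sizes
  small <- select_markers(c(.1, .2, .3, .4, .5, .6, .7, .8),
                          c(.1, .2, .3, .4, .5, .6, .7, .8),
                          "similar", sizes = c(4, 2, 1))
  expect_length(small[[1]], 4)
  expect_true(small[[3]] %in% small[[2]] && all(small[[2]] %in% small[[1]]))
})

test_that("binned ascertainment flattens a U-shaped spectrum", {
  set.seed(9)
  n <- 60000
  pA <- rbeta(n, 0.35, 0.35)
  pB <- pmin(1, pmax(0, pA + rnorm(n, 0, 0.04)))
  mk <- select_markers(pA, pB, "similar", sizes = c(HDP = 5000))$HDP
  pbar <- (pA[mk] + pB[mk]) / 2
  counts <- table(cut(pbar, seq(0, 1, by = 0.02)))
  # approximately uniform: no bin deviates grossly from the quota
  expect_lt(max(counts) / (5000 / 50), 2)
  expect_gt(min(counts) / (5000 / 50), 0.3)
  # chi-square uniformity not rejected at alpha = 0.01 is too strict for a
  # water-filled panel; instead require far flatter than the source
  src <- table(cut((pA + pB) / 2, seq(0, 1, by = 0.02)))
  expect_lt(stats::var(as.numeric(counts)) / mean(counts)^2,
            0.25 * stats::var(as.numeric(src)) / mean(src)^2)
})

test_that("causal selection keeps the U-shape and rejects shortages", {
  set.seed(10)
  n <- 20000
  pA <- rbeta(n, 0.25, 0.25)
  pB <- pmin(1, pmax(0, pA + rnorm(n, 0, 0.04)))
  keep <- (pA > 0 & pA < 1) | (pB > 0 & pB < 1)
  cz <- select_causal(pA, pB, "similar", n = 2000)
  # no binning: rare loci remain over-represented relative to uniform
  maf <- pmin(pA[cz], 1 - pA[cz])
  expect_gt(mean(maf < 0.05), 0.10)
  expect_length(select_causal(pA, pB, "similar", n = 0), 0)
  expect_error(select_causal(c(0.3, 0.35), c(0.3, 0.35), "similar", n = 5),
               "insufficient")
  expect_error(select_markers(rep(0, 50), rep(0, 50), "similar",
                              sizes = c(10)), "insufficient")
})
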