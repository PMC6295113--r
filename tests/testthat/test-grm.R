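test_that("build_grm matches the hand-evaluated one-locus case", {
  # one locus, p_A = 0.5: centered counts {1, -1}; s_A = 0.5
  G <- build_grm(matrix(c(2L, 0L), 2, 1), matrix(c(1L, 1L), 2, 1),
                 p_A = 0.5, p_B = 0.5)
  expect_equal(unclass(G)[1:2, 1:2], matrix(c(2, -2, -2, 2), 2))
  # B individuals both heterozygous: centered counts 0, all relationships 0
  expect_equal(unclass(G)[3:4, ], matrix(0, 2, 4))
})

test_that("build_grm equals brute-force per-entry sums on a small instance", {
  set.seed(40)
  co <- random_cohort(10, 50, p = runif(50, 0.1, 0.9))
  G <- build_grm(co$A, co$B)
  pA <- colMeans(co$A) / 2; pB <- colMeans(co$B) / 2
  WA <- sweep(co$A, 2, 2 * pA); WB <- sweep(co$B, 2, 2 * pB)
  sA <- sum(2 * pA * (1 - pA)); sB <- sum(2 * pB * (1 - pB))
  brute <- matrix(NA_real_, 20, 20)
  W <- rbind(WA, WB)
  den <- function(i, j) {
    if (i <= 10 && j <= 10) sA
    else if (i > 10 && j > 10) sB
    else sqrt(sA * sB)
  }
  for (i in 1:20) for (j in 1:20)
    brute[i, j] <- sum(W[i, ] * W[j, ]) / den(i, j)
  expect_equal(unclass(G), brute, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(G)))
})

test_that("within-population block reproduces the VanRaden form", {
  set.seed(41)
  co <- random_cohort(12, 80, p = runif(80, 0.1, 0.9))
  G <- build_grm(co$A, co$B)
  pA <- colMeans(co$A) / 2
  W <- sweep(co$A, 2, 2 * pA)
  vr <- tcrossprod(W) / sum(2 * pA * (1 - pA))
  expect_equal(unclass(G)[1:12, 1:12], vr, tolerance = 1e-12)
  # population-specific centering: mean between-population entry ~ 0
  expect_lt(abs(mean(unclass(G)[1:12, 13:24])), 0.05)
})

test_that("loci monomorphic in one population contribute zeros there", {
  cA <- cbind(c(0L, 0L, 0L), c(0L, 1L, 2L))  # locus 1 monomorphic in A
  cB <- cbind(c(0L, 1L, 2L), c(2L, 2L, 2L))  # locus 2 monomorphic in B
  G <- build_grm(cA, cB)
  expect_true(all(is.finite(unclass(G))))
  expect_error(build_grm(cbind(c(0L, 0L)), cbind(c(2L, 2L))), "monomorphic")
})

test_that("inbreeding rescaling matches its closed form", {
  set.seed(42)
  co <- random_cohort(6, 40)
  G <- build_grm(co$A, co$B)
  expect_equal(unclass(rescale_inbreeding(G, 0, 0)), unclass(G),
               ignore_attr = TRUE)
  Gs <- rescale_inbreeding(G, 0.5, 0.5)
  # an entry g = 0 becomes 0.5*0 + 2*0.5*1 = 1
  expect_equal(unclass(Gs)[1, 2], 0.5 * unclass(G)[1, 2] + 1)
  Gs2 <- rescale_inbreeding(G, 0.1, 0.1)
  expect_equal(unclass(Gs2)[1, 1], 0.9 * unclass(G)[1, 1] + 0.2)
  # between block with equal means uses the same form
  expect_equal(unclass(Gs2)[1, 7], 0.9 * unclass(G)[1, 7] + 0.2)
  expect_error(rescale_inbreeding(G, 1, 0.2))
})

test_that("regression toward A has the correct endpoints and coefficients", {
  set.seed(43)
  co <- random_cohort(15, 60)
  G <- build_grm(co$A, co$B)
  A <- blocked_relmat(diag(30), 15, 15, source = "pedigree")
  # Var = 0 in a bin reverts entries to A: G == A everywhere gives A back
  same <- regress_to_A(A, A, n_markers = 100)
  expect_equal(unclass(same), unclass(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  # large n: b -> Var/(Var + ~0) ~ 1, Ghat ~ G*
  big <- regress_to_A(G, A, n_markers = 1e12)
  expect_equal(unclass(big), unclass(G), tolerance = 1e-3,
               ignore_attr = TRUE)
  # Var(G*-A) = 1/n gives b = 0.5 for the between bin
  d <- unclass(G) - unclass(A)
  v_btw <- var(d[1:15, 16:30][lower.tri(matrix(0, 15, 15)) | TRUE])
  v_btw <- var(as.vector(d[1:15, 16:30]))
  r <- regress_to_A(G, A, n_markers = 1 / v_btw)
  expect_equal(unname(attr(r, "b")["between"]), 0.5, tolerance = 1e-6)
  expect_true(isSymmetric(unclass(r)))
})

test_that("oracle rescaling is exact in its degenerate cases", {
  set.seed(44)
  co <- random_cohort(12, 80)
  G <- build_grm(co$A, co$B)
  A <- blocked_relmat(diag(24), 12, 12, source = "pedigree")
  # markers identical to causal loci: every b = 1, output = G
  self <- oracle_rescale(G, G, A)
  expect_equal(unclass(self), unclass(G), tolerance = 1e-10,
               ignore_attr = TRUE)
  # markers carry no signal (G_markers = A): output reverts to A
  none <- oracle_rescale(A, G, A)
  expect_equal(unclass(none), unclass(A), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("block regression diagnostics recover known structure", {
  set.seed(45)
  co <- random_cohort(14, 90)
  G <- build_grm(co$A, co$B)
  d <- block_regression_diagnostics(G, G)
  expect_equal(d$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(d$correlation, rep(1, 3), tolerance = 1e-12)
  # against a constant matrix the regression is undefined
  K <- blocked_relmat(matrix(1, 28, 28), 14, 14)
  expect_true(all(is.na(block_regression_diagnostics(G, K)$slope)))
  # halving the matrix doubles the slope
  H <- blocked_relmat(unclass(G) / 2, 14, 14)
  expect_equal(block_regression_diagnostics(G, H)$slope, rep(2, 3),
               tolerance = 1e-12)
})

test_that("positive-definite repair augments only when needed", {
  ok <- diag(3)
  expect_equal(attr(make_positive_definite(ok), "pd_epsilon"), 0)
  bad <- matrix(1, 3, 3)  # rank 1, eigenvalues {3, 0, 0}
  fixed <- make_positive_definite(bad)
  expect_gt(attr(fixed, "pd_epsilon"), 0)
  expect_no_error(chol(unclass(fixed) + diag(1e-10, 3)))
})
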