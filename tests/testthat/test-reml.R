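# Independent restricted-likelihood evaluator used as the oracle: textbook
# matrix form, written directly from the model definition.
oracle_remlik <- function(y, X, G, pop, s2A, s2B, sAB, seA, seB) {
  S <- matrix(c(s2A, sAB, sAB, s2B), 2)
  if (min(eigen(S, only.values = TRUE)$values) < 0) return(-Inf)
  iA <- pop == "A"
  V <- matrix(0, length(y), length(y))
  V[iA, iA] <- s2A * unclass(G)[iA, iA]
  V[!iA, !iA] <- s2B * unclass(G)[!iA, !iA]
  V[iA, !iA] <- sAB * unclass(G)[iA, !iA]
  V[!iA, iA] <- sAB * unclass(G)[!iA, iA]
  diag(V) <- diag(V) + ifelse(iA, seA, seB)
  if (min(eigen(V, only.values = TRUE)$values) <= 0) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

test_that("REML optimum agrees with a grid-search oracle on a toy instance", {
  set.seed(60)
  n <- 6
  pop <- rep(c("A", "B"), each = 3)
  G <- structured_G(3, 3, k = 2, ridge = 0.5)
  y <- simulate_from_G(G, pop, 1, 1, 0.5, 1, 1)
  X <- cbind(as.numeric(pop == "A"), as.numeric(pop == "B"))
  fit <- fit_bivariate_reml(y, pop, G, method = "nm")
  ll_fit <- oracle_remlik(y, X, G, pop, fit$sigma2_A, fit$sigma2_B,
                          fit$sigma_AB, fit$sigma2_eA, fit$sigma2_eB)
  expect_equal(ll_fit, fit$loglik, tolerance = 1e-6)
  # coarse grid over the 5 parameters around the optimum
  grid_best <- -Inf
  gv <- function(x) x * c(0.5, 0.75, 1, 1.5, 2)
  for (a in gv(fit$sigma2_A)) for (b in gv(fit$sigma2_B))
    for (cc in fit$sigma_AB + c(-0.4, -0.2, 0, 0.2, 0.4))
      for (ea in gv(fit$sigma2_eA)) for (eb in gv(fit$sigma2_eB)) {
        ll <- oracle_remlik(y, X, G, pop, a, b, cc, ea, eb)
        grid_best <- max(grid_best, ll)
      }
  expect_gte(fit$loglik + 1e-6, grid_best)
})

test_that("AI and Nelder-Mead optimizers find the same optimum", {
  set.seed(61)
  pop <- rep(c("A", "B"), each = 25)
  G <- structured_G(25, 25)
  y <- simulate_from_G(G, pop, 0.4, 0.5, 0.3, 0.6, 0.7)
  f1 <- fit_bivariate_reml(y, pop, G, method = "ai")
  f2 <- fit_bivariate_reml(y, pop, G, method = "nm")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$r_g, f2$r_g, tolerance = 0.02)
  expect_true(f1$converged)
})

test_that("parameters are recovered on self-simulated data", {
  set.seed(62)
  n <- 400
  pop <- rep(c("A", "B"), each = n)
  G <- structured_G(n, n, k = 30, ridge = 0.4)
  truth <- list(s2A = 0.3, s2B = 0.3, sAB = 0.15, seA = 0.7, seB = 0.7)
  reps <- 20
  est <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("s2A", "sAB", "rg", "h2A")))
  for (r in seq_len(reps)) {
    y <- simulate_from_G(G, pop, truth$s2A, truth$s2B, truth$sAB,
                         truth$seA, truth$seB, mu = c(1, -1))
    f <- fit_bivariate_reml(y, pop, G)
    est[r, ] <- c(f$sigma2_A, f$sigma_AB, f$r_g, f$h2_A)
  }
  mce <- apply(est, 2, sd) / sqrt(reps)
  true_rg <- truth$sAB / sqrt(truth$s2A * truth$s2B)
  expect_lt(abs(mean(est[, "s2A"]) - truth$s2A), 3 * mce["s2A"])
  expect_lt(abs(mean(est[, "sAB"]) - truth$sAB), 3 * mce["sAB"])
  expect_lt(abs(mean(est[, "rg"]) - true_rg), 3 * mce["rg"])
  expect_lt(abs(mean(est[, "h2A"]) - 0.3), 3 * mce["h2A"])
})

test_that("restricted likelihood is invariant to shifting one population", {
  set.seed(63)
  pop <- rep(c("A", "B"), each = 20)
  G <- structured_G(20, 20)
  y <- simulate_from_G(G, pop, 0.5, 0.5, 0.2, 0.5, 0.5)
  f1 <- fit_bivariate_reml(y, pop, G)
  y2 <- y + ifelse(pop == "A", 100, 0)
  f2 <- fit_bivariate_reml(y2, pop, G)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$r_g, f2$r_g, tolerance = 1e-3)
})

test_that("genetic correlation helper clips and handles degeneracy", {
  expect_equal(genetic_correlation(list(sigma2_A = 1, sigma2_B = 0.64,
                                        sigma_AB = 0.4)), 0.5)
  expect_equal(genetic_correlation(list(sigma2_A = 1, sigma2_B = 1,
                                        sigma_AB = 0)), 0)
  expect_equal(genetic_correlation(list(sigma2_A = 1, sigma2_B = 1,
                                        sigma_AB = 1.2)), 1)
  expect_true(is.na(genetic_correlation(list(sigma2_A = 0, sigma2_B = 1,
                                             sigma_AB = 0))))
  expect_error(fit_bivariate_reml(rep(1, 10), rep(c("A", "B"), each = 5),
                                  structured_G(5, 5)), "zero variance")
})
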