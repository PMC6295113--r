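#' Bivariate GREML for the genetic correlation between two populations
#'
#' Fits the stacked bivariate mixed model `y = X mu + a + e`, where each
#' individual is phenotyped in exactly one population, the fixed effects
#' are the two population means, the additive genetic values have
#' covariance `[[sigma2_A G_AA, sigma_AB G_AB], [sigma_AB G_BA,
#' sigma2_B G_BB]]` for a blocked relationship matrix G, and the residuals
#' are independent with a separate variance per population. Variance
#' components are estimated by restricted maximum likelihood using
#' average-information (AI) updates on an unconstrained parameterization:
#' the 2x2 genetic covariance matrix is expressed through its Cholesky
#' factor with log-diagonal (so it stays positive semi-definite and
#' `|r_g| <= 1` by construction) and the residual variances through their
#' logs. Non-improving AI steps are safeguarded by step halving and ridge
#' damping of the AI matrix; a derivative-free Nelder-Mead optimizer over
#' the same parameterization is available for tiny instances.
#'
#' @param y Numeric phenotype vector, population A individuals first.
#' @param pop Factor/character of `"A"`/`"B"` aligned with `y`.
#' @param G A [blocked_relmat] on the same individuals (made positive
#'   definite with [make_positive_definite] if needed).
#' @param method `"ai"` (default) or `"nm"` (Nelder-Mead).
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-6`).
#' @param max_iter Maximum number of iterations (default 200).
#' @param start Optional list with starting values `sigma2_A`, `sigma2_B`,
#'   `sigma_AB`, `sigma2_eA`, `sigma2_eB`.
#' @return A list of class `vc_estimate`: the five variance components,
#'   `r_g` (genetic correlation, clipped to `[-1, 1]`), `h2_A`, `h2_B`
#'   (genomic heritabilities), `loglik`, `iterations`, `converged`.
#' @export
fit_bivariate_reml <- function(y, pop, G, method = c("ai", "nm"),
                               tol = 1e-6, max_iter = 200, start = NULL) {
  method <- match.arg(method)
  pop <- factor(pop, levels = c("A", "B"))
  n <- length(y)
  stopifnot(nrow(G) == n, all(table(pop) > 0))
  if (stats::sd(y) == 0) stop("phenotypes have zero variance")
  iA <- pop == "A"; iB <- pop == "B"
  if (any(which(iA) > min(which(iB))))
    stop("individuals must be ordered population A first")

  Gm <- unclass(make_positive_definite(G))
  X <- cbind(A = as.numeric(iA), B = as.numeric(iB))
  # base covariance structures: genetic AA / AB+BA / BB, residual A / B
  C <- vector("list", 5)
  Z <- matrix(0, n, n)
  C[[1]] <- Z; C[[1]][iA, iA] <- Gm[iA, iA]
  C[[2]] <- Z; C[[2]][iA, iB] <- Gm[iA, iB]; C[[2]][iB, iA] <- Gm[iB, iA]
  C[[3]] <- Z; C[[3]][iB, iB] <- Gm[iB, iB]
  C[[4]] <- diag(as.numeric(iA)); C[[5]] <- diag(as.numeric(iB))

  sig_of_theta <- function(th) {
    l1 <- th[1]; l2 <- th[2]; l3 <- th[3]
    c(exp(2 * l1), exp(l1) * l2, l2^2 + exp(2 * l3),
      exp(2 * th[4]), exp(2 * th[5]))
  }
  jac <- function(th) {
    l1 <- th[1]; l2 <- th[2]; l3 <- th[3]
    J <- matrix(0, 5, 5)  # d sigma_j / d theta_k
    J[1, 1] <- 2 * exp(2 * l1)
    J[2, 1] <- exp(l1) * l2; J[2, 2] <- exp(l1)
    J[3, 2] <- 2 * l2;       J[3, 3] <- 2 * exp(2 * l3)
    J[4, 4] <- 2 * exp(2 * th[4])
    J[5, 5] <- 2 * exp(2 * th[5])
    J
  }

  vmat <- function(sig) {
    V <- sig[1] * C[[1]] + sig[2] * C[[2]] + sig[3] * C[[3]]
    diag(V) <- diag(V) + sig[4] * as.numeric(iA) + sig[5] * as.numeric(iB)
    V
  }
  # restricted log-likelihood and the pieces needed for scores
  eval_ll <- function(th, full = FALSE) {
    sig <- sig_of_theta(th)
    V <- vmat(sig)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(if (full) NULL else -Inf)
    Vinv <- chol2inv(ch)
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    cx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cx)) return(if (full) NULL else -Inf)
    XtVXi <- chol2inv(cx)
    alpha <- XtVXi %*% crossprod(W, y)
    Py <- Vinv %*% y - W %*% alpha
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) +
                  sum(y * Py))
    if (!full) return(ll)
    list(ll = ll, Vinv = Vinv, W = W, XtVXi = XtVXi, Py = Py, sig = sig)
  }

  v0 <- function(x) max(stats::var(x), 1e-8)
  th <- if (is.null(start)) {
    c(0.5 * log(0.5 * v0(y[iA])), 0, 0.5 * log(0.5 * v0(y[iB])),
      0.5 * log(0.5 * v0(y[iA])), 0.5 * log(0.5 * v0(y[iB])))
  } else {
    l1 <- 0.5 * log(start$sigma2_A)
    l2 <- start$sigma_AB / exp(l1)
    l3 <- 0.5 * log(max(start$sigma2_B - l2^2, 1e-8))
    c(l1, l2, l3, 0.5 * log(start$sigma2_eA), 0.5 * log(start$sigma2_eB))
  }

  conv <- FALSE; iter <- 0L
  if (method == "nm") {
    op <- stats::optim(th, function(t) -eval_ll(t), method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    th <- op$par; ll <- -op$value; conv <- op$convergence == 0
    iter <- as.integer(op$counts[1])
  } else {
    st <- eval_ll(th, full = TRUE)
    if (is.null(st)) stop("starting covariance matrix not positive definite")
    ll <- st$ll
    for (iter in seq_len(max_iter)) {
      Py <- st$Py; Vinv <- st$Vinv; W <- st$W; XtVXi <- st$XtVXi
      u <- lapply(C, function(Ck) Ck %*% Py)
      Pu <- lapply(u, function(uk)
        Vinv %*% uk - W %*% (XtVXi %*% crossprod(W, uk)))
      sc_sig <- numeric(5); AI <- matrix(0, 5, 5)
      for (j in 1:5) {
        trPC <- sum(Vinv * C[[j]]) -
          sum(XtVXi * crossprod(W, C[[j]] %*% W))
        sc_sig[j] <- -0.5 * (trPC - sum(Py * u[[j]]))
        for (k in j:5) {
          AI[j, k] <- AI[k, j] <- 0.5 * sum(u[[j]] * Pu[[k]])
        }
      }
      J <- jac(th)
      sc <- drop(crossprod(J, sc_sig))
      AIt <- crossprod(J, AI %*% J)
      ridge <- 1e-8 * mean(diag(AIt))
      step_ok <- FALSE
      for (damp in 0:8) {
        delta <- tryCatch(solve(AIt + diag(ridge * 10^damp, 5), sc),
                          error = function(e) NULL)
        if (is.null(delta)) next
        fac <- 1
        for (h in 0:12) {
          cand <- th + fac * delta
          st2 <- eval_ll(cand, full = TRUE)
          if (!is.null(st2) && is.finite(st2$ll) && st2$ll >= ll - 1e-10) {
            step_ok <- TRUE; break
          }
          fac <- fac / 2
        }
        if (step_ok) break
      }
      if (!step_ok) break
      dll <- st2$ll - ll
      th <- cand; ll <- st2$ll; st <- st2
      if (abs(dll) < tol) { conv <- TRUE; break }
    }
  }

  sig <- sig_of_theta(th)
  rg <- if (sig[1] > 0 && sig[3] > 0)
    sig[2] / sqrt(sig[1] * sig[3]) else NA_real_
  out <- list(sigma2_A = sig[1], sigma2_B = sig[3], sigma_AB = sig[2],
              sigma2_eA = sig[4], sigma2_eB = sig[5],
              r_g = if (is.na(rg)) NA_real_ else max(-1, min(1, rg)),
              h2_A = sig[1] / (sig[1] + sig[4]),
              h2_B = sig[3] / (sig[3] + sig[5]),
              loglik = ll, iterations = iter, converged = conv)
  class(out) <- "vc_estimate"
  out
}

#' Genetic correlation from a variance-component estimate
#'
#' `r_g = sigma_AB / sqrt(sigma2_A sigma2_B)`, clipped to `[-1, 1]`.
#' Undefined (NA) if either genetic variance is zero.
#'
#' @param vc A `vc_estimate` (or list with `sigma2_A`, `sigma2_B`,
#'   `sigma_AB`).
#' @return The genetic correlation.
#' @export
genetic_correlation <- function(vc) {
  if (vc$sigma2_A <= 0 || vc$sigma2_B <= 0) return(NA_real_)
  max(-1, min(1, vc$sigma_AB / sqrt(vc$sigma2_A * vc$sigma2_B)))
}

#' @export
print.vc_estimate <- function(x, ...) {
  cat("Bivariate GREML variance components\n")
  cat(sprintf("  sigma2_A = %.4f  sigma2_B = %.4f  sigma_AB = %.4f\n",
              x$sigma2_A, x$sigma2_B, x$sigma_AB))
  cat(sprintf("  sigma2_eA = %.4f  sigma2_eB = %.4f\n",
              x$sigma2_eA, x$sigma2_eB))
  cat(sprintf("  r_g = %.4f  h2_A = %.3f  h2_B = %.3f  (%s, %d iter)\n",
              x$r_g, x$h2_A, x$h2_B,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
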