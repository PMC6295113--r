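#' Study configuration
#'
#' Bundles the design of a simulation study: scenarios x marker panels x
#' true genetic correlations x replicates. The `full` preset mirrors the
#' study design (full-size populations, 10 chromosomes x 300,000 loci,
#' panels 200,000 / 20,000 / 2,000, 2,000 causal loci, 50 replicates, six
#' correlations); the `desk` preset is a reduction for tractable runs
#' (population sizes x 0.4, a drift-matched shorter split, 10 chromosomes
#' x 30,000 loci, panels 6,000 / 1,500 / 400, 400 causal loci, 10
#' replicates, correlations 0.8 and 0.4). The desk scaling is chosen to
#' preserve the quantities the study measures: the allele-frequency
#' spectrum shape, the post-split drift and LD-phase consistency, and the
#' balance between true relationship variance and marker sampling error
#' that governs the regression coefficients toward pedigree
#' relationships; see the methods vignette.
#'
#' @param preset `"desk"` or `"full"`.
#' @param scenarios Scenario tags (see [select_loci]).
#' @param panels Relationship sources to fit: subset of `"causal"`,
#'   `"HDP"`, `"MDP"`, `"LDP"`.
#' @param rhos True genetic correlations to simulate.
#' @param n_reps Number of replicates.
#' @param regression Regression modes to fit: subset of `"none"`,
#'   `"regress-to-A"`, `"oracle-rescale"` (the latter two apply to marker
#'   panels only).
#' @param h2 Per-population heritability.
#' @param seed Master seed; per-replicate and per-stage seeds derive from
#'   it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(preset = c("desk", "full"),
                         scenarios = c("similar-similar", "similar-different"),
                         panels = c("causal", "HDP", "MDP", "LDP"),
                         rhos = NULL, n_reps = NULL,
                         regression = "none", h2 = 0.3, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "full") {
    cfg <- list(scale = 1, loci_per_chr = 300000,
                marker_sizes = c(HDP = 200000, MDP = 20000, LDP = 2000),
                n_causal = 2000,
                rhos = if (is.null(rhos)) c(1, 0.8, 0.6, 0.4, 0.2, 0) else rhos,
                n_reps = if (is.null(n_reps)) 50 else n_reps)
  } else {
    cfg <- list(scale = 0.4, loci_per_chr = 30000,
                marker_sizes = c(HDP = 6000, MDP = 1500, LDP = 400),
                n_causal = 400,
                rhos = if (is.null(rhos)) c(0.8, 0.4) else rhos,
                n_reps = if (is.null(n_reps)) 10 else n_reps)
  }
  cfg$mutation_rate <- 5e-5
  cfg$preset <- preset
  cfg$scenarios <- scenarios
  cfg$panels <- panels
  cfg$regression <- regression
  cfg$h2 <- h2
  cfg$seed <- seed
  class(cfg) <- "study_config"
  cfg
}

# deterministic per-replicate/per-stage seed below 2^31
.stage_seed <- function(master, rep, stage) {
  (abs(master) %% 1000003L) * 2017L + rep * 1009L + stage * 97L + 1L
}

#' Run the simulation study
#'
#' For every replicate: simulate the two populations forward in time,
#' build the pedigree relationship matrix, and for every scenario select
#' markers and causal loci and build the genomic relationship matrices;
#' then for every true correlation simulate effects and phenotypes (shared
#' across panels) and fit the bivariate GREML for every requested panel
#' and regression mode. Optionally records, per replicate and scenario,
#' the block-wise regression diagnostics of causal-locus on marker
#' relationships, the shrinkage coefficients of the regression toward the
#' pedigree, and the rare-allele fractions of the selected loci.
#'
#' @param config A [study_config()].
#' @param diagnostics Record relationship diagnostics (default `TRUE`).
#' @param verbose Print progress.
#' @return A list of class `study_result`: `estimates` (one row per fit),
#'   `diagnostics`, `regression_b`, `panel_maf`, `failures` (replicates
#'   that errored, with messages; summaries cover the successful ones),
#'   `config`.
#' @export
run_study <- function(config, diagnostics = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  est <- list(); diag_rows <- list(); b_rows <- list(); maf_rows <- list()
  failures <- list()
  sched <- build_demography(if (config$scale == 1) "full" else "desk",
                            config$scale)
  marker_only <- setdiff(config$panels, "causal")
  for (rep in seq_len(config$n_reps)) {
    if (verbose) message("replicate ", rep)
    rep_ok <- tryCatch({
    set.seed(.stage_seed(config$seed, rep, 1L))
    map <- genome_map(n_chr = 10, chr_len_M = 1,
                      loci_per_chr = config$loci_per_chr)
    sim <- run_simulation(sched, map, mutation_rate = config$mutation_rate,
                          seed = .stage_seed(config$seed, rep, 2L))
    A <- build_pedigree_A(sim$pedigree)
    fbar <- attr(A, "F_bar")
    for (sc in config$scenarios) {
      set.seed(.stage_seed(config$seed, rep, 3L + match(sc, config$scenarios)))
      panel <- select_loci(sim$freq_A, sim$freq_B, scenario = sc,
                           marker_sizes = config$marker_sizes,
                           n_causal = config$n_causal)
      counts <- list()
      loci_of <- c(list(causal = panel$causal), panel$markers)
      for (pn in unique(c("causal", config$panels))) {
        counts[[pn]] <- list(A = allele_counts(sim$hap_A, loci_of[[pn]]),
                             B = allele_counts(sim$hap_B, loci_of[[pn]]))
      }
      G <- lapply(unique(c("causal", config$panels)), function(pn)
        build_grm(counts[[pn]]$A, counts[[pn]]$B, source = pn))
      names(G) <- unique(c("causal", config$panels))

      Gfit <- list()
      for (mode in config$regression) {
        # the causal-informed rescaling is defined for the scenario with
        # matched marker/causal frequency differences; elsewhere the
        # between-population bins can have near-zero marker variance
        if (mode == "oracle-rescale" && sc != "similar-similar") next
        for (pn in config$panels) {
          if (mode != "none" && pn == "causal") next
          Gfit[[paste(mode, pn)]] <- switch(
            mode,
            "none" = G[[pn]],
            "regress-to-A" = {
              gs <- rescale_inbreeding(G[[pn]], fbar["A"], fbar["B"])
              regress_to_A(gs, A)
            },
            "oracle-rescale" = {
              gs <- rescale_inbreeding(G[[pn]], fbar["A"], fbar["B"])
              oracle_rescale(gs, G$causal, A)
            })
        }
      }
      if (diagnostics) {
        for (pn in marker_only) {
          d <- block_regression_diagnostics(G$causal, G[[pn]])
          d$scenario <- sc; d$panel <- pn; d$rep <- rep
          diag_rows[[length(diag_rows) + 1L]] <- d
          gs <- rescale_inbreeding(G[[pn]], fbar["A"], fbar["B"])
          b <- attr(regress_to_A(gs, A), "b")
          b_rows[[length(b_rows) + 1L]] <- data.frame(
            scenario = sc, panel = pn, rep = rep,
            bin = names(b), b = as.numeric(b))
        }
        for (pn in names(loci_of)) {
          maf_rows[[length(maf_rows) + 1L]] <- data.frame(
            scenario = sc, panel = pn, rep = rep,
            frac_maf_lt_05 = maf_below(panel, loci_of[[pn]]))
        }
      }
      for (rho in config$rhos) {
        set.seed(.stage_seed(config$seed, rep,
                             100L + match(sc, config$scenarios) * 10L +
                               match(rho, config$rhos)))
        eff <- sample_effects(config$n_causal, rho)
        tr <- compute_agv_and_phenotypes(counts$causal$A, counts$causal$B,
                                         eff, h2 = config$h2)
        for (nm in names(Gfit)) {
          fit <- fit_bivariate_reml(tr$y, tr$pop, Gfit[[nm]])
          parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
          est[[length(est) + 1L]] <- data.frame(
            scenario = sc, panel = parts[2], regression = parts[1],
            rho = rho, rep = rep, r_g = fit$r_g,
            h2_A = fit$h2_A, h2_B = fit$h2_B,
            sigma2_A = fit$sigma2_A, sigma2_B = fit$sigma2_B,
            sigma_AB = fit$sigma_AB, converged = fit$converged)
        }
      }
      }
      rm(sim, A); gc(FALSE)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(rep_ok)) {
      warning("replicate ", rep, " failed: ", rep_ok)
      failures[[length(failures) + 1L]] <- data.frame(rep = rep,
                                                     error = rep_ok)
    }
  }
  structure(list(
    estimates = do.call(rbind, est),
    diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows) else NULL,
    regression_b = if (length(b_rows)) do.call(rbind, b_rows) else NULL,
    panel_maf = if (length(maf_rows)) do.call(rbind, maf_rows) else NULL,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    config = config), class = "study_result")
}

#' Mean, standard error, and relative bias of replicate estimates
#'
#' Relative bias is `100 (rho - mean) / rho` percent, defined only for
#' `rho != 0` (the absolute bias is reported in `bias_abs` regardless).
#' The SEM is the standard deviation across replicates divided by the
#' square root of the number of replicates (NA for a single replicate).
#'
#' @param estimates Numeric vector of per-replicate estimates.
#' @param rho True simulated value.
#' @return Data frame with `mean`, `sem`, `bias_abs`, `bias_pct`, `n`.
#' @export
bias_summary <- function(estimates, rho) {
  estimates <- estimates[!is.na(estimates)]
  n <- length(estimates)
  m <- mean(estimates)
  sem <- if (n >= 2) stats::sd(estimates) / sqrt(n) else NA_real_
  data.frame(mean = m, sem = sem, bias_abs = rho - m,
             bias_pct = if (rho != 0) 100 * (rho - m) / rho else NA_real_,
             n = n)
}

#' Summarize a study result per design cell
#'
#' One row per scenario x panel x regression x rho with the mean estimated
#' genetic correlation, its SEM over replicates, the relative bias, and
#' mean genomic heritabilities.
#'
#' @param study A `study_result` from [run_study()].
#' @return Data frame of cell summaries.
#' @export
summarize_study <- function(study) {
  e <- study$estimates
  key <- interaction(e$scenario, e$panel, e$regression, e$rho, drop = TRUE)
  out <- do.call(rbind, lapply(split(e, key), function(d) {
    s <- bias_summary(d$r_g, d$rho[1])
    data.frame(scenario = d$scenario[1], panel = d$panel[1],
               regression = d$regression[1], rho = d$rho[1],
               mean_r_g = s$mean, sem = s$sem, bias_pct = s$bias_pct,
               mean_h2_A = mean(d$h2_A), mean_h2_B = mean(d$h2_B),
               n_reps = s$n)
  }))
  rownames(out) <- NULL
  out[order(out$scenario, out$panel, out$regression, -out$rho), ]
}

#' Mean relative bias over non-zero correlations for one cell
#'
#' Averages the per-rho relative bias of the mean estimate across the
#' non-zero true correlations of a study, for one scenario / panel /
#' regression mode. This is the "underestimated by x percent" summary.
#'
#' @param study A `study_result`.
#' @param scenario,panel,regression Cell selectors.
#' @return Mean relative bias in percent.
#' @export
mean_relative_bias <- function(study, scenario, panel, regression = "none") {
  s <- summarize_study(study)
  s <- s[s$scenario == scenario & s$panel == panel &
           s$regression == regression & s$rho != 0, ]
  if (nrow(s) == 0) return(NA_real_)
  mean(s$bias_pct)
}
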