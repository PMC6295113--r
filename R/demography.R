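#' Demography schedule for the two-population simulation
#'
#' Builds the per-generation census sizes of the simulated populations: a
#' historical population run for 211 generations (generations -211 to -1)
#' with a bottleneck to create linkage disequilibrium, followed by a random
#' split into two populations A and B kept apart for 50 generations. Sizes
#' ramp linearly between the stated endpoints, rounded to the nearest
#' integer. The sex ratio is 1 male : 5 females throughout (males =
#' round(N/6)).
#'
#' The full preset follows the study design: the historical population
#' starts at 300, declines to 50 at generation -112, recovers to 300 at
#' generation -12, stays at 300 through generation -2, and expands to 1800
#' in generation -1. That cohort is split into two populations of 900
#' (generation 0), which grow to 1800 (generations 1-40), decline to 120
#' breeding individuals by generation 49, and produce an analyzed cohort of
#' 1000 per population in generation 50. The `desk` preset multiplies all
#' census sizes by `scale_factor` (minimum size 20) for tractable runs.
#'
#' The desk preset also shortens the constant-size phase after the split
#' (`n_constant` generations instead of 40) so that the cumulative
#' post-split drift, sum of 1/(2 Ne) over post-split generations, matches
#' the full design under the reduced census sizes. Without this the
#' reduced populations accumulate about four times the full design's
#' population-specific drift and LD, which destroys the between-population
#' relationship structure the study measures. The 10 final generations
#' (bottleneck ramp to 120 x scale breeding individuals plus the analyzed
#' cohort), which carry the recorded pedigree, are kept in full.
#'
#' @param preset `"full"` or `"desk"`.
#' @param scale_factor Multiplier in (0, 1] applied to all census sizes
#'   under the `desk` preset; must be 1 for `full`.
#' @param n_constant Number of constant-size generations between the split
#'   and the final 10-generation bottleneck phase. Defaults to 40 for
#'   `full` and to the drift-matched `round(42 * scale_factor - 2)` for
#'   `desk`.
#' @return A data frame of class `demography_schedule` with columns
#'   `generation`, `pop` (`"HIST"`, `"A"`, `"B"`), `N`, `N_m`, `N_f`, and
#'   `litter` (offspring per dam when this cohort breeds).
#' @examples
#' sched <- build_demography("desk", 0.25)
#' head(sched)
#' @export
build_demography <- function(preset = c("full", "desk"), scale_factor = 1,
                             n_constant = NULL) {
  preset <- match.arg(preset)
  if (is.null(n_constant)) {
    # desk: shorten the constant phase so the cumulative post-split drift
    # sum 1/(2 Ne) matches the full design under the scaled census sizes:
    # 1/(1000 s) + k/(2000 s) = 1/1000 + 40/2000  =>  k = 42 s - 2
    n_constant <- if (preset == "full") 40L
                  else max(2L, as.integer(round(42 * scale_factor - 2)))
  }
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0, scale_factor <= 1)
  if (preset == "full" && scale_factor != 1)
    stop("the full preset uses scale_factor = 1")

  ramp <- function(g, g0, g1, n0, n1) {
    round(n0 + (n1 - n0) * (g - g0) / (g1 - g0))
  }
  hist_n <- function(g) {
    ifelse(g <= -112, ramp(g, -211, -112, 300, 50),
    ifelse(g <= -12,  ramp(g, -112, -12, 50, 300),
    ifelse(g <= -2,   300, 1800)))
  }
  g_hist <- -211:-1
  hist_df <- data.frame(generation = g_hist, pop = "HIST",
                        N = hist_n(g_hist), litter = 10L)

  # split populations: 900 at gen 0, 1800 during the constant phase, then a
  # 9-generation ramp to 120 breeding individuals and 1000 analyzed
  # offspring in the final generation (full preset: generations 41-50)
  g_last <- n_constant + 10
  g_pop <- 0:g_last
  pop_n <- ifelse(g_pop == 0, 900,
           ifelse(g_pop <= n_constant, 1800,
           ifelse(g_pop <= g_last - 1,
                  ramp(g_pop, n_constant, g_last - 1, 1800, 120), 1000)))
  pop_litter <- ifelse(g_pop <= n_constant - 1, 10L, 20L)
  pop_df <- rbind(
    data.frame(generation = g_pop, pop = "A", N = pop_n, litter = pop_litter),
    data.frame(generation = g_pop, pop = "B", N = pop_n, litter = pop_litter)
  )

  sched <- rbind(hist_df, pop_df)
  if (preset == "desk") {
    sched$N <- pmax(20L, as.integer(round(sched$N * scale_factor)))
  }
  sched$N <- as.integer(sched$N)
  sched$N_m <- as.integer(round(sched$N / 6))
  sched$N_f <- sched$N - sched$N_m
  if (any(sched$N_m < 1L))
    stop("scale_factor too small: fewer than one male in some generation")
  sched <- sched[, c("generation", "pop", "N", "N_m", "N_f", "litter")]
  class(sched) <- c("demography_schedule", "data.frame")
  attr(sched, "preset") <- preset
  attr(sched, "scale_factor") <- scale_factor
  sched
}

#' Per-generation effective population size
#'
#' Effective size of one generation under unequal sex numbers:
#' 1/Ne = 1/(4 Nm) + 1/(4 Nf).
#'
#' @param N_m Number of breeding males (>= 1).
#' @param N_f Number of breeding females (>= 1).
#' @return The effective size, 4 Nm Nf / (Nm + Nf).
#' @examples
#' effective_size(50, 250)   # ~166.7
#' effective_size(100, 100)  # 200, equal sexes give Ne = 2N
#' @export
effective_size <- function(N_m, N_f) {
  stopifnot(all(N_m >= 1), all(N_f >= 1))
  1 / (1 / (4 * N_m) + 1 / (4 * N_f))
}

#' Harmonic-mean effective size of the historical population
#'
#' The effective size of a population whose census size changes over time is
#' approximated by the harmonic mean of the per-generation effective sizes.
#' Applied to the historical generations (-211 to -1) of a demography
#' schedule; the bottleneck generations dominate the harmonic mean.
#'
#' @param schedule A `demography_schedule` (or compatible data frame with
#'   columns `pop`, `N_m`, `N_f`, `generation`).
#' @return The harmonic mean of per-generation Ne over the historical
#'   generations.
#' @export
harmonic_mean_Ne <- function(schedule) {
  h <- schedule[schedule$pop == "HIST", , drop = FALSE]
  if (nrow(h) == 0L) stop("schedule contains no historical generations")
  ne <- effective_size(h$N_m, h$N_f)
  nrow(h) / sum(1 / ne)
}
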