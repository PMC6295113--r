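#' Selection criteria on per-population allele frequencies
#'
#' Loci are selected to have either similar or different allele frequencies
#' in the two populations, using three criteria: (1) segregation, (2) the
#' absolute allele-frequency difference, and (3) the relative difference in
#' the variance explained by the locus, `|2pA(1-pA) - 2pB(1-pB)| /
#' (2 pbar (1 - pbar))` with `pbar = (pA + pB)/2`. The third criterion
#' mainly screens low-frequency loci, where a small frequency difference
#' can imply a large difference in explained variance.
#'
#' `criterion_similar`: segregating in both populations, `|pA - pB| < 0.14`,
#' and variance ratio `< 2`. `criterion_different`: segregating in at least
#' one population, `|pA - pB| > 0.14`, and variance ratio `> 1`.
#' `relax_segregation = TRUE` (used for causal loci in every scenario)
#' replaces the both-populations segregation requirement of the similar
#' criteria with segregation in at least one population.
#'
#' @param p_A,p_B Allele-1 frequencies, each in `[0, 1]` (vectorized).
#' @param relax_segregation Require segregation in only one population.
#' @return Logical vector.
#' @export
criterion_similar <- function(p_A, p_B, relax_segregation = FALSE) {
  stopifnot(all(p_A >= 0 & p_A <= 1), all(p_B >= 0 & p_B <= 1))
  seg <- if (relax_segregation)
    (p_A > 0 & p_A < 1) | (p_B > 0 & p_B < 1)
  else
    (p_A > 0 & p_A < 1) & (p_B > 0 & p_B < 1)
  pbar <- (p_A + p_B) / 2
  denom <- 2 * pbar * (1 - pbar)
  ratio <- ifelse(denom > 0,
                  abs(2 * p_A * (1 - p_A) - 2 * p_B * (1 - p_B)) / denom, Inf)
  seg & abs(p_A - p_B) < 0.14 & ratio < 2
}

#' @rdname criterion_similar
#' @export
criterion_different <- function(p_A, p_B) {
  stopifnot(all(p_A >= 0 & p_A <= 1), all(p_B >= 0 & p_B <= 1))
  seg <- (p_A > 0 & p_A < 1) | (p_B > 0 & p_B < 1)
  pbar <- (p_A + p_B) / 2
  denom <- 2 * pbar * (1 - pbar)
  ratio <- ifelse(denom > 0,
                  abs(2 * p_A * (1 - p_A) - 2 * p_B * (1 - p_B)) / denom, 0)
  seg & abs(p_A - p_B) > 0.14 & ratio > 1
}

# Sample `total` loci from `idx`, aiming at equal numbers per 0.02-wide bin
# of pbar. Underfilled extreme bins are merged with their neighbour; any
# remaining shortfall is reallocated proportionally across bins that still
# have loci (water-filling), which keeps the selected spectrum as uniform
# as the candidates allow.
.sample_uniform_bins <- function(idx, pbar, total, n_bins = 50) {
  if (total == 0) return(integer(0))
  if (length(idx) < total)
    stop("insufficient qualifying loci: need ", total, ", have ", length(idx))
  bin <- pmin(floor(pbar * n_bins), n_bins - 1L) + 1L
  groups <- split(idx, factor(bin, levels = seq_len(n_bins)))
  quota <- rep(total / n_bins, n_bins)
  # merge underfilled extreme bins into their neighbours
  sizes <- lengths(groups)
  if (sizes[1] < quota[1]) {
    groups[[2]] <- c(groups[[1]], groups[[2]])
    quota[2] <- quota[2] + quota[1]
    groups[[1]] <- integer(0); quota[1] <- 0
  }
  if (sizes[n_bins] < quota[n_bins]) {
    groups[[n_bins - 1L]] <- c(groups[[n_bins - 1L]], groups[[n_bins]])
    quota[n_bins - 1L] <- quota[n_bins - 1L] + quota[n_bins]
    groups[[n_bins]] <- integer(0); quota[n_bins] <- 0
  }
  cap <- lengths(groups)
  take <- pmin(cap, quota)
  # redistribute shortfall over bins with remaining capacity (water-fill)
  repeat {
    deficit <- total - sum(take)
    room <- cap - take
    if (deficit < 1e-9 || sum(room) <= 1e-12) break
    add <- pmin(room, deficit * room / sum(room))
    if (sum(add) < 1e-12) break
    take <- take + add
  }
  ti <- as.integer(floor(take + 1e-9))
  short <- total - sum(ti)
  if (short > 0) {  # hand out the last units by largest fractional part
    frac <- take - ti
    cand <- order(-frac, -(cap - ti))
    cand <- cand[cap[cand] - ti[cand] > 0]
    bump <- utils::head(cand, short)
    ti[bump] <- ti[bump] + 1L
    if (length(bump) < short)
      stop("insufficient qualifying loci after binning")
  }
  take <- ti
  sel <- unlist(lapply(seq_len(n_bins), function(b) {
    g <- groups[[b]]
    if (take[b] == 0) integer(0)
    else if (length(g) == 1 && take[b] == 1) g
    else sample(g, take[b])
  }), use.names = FALSE)
  sort(sel)
}

#' Select nested marker panels under an allele-frequency scenario
#'
#' Markers must satisfy the scenario's criteria ([criterion_similar] or
#' [criterion_different]); qualifying loci are binned by their average
#' allele frequency over the two populations into 50 bins of width 0.02
#' and an (approximately) equal number is sampled per bin, so the selected
#' panel has a roughly uniform allele-frequency distribution, as on
#' commercial marker chips. The medium and low density panels are nested
#' subsets, subsampled per bin from their parent panel to preserve
#' uniformity.
#'
#' @param p_A,p_B Allele-1 frequencies of all candidate loci.
#' @param scenario `"similar"` or `"different"` (marker criteria).
#' @param sizes Named or unnamed vector of nested panel sizes, largest
#'   first (e.g. `c(HDP = 20000, MDP = 2000, LDP = 400)`).
#' @return Named list of sorted locus index vectors, one per panel,
#'   each a subset of the previous.
#' @export
select_markers <- function(p_A, p_B, scenario = c("similar", "different"),
                           sizes = c(HDP = 200000, MDP = 20000, LDP = 2000)) {
  scenario <- match.arg(scenario)
  stopifnot(length(sizes) >= 1, all(diff(sizes) < 0))
  ok <- if (scenario == "similar") criterion_similar(p_A, p_B)
        else criterion_different(p_A, p_B)
  pbar <- (p_A + p_B) / 2
  if (is.null(names(sizes)))
    names(sizes) <- paste0("panel", seq_along(sizes))
  panels <- list()
  idx <- which(ok)
  for (k in seq_along(sizes)) {
    idx <- .sample_uniform_bins(idx, pbar[idx], sizes[k])
    panels[[names(sizes)[k]]] <- idx
  }
  panels
}

#' Select causal loci under an allele-frequency scenario
#'
#' Causal loci use the same criteria and cut-offs as markers except that
#' segregation is required in only one population in every scenario (some
#' causal loci are population-specific). They are sampled uniformly from
#' the qualifying loci -- no frequency binning -- so their allele
#' frequencies keep the U-shaped spectrum of segregating loci.
#'
#' @param p_A,p_B Allele-1 frequencies of all candidate loci.
#' @param scenario `"similar"` or `"different"` (causal-locus criteria).
#' @param n Number of causal loci.
#' @param exclude Locus indices unavailable for selection (the markers).
#' @return Sorted vector of causal locus indices.
#' @export
select_causal <- function(p_A, p_B, scenario = c("similar", "different"),
                          n = 2000, exclude = integer(0)) {
  scenario <- match.arg(scenario)
  if (n == 0) return(integer(0))
  ok <- if (scenario == "similar")
    criterion_similar(p_A, p_B, relax_segregation = TRUE)
  else criterion_different(p_A, p_B)
  idx <- setdiff(which(ok), exclude)
  if (length(idx) < n)
    stop("insufficient qualifying causal candidates: need ", n,
         ", have ", length(idx))
  sort(sample(idx, n))
}

#' Select markers and causal loci for one study scenario
#'
#' Combines [select_markers] and [select_causal] for the three study
#' scenarios: `"similar-similar"` (markers and causal loci both with
#' similar frequencies in the two populations), `"similar-different"`
#' (markers similar, causal loci different), and `"different-different"`.
#'
#' @param p_A,p_B Allele-1 frequencies of all candidate loci.
#' @param scenario Scenario tag.
#' @param marker_sizes Nested marker panel sizes, largest first.
#' @param n_causal Number of causal loci.
#' @return A list of class `locus_panel` with `markers` (named list of
#'   nested index vectors), `causal`, `scenario`, `p_A`, `p_B`.
#' @export
select_loci <- function(p_A, p_B,
                        scenario = c("similar-similar", "similar-different",
                                     "different-different"),
                        marker_sizes = c(HDP = 200000, MDP = 20000, LDP = 2000),
                        n_causal = 2000) {
  scenario <- match.arg(scenario)
  parts <- strsplit(scenario, "-", fixed = TRUE)[[1]]
  markers <- select_markers(p_A, p_B, parts[1], marker_sizes)
  causal <- select_causal(p_A, p_B, parts[2], n_causal,
                          exclude = markers[[1]])
  structure(list(markers = markers, causal = causal, scenario = scenario,
                 p_A = p_A, p_B = p_B), class = "locus_panel")
}

#' Fraction of loci with minor allele frequency below a threshold
#'
#' Averaged over the two populations; the minor allele frequency is
#' `min(p, 1-p)` per population.
#'
#' @param panel A `locus_panel`.
#' @param loci Locus indices (e.g. `panel$causal` or a marker panel).
#' @param threshold MAF threshold (default 0.05).
#' @return Mean over populations of the fraction of `loci` with MAF below
#'   `threshold`.
#' @export
maf_below <- function(panel, loci, threshold = 0.05) {
  mafA <- pmin(panel$p_A[loci], 1 - panel$p_A[loci])
  mafB <- pmin(panel$p_B[loci], 1 - panel$p_B[loci])
  mean(c(mean(mafA < threshold), mean(mafB < threshold)))
}
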