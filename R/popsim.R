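#' Breed one discrete generation
#'
#' Produces an offspring cohort from a parental haplotype panel under random
#' mating with a 1:5 male:female ratio. Every dam contributes `litter`
#' candidate offspring to a pool; the next generation is drawn uniformly
#' without replacement from that pool, so the number of selected offspring
#' per parent is approximately Poisson, as in the Wright-Fisher model. Each
#' candidate receives a uniformly drawn sire. Gametes recombine under the
#' Haldane model (Poisson number of crossovers per chromosome with mean
#' equal to its length in Morgan, uniform crossover positions, random start
#' haplotype) and then mutate recurrently (allele flip) at `mutation_rate`
#' per locus per gamete.
#'
#' @param parents A list with `hap` (raw matrix, loci x haplotypes;
#'   individual j owns columns 2j-1 and 2j) and `sex` (integer vector,
#'   1 = male, 2 = female).
#' @param n_off Number of offspring to produce.
#' @param n_off_m Number of males among the offspring (sexes assigned at
#'   random); defaults to `round(n_off/6)`.
#' @param litter Candidate offspring per dam.
#' @param map A [genome_map()].
#' @param mutation_rate Per-locus per-gamete allele flip probability.
#' @return A list with `hap` (offspring haplotypes), `sex`, `sire`, `dam`
#'   (1-based indices into the parental cohort).
#' @export
breed_generation <- function(parents, n_off, n_off_m = round(n_off / 6),
                             litter = 10, map, mutation_rate = 0) {
  stopifnot(mutation_rate >= 0, n_off >= 1)
  males <- which(parents$sex == 1L)
  dams <- which(parents$sex == 2L)
  if (length(males) < 1L || length(dams) < 1L)
    stop("need at least one male and one female parent")
  pool <- rep(dams, each = litter)
  if (length(pool) < n_off)
    stop("offspring demand exceeds the dam x litter pool (",
         length(pool), " < ", n_off, ")")
  dam_idx <- sample(pool, n_off, replace = FALSE)
  sire_idx <- sample(males, n_off, replace = TRUE)
  hap <- .breed_cpp(parents$hap, sire_idx - 1L, dam_idx - 1L,
                    map$chr_start, map$chr_len_M, map$pos_M, mutation_rate)
  sex <- sample(rep(c(1L, 2L), c(n_off_m, n_off - n_off_m)))
  list(hap = hap, sex = sex, sire = sire_idx, dam = dam_idx)
}

#' Allele-1 frequency at every locus of a haplotype panel
#'
#' @param hap Raw haplotype matrix (loci x haplotypes).
#' @return Numeric vector of allele-1 frequencies in `[0, 1]`.
#' @export
allele_freq <- function(hap) .hap_freq_cpp(hap)

#' Allele counts for selected loci
#'
#' @param hap Raw haplotype matrix.
#' @param loci 1-based locus indices.
#' @return Integer matrix, individuals x loci, entries 0/1/2.
#' @export
allele_counts <- function(hap, loci) .geno_cpp(hap, as.integer(loci))

#' Phased alleles for selected loci
#'
#' @param hap Raw haplotype matrix.
#' @param loci 1-based locus indices.
#' @return Integer matrix, haplotypes x loci, entries 0/1.
#' @export
hap_alleles <- function(hap, loci) .hap_subset_cpp(hap, as.integer(loci))

# breed through a run of schedule rows for one population, recording
# pedigree for generations >= ped_from. `cohort` is the generation at
# rows$generation[1] - 1 state.
.breed_through <- function(cohort, rows, map, mutation_rate, pop,
                           ped_from, id_offset = 0L) {
  ped <- list()
  next_id <- id_offset
  ids <- rep(0L, length(cohort$sex))  # 0 = not in pedigree
  for (r in seq_len(nrow(rows))) {
    g <- rows$generation[r]
    off <- breed_generation(cohort, n_off = rows$N[r], n_off_m = rows$N_m[r],
                            litter = cohort$litter, map = map,
                            mutation_rate = mutation_rate)
    off$litter <- rows$litter[r]
    if (g >= ped_from) {
      off_ids <- next_id + seq_len(rows$N[r])
      next_id <- next_id + rows$N[r]
      ped[[length(ped) + 1L]] <- data.frame(
        id = off_ids,
        sire = ids[off$sire],
        dam = ids[off$dam],
        generation = g, population = pop, sex = off$sex)
      ids <- off_ids
    }
    cohort <- off
    rm(off); gc(FALSE)
  }
  cohort$ids <- ids
  list(cohort = cohort, pedigree = do.call(rbind, ped), next_id = next_id)
}

#' Run the full two-population forward simulation
#'
#' Simulates the historical population from generation -211 (founder
#' haplotypes drawn Bernoulli(0.5), so mutation-drift over 211 generations
#' shapes the final spectrum), splits the last historical cohort randomly
#' into populations A and B, and breeds each forward to generation 50.
#' Recurrent mutation operates only while producing historical generations
#' and is stopped afterwards. The pedigree of generations 41-50 is
#' recorded, with generation-41 individuals as founders (unknown parents).
#'
#' @param schedule A [build_demography()] schedule.
#' @param map A [genome_map()].
#' @param mutation_rate Per-locus per-gamete mutation probability in the
#'   historical population (default 0.00005).
#' @param seed Optional integer seed (applied via `set.seed`).
#' @return A list of class `popsim_result` with `hap_A`, `hap_B` (raw
#'   haplotype matrices of the generation-50 cohorts), `freq_A`, `freq_B`
#'   (allele-1 frequencies in those cohorts), `pedigree` (generations
#'   41-50, both populations; unknown parents coded 0), `map`, `schedule`.
#' @export
run_simulation <- function(schedule, map, mutation_rate = 0.00005,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hist <- schedule[schedule$pop == "HIST", , drop = FALSE]
  if (nrow(hist) == 0L) stop("schedule has no historical generations")
  hist <- hist[order(hist$generation), , drop = FALSE]

  # founders at generation -211
  n0 <- hist$N[1]
  L <- map$n_loci
  hap <- matrix(as.raw(stats::rbinom(L * 2 * n0, 1L, 0.5)), nrow = L)
  cohort <- list(hap = hap,
                 sex = sample(rep(c(1L, 2L), c(hist$N_m[1], hist$N_f[1]))),
                 litter = hist$litter[1])
  for (r in 2:nrow(hist)) {
    off <- breed_generation(cohort, n_off = hist$N[r], n_off_m = hist$N_m[r],
                            litter = cohort$litter, map = map,
                            mutation_rate = mutation_rate)
    off$litter <- hist$litter[r]
    cohort <- off
  }

  # random split of the last historical cohort into A and B halves
  pops <- sort(unique(schedule$pop[schedule$pop != "HIST"]))
  n_hist <- length(cohort$sex)
  out <- list(map = map, schedule = schedule)
  perm <- sample.int(n_hist)
  halves <- lapply(seq_along(pops), function(k)
    sort(perm[seq.int(k, n_hist, by = length(pops))]))

  # extract every split cohort before breeding so the historical
  # haplotypes can be released (they dominate peak memory)
  splits <- vector("list", length(pops))
  rows_of <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    rows <- schedule[schedule$pop == pops[k], , drop = FALSE]
    rows_of[[k]] <- rows[order(rows$generation), , drop = FALSE]
    idx <- halves[[k]]
    if (rows_of[[k]]$N[1] != length(idx))
      stop("generation-0 size must equal half the last historical cohort")
    hcols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    splits[[k]] <- list(
      hap = cohort$hap[, hcols, drop = FALSE],
      sex = sample(rep(c(1L, 2L),
                       c(rows_of[[k]]$N_m[1], rows_of[[k]]$N_f[1]))),
      litter = rows_of[[k]]$litter[1])
  }
  rm(cohort); gc(FALSE)

  ped <- list()
  id_offset <- 0L
  for (k in seq_along(pops)) {
    p <- pops[k]
    rows <- rows_of[[k]]
    res <- .breed_through(splits[[k]], rows[-1, , drop = FALSE], map,
                          mutation_rate = 0, pop = p,
                          ped_from = max(rows$generation) - 9L,
                          id_offset = id_offset)
    splits[k] <- list(NULL)
    id_offset <- res$next_id
    ped[[k]] <- res$pedigree
    out[[paste0("hap_", p)]] <- res$cohort$hap
    out[[paste0("freq_", p)]] <- allele_freq(res$cohort$hap)
    out[[paste0("ids_", p)]] <- res$cohort$ids
  }
  ped <- do.call(rbind, ped)
  # generation-41 individuals are pedigree founders
  ped$sire[ped$generation == min(ped$generation)] <- 0L
  ped$dam[ped$generation == min(ped$generation)] <- 0L
  rownames(ped) <- NULL
  out$pedigree <- ped
  class(out) <- "popsim_result"
  out
}
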