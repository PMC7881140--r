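#' Scenario archetypes for sweep-mechanism simulations
#'
#' Builds a [sim_config()] for one of the canonical sweep archetypes seen
#' in evolve-and-resequence experiments:
#'
#' * `neutral` — no selected loci; pure drift on standing variation.
#' * `hard` — a favored standing allele carried by a single founder
#'   haplotype (`k = 1`); all its linked hitchhikers fix with it.
#' * `soft_standing` — the same favored allele copied onto `k >= 2`
#'   distinct founder haplotypes; shared variants fix while carrier-private
#'   variants plateau at the carrier-haplotype frequencies.
#' * `de_novo_late` — the favored allele is absent from the founders and is
#'   injected on one chromosome at generation `introduction` (re-injected
#'   while lost, emulating recurrent mutation, so a late sweep eventually
#'   starts).
#' * `fm_recombination` — two favored loci at distant positions, each on a
#'   different founder haplotype, fitness multiplicative across loci so
#'   the recombinant joining both is fittest. Each carrier haplotype also
#'   bears a linked deleterious variant positioned outside the span
#'   between the favored loci, solved so the single haplotypes are
#'   marginally neutral (`fm_net_fitness`, default 1): they linger at
#'   their founding frequencies (`fm_founder_freq`, two distinct
#'   intermediate values) until a crossover between the favored loci —
#'   rare, the scenario's crossover rate is low — yields a load-free
#'   recombinant with the full advantage `(1+s_a)(1+s_b) - 1 = s`, which
#'   then sweeps late. This is the recombinational route to a late sweep:
#'   beneficial alleles from two backgrounds united on one haplotype.
#'
#' @param kind one of `"neutral"`, `"hard"`, `"soft_standing"`,
#'   `"de_novo_late"`, `"fm_recombination"`.
#' @param n_generations,n_diploids,genome_length,recomb_rate,n_loci,
#'   n_founders see [sim_config()]; defaults emulate a 500-kb region in a
#'   laboratory population of 200 diploids founded from 27 lines.
#' @param s selection advantage of the sweeping haplotype (genotype fitness
#'   1, 1+hs, 1+s per locus). For `fm_recombination` this is the advantage
#'   of the recombinant; each single favored locus gets
#'   `sqrt(1+s) - 1`.
#' @param h dominance (default 0.5, genic selection).
#' @param k number of carrier founder haplotypes for `soft_standing`.
#' @param introduction generation of the de novo injection.
#' @param sel_position genomic position of the favored locus as a
#'   fraction of `genome_length` (single-locus archetypes).
#' @param fm_net_fitness length-2 marginal net fitness of the two single
#'   carrier haplotypes in `fm_recombination` (deleterious partners are
#'   solved to give these); the default 1 keeps the singles drifting so
#'   the sweep begins only after the joining crossover.
#' @param fm_founder_freq length-2 founding frequencies of the two
#'   carrier haplotypes (the remaining founders share the rest evenly).
#' @param seed seed for the founder-panel draw (the same panel founds every
#'   replicate; pass per-replicate seeds to [simulate_wf()] instead).
#' @return A [sim_config()]; the focal loci are recorded in
#'   `$selected_loci` and sensible pooled-sequencing sampling generations
#'   in `attr(, "sample_generations")`.
#' @export
make_scenario <- function(kind = c("neutral", "hard", "soft_standing",
                                   "de_novo_late", "fm_recombination"),
                          n_generations = 180, n_diploids = 200,
                          n_loci = 800, genome_length = 5e5,
                          n_founders = 27, recomb_rate = 0.01,
                          s = 0.5, h = 0.5, k = 2, introduction = 60,
                          sel_position = 0.5,
                          fm_net_fitness = c(1, 1),
                          fm_founder_freq = c(0.18, 0.38), seed = NULL) {
  kind <- match.arg(kind)
  # the recombination archetype is a rare event: with a low crossover
  # rate the joining happens late (or not at all, in most replicates),
  # its breakpoint neighbourhood is not eroded while the recombinant
  # sweeps, and competing recombinants are unlikely
  if (kind == "fm_recombination" && missing(recomb_rate))
    recomb_rate <- 3e-4
  if (!is.null(seed)) set.seed(seed)
  F <- make_founders(n_founders, n_loci)
  positions <- sort(sample.int(genome_length, n_loci))

  at_frac <- function(fr) which.min(abs(positions - fr * genome_length))
  sel <- NULL

  if (kind == "hard" || kind == "soft_standing") {
    kk <- if (kind == "hard") 1L else as.integer(k)
    if (kk > n_founders) stop("k exceeds founder haplotype count")
    loc <- at_frac(sel_position)
    F[, loc] <- 0L
    F[sample.int(n_founders, kk), loc] <- 1L
    sel <- data.frame(locus = loc, s = s, h = h, introduction = 0L,
                      recurrent = FALSE)
  } else if (kind == "de_novo_late") {
    loc <- at_frac(sel_position)
    F[, loc] <- 0L
    sel <- data.frame(locus = loc, s = s, h = h,
                      introduction = as.integer(introduction),
                      recurrent = TRUE)
  } else if (kind == "fm_recombination") {
    la <- at_frac(0.25); lb <- at_frac(0.75)
    da <- at_frac(0.92); db <- at_frac(0.08)
    loci <- c(la, lb, da, db)
    if (anyDuplicated(loci)) stop("genome too sparse to place FM loci")
    s_single <- sqrt(1 + s) - 1
    s_da <- fm_net_fitness[1] / (1 + s_single) - 1
    s_db <- fm_net_fitness[2] / (1 + s_single) - 1
    F[, loci] <- 0L
    ca <- sample.int(n_founders, 2L)        # two distinct carrier founders
    F[ca[1], c(la, da)] <- 1L               # haplotype A: favored + load
    F[ca[2], c(lb, db)] <- 1L               # haplotype B: favored + load
    sel <- data.frame(locus = c(la, lb, da, db),
                      s = c(s_single, s_single, s_da, s_db),
                      h = h, introduction = 0L, recurrent = FALSE)
  }

  founder_weights <- NULL
  if (kind == "fm_recombination") {
    founder_weights <- rep((1 - sum(fm_founder_freq)) / (n_founders - 2),
                           n_founders)
    founder_weights[ca] <- fm_founder_freq
  }

  cfg <- sim_config(n_generations = n_generations, n_diploids = n_diploids,
                    founder_haplotypes = F, positions = positions,
                    genome_length = genome_length, recomb_rate = recomb_rate,
                    selected_loci = sel, founder_weights = founder_weights)
  attr(cfg, "kind") <- kind
  attr(cfg, "sample_generations") <-
    unique(pmin(c(0, 7, 12, 31, 61, 114, 162, 180), n_generations))
  cfg
}

#' Census schedule with a bottleneck and gradual recovery
#'
#' Piecewise census-size schedule emulating the demography of a stressed
#' experimental population: constant at `base`, an abrupt crash to
#' `floor_n` at `crash_at`, then geometric recovery back to `base` over
#' `recovery` generations.
#'
#' @param n_generations schedule length minus one (element 1 is
#'   generation 0).
#' @param base,floor_n census sizes (diploids) before the crash and at its
#'   bottom.
#' @param crash_at generation of the crash.
#' @param recovery number of generations over which the census returns to
#'   `base`.
#' @return Integer vector of length `n_generations + 1`, usable as the
#'   `n_diploids` argument of [sim_config()].
#' @export
bottleneck_schedule <- function(n_generations, base = 200, floor_n = 30,
                                crash_at = 13, recovery = 100) {
  stopifnot(crash_at >= 1, crash_at <= n_generations, floor_n >= 1,
            base >= floor_n)
  g <- 0:n_generations
  n <- rep(base, n_generations + 1L)
  ramp <- exp(seq(log(floor_n), log(base), length.out = recovery + 1L))
  idx <- g >= crash_at
  n[idx] <- c(ramp, rep(base, sum(idx)))[seq_len(sum(idx))]
  as.integer(round(n))
}
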