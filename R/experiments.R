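#' Unlinked neutral pool-seq counts
#'
#' Simulates `n_sites` independent neutral Wright-Fisher trajectories
#' (initial frequencies from the founder-panel spectrum unless given) and
#' pool-sequences them at the sampled generations — the standard test bed
#' for the drift-based effective-population-size estimator, where the
#' unlinked-sites composite likelihood assumption holds exactly.
#'
#' @param n_sites number of sites.
#' @param ne diploid population size of the simulation.
#' @param generations sampled generations (first is the initial one).
#' @param mean_depth,pool_chromosomes sequencing model as in
#'   [pool_sequence()].
#' @param p0 initial frequencies (recycled), or `NULL` for the
#'   neutral-equilibrium founder spectrum.
#' @param replicate_id sample label.
#' @param seed optional RNG seed.
#' @return An [allele_counts()] object.
#' @export
sim_unlinked_counts <- function(n_sites, ne, generations,
                                mean_depth = 100, pool_chromosomes = 200,
                                p0 = NULL, replicate_id = "R1",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (pool_chromosomes > 2 * ne)
    stop("pool_chromosomes exceeds population chromosomes")
  generations <- as.integer(generations)
  if (is.null(p0)) {
    w <- 1 / (1:26)
    p0 <- sample(1:26, n_sites, TRUE, w / sum(w)) / 27
  }
  P <- simulate_wf_locus(n_sites, p0, ne, 0, 0.5,
                         max(generations) - generations[1],
                         keep_gens = generations - generations[1])
  cnt <- round(P * 2 * ne)
  in_pool <- matrix(stats::rhyper(length(cnt), cnt, 2 * ne - cnt,
                                  pool_chromosomes), nrow(cnt))
  dp <- matrix(stats::rpois(length(cnt), mean_depth), nrow(cnt))
  alt <- matrix(stats::rbinom(length(cnt), dp, in_pool / pool_chromosomes),
                nrow(cnt))
  allele_counts(
    data.frame(chrom = "sim1", pos = seq_len(n_sites) * 1000L,
               ref_allele = "A", alt_allele = "T",
               stringsAsFactors = FALSE),
    data.frame(replicate = replicate_id, generation = generations,
               pool_chromosomes = as.integer(pool_chromosomes),
               stringsAsFactors = FALSE),
    dp - alt, alt)
}

#' Effective-population-size recovery experiment
#'
#' Simulates unlinked neutral pool-seq datasets at a known true Ne and
#' re-estimates it with [estimate_ne()], reporting how often the estimate
#' falls within a relative tolerance of the truth.
#'
#' @param n_seeds number of independent datasets (default 20).
#' @param ne_true simulating population size (default 200).
#' @param n_sites,mean_depth,pool_chromosomes,generations dataset design.
#' @param ne_grid estimation grid (default 80..400 in steps of 20,
#'   bracketing the truth with ~10% resolution).
#' @param tolerance relative error counted as a recovery (default 0.3).
#' @param seed master seed.
#' @return List with `ne_hat` (per seed), `recovered` (fraction inside
#'   the band), `ci_width` (per seed) and the settings.
#' @export
ne_recovery_experiment <- function(n_seeds = 20, ne_true = 200,
                                   n_sites = 500, mean_depth = 100,
                                   pool_chromosomes = 200,
                                   generations = c(0, 10, 20, 30),
                                   ne_grid = seq(80, 400, by = 20),
                                   tolerance = 0.3, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(1e8, n_seeds)
  ne_hat <- ci_width <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    acm <- sim_unlinked_counts(n_sites, ne_true, generations, mean_depth,
                               pool_chromosomes, seed = seeds[i])
    est <- estimate_ne(acm, ne_grid = ne_grid, site_stride = 1)
    ne_hat[i] <- est$ne_hat
    ci_width[i] <- est$ci_upper - est$ci_lower
  }
  list(ne_hat = ne_hat,
       recovered = mean(abs(ne_hat - ne_true) <= tolerance * ne_true),
       ci_width = ci_width, ne_true = ne_true, n_sites = n_sites,
       generations = generations)
}

#' Sweep-detection power experiment
#'
#' Simulates hard-sweep genomes and asks how often the scan's top-ranked
#' window contains the favored locus.
#'
#' @param n_seeds number of simulated genomes (default 20).
#' @param s,ne selection coefficient and population size of the sweep.
#' @param generations sampled generations.
#' @param mean_depth,pool_chromosomes sequencing model.
#' @param window_bp,step_bp,max_states scan settings.
#' @param n_loci,genome_length,recomb_rate genome design. The default
#'   region spans ~0.6 Morgans, long enough that recombination confines
#'   the sweep's hitchhiking footprint to the windows around the favored
#'   locus while it runs; on a short fully linked segment every window
#'   hitchhikes equally and window ranks are arbitrary, so top-window
#'   localization is only meaningful on a multi-window map.
#' @param seed master seed.
#' @return List with `hit` (logical per seed: favored locus inside the
#'   top window), `power` (mean), `top_lr` per seed.
#' @export
sweep_power_experiment <- function(n_seeds = 20, s = 0.5, ne = 200,
                                   generations = c(0, 10, 20, 30),
                                   mean_depth = 100,
                                   pool_chromosomes = 200,
                                   window_bp = 5e5, step_bp = 25e4,
                                   max_states = 101, n_loci = 1000,
                                   genome_length = 5e6,
                                   recomb_rate = 0.6, seed = 1) {
  set.seed(seed)
  hit <- logical(n_seeds)
  top_lr <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- make_scenario("hard", n_generations = max(generations),
                         n_diploids = ne, n_loci = n_loci,
                         genome_length = genome_length, s = s,
                         recomb_rate = recomb_rate,
                         sel_position = stats::runif(1, 0.25, 0.75),
                         seed = sample.int(1e8, 1))
    # condition on the sweep rising (a hard-sweep genome)
    for (try in 1:40) {
      res <- simulate_wf(cfg, seed = sample.int(1e8, 1))
      pf <- res$true_freqs[cfg$selected_loci$locus, ncol(res$true_freqs)]
      if (pf > 0.8) break
    }
    acm <- pool_sequence(res, generations, "R1", pool_chromosomes,
                         mean_depth, seed = sample.int(1e8, 1))
    sc <- scan_selection(acm, list(range(generations)), window_bp,
                         step_bp, ne, max_states = max_states)
    top <- sc[which.max(sc$lr_stat), ]
    pos <- cfg$positions[cfg$selected_loci$locus]
    hit[i] <- pos - 1 >= top$start && pos - 1 < top$end
    top_lr[i] <- top$lr_stat
  }
  list(hit = hit, power = mean(hit), top_lr = top_lr)
}
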