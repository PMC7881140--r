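#' Vectorized single-locus Wright-Fisher trajectories
#'
#' Simulates `n_paths` independent biallelic loci in a Wright-Fisher
#' population of `ne` diploids under genic/dominant selection: each
#' generation the post-selection frequency
#' \deqn{p^* = \frac{p^2(1+s) + p(1-p)(1+hs)}{p^2(1+s) + 2p(1-p)(1+hs) + (1-p)^2}}
#' is binomially resampled as `Binomial(2 ne, p*) / (2 ne)`. This is the
#' drift engine behind the empirical nulls (scan threshold, sweep-start
#' distribution) and the Monte-Carlo checks of the full simulator.
#'
#' @param n_paths number of independent trajectories.
#' @param p0 initial allele frequency, scalar or length `n_paths`.
#' @param ne diploid population size.
#' @param s,h selection coefficient (`s > -1`) and dominance.
#' @param n_generations number of generations to iterate.
#' @param keep_gens generations (0-based, 0 = initial) at which to record
#'   frequencies; default all.
#' @return Numeric matrix `n_paths` x `length(keep_gens)` of allele
#'   frequencies, with `keep_gens` as column names.
#' @export
simulate_wf_locus <- function(n_paths, p0, ne, s = 0, h = 0.5,
                              n_generations, keep_gens = NULL) {
  stopifnot(n_paths >= 1, ne >= 1, s > -1, all(p0 >= 0), all(p0 <= 1))
  if (is.null(keep_gens)) keep_gens <- 0:n_generations
  keep_gens <- as.integer(keep_gens)
  stopifnot(all(keep_gens >= 0), all(keep_gens <= n_generations))
  p <- rep_len(as.numeric(p0), n_paths)
  out <- matrix(NA_real_, n_paths, length(keep_gens),
                dimnames = list(NULL, keep_gens))
  if (0L %in% keep_gens) out[, match(0L, keep_gens)] <- p
  two_ne <- 2L * as.integer(ne)
  for (t in seq_len(max(keep_gens))) {
    p <- .post_selection(p, s, h)
    p <- stats::rbinom(n_paths, two_ne, p) / two_ne
    j <- match(t, keep_gens)
    if (!is.na(j)) out[, j] <- p
  }
  out
}

# deterministic one-generation selection map; s = 0 is the identity
.post_selection <- function(p, s, h) {
  if (s == 0) return(p)
  q <- 1 - p
  num <- p * p * (1 + s) + p * q * (1 + h * s)
  den <- p * p * (1 + s) + 2 * p * q * (1 + h * s) + q * q
  num / den
}

#' Null distribution of sweep-start times for a standing variant
#'
#' Simulates single-locus Wright-Fisher trajectories of a standing allele
#' at initial frequency `p0` under selection `s` acting from generation 0,
#' keeps those that reach fixation, and records each one's sweep-start
#' time: the first generation at which the frequency exceeds 0.25 and
#' never subsequently drops below 0.1 (an establishment-style definition
#' robust to drift jitter). The resulting conditional distribution is the
#' reference null for the lateness test: a sweep observed to start `t`
#' generations after the onset of selection is improbably late when few
#' null draws start that late.
#'
#' @param s selection coefficient (> 0).
#' @param ne diploid effective population size.
#' @param p0 initial allele frequency in (0, 1).
#' @param n_generations trajectory length (default 300; long enough for
#'   fixation at the selection strengths of interest).
#' @param n_sims number of simulated trajectories.
#' @param seed optional RNG seed.
#' @param h dominance.
#' @return Object of class `"lateness_null"`: list with sorted
#'   `start_times` (conditional on fixation), `n_fixed`, `n_sims` and the
#'   parameters.
#' @export
lateness_null <- function(s, ne, p0, n_generations = 300, n_sims = 10000,
                          seed = NULL, h = 0.5) {
  stopifnot(s > 0, p0 > 0, p0 < 1)
  if (n_sims < 1) stop("n_sims must be positive")
  if (!is.null(seed)) set.seed(seed)
  chunk <- 20000L
  starts <- vector("list", ceiling(n_sims / chunk))
  done <- 0L
  ci <- 0L
  while (done < n_sims) {
    n <- min(chunk, n_sims - done)
    P <- simulate_wf_locus(n, p0, ne, s, h, n_generations)
    fixed <- P[, ncol(P)] == 1
    if (any(fixed)) {
      Pf <- P[fixed, , drop = FALSE]
      ci <- ci + 1L
      starts[[ci]] <- .sweep_start_times(Pf)
    }
    done <- done + n
  }
  st <- unlist(starts)
  if (!length(st))
    stop("no fixations observed; increase n_sims, n_generations or s")
  structure(list(start_times = sort(st), n_fixed = length(st),
                 n_sims = n_sims,
                 params = list(s = s, ne = ne, p0 = p0, h = h,
                               n_generations = n_generations)),
            class = "lateness_null")
}

# rows = fixed trajectories (generations 0..G in columns); returns, per
# row, the first generation with p > 0.25 whose suffix minimum stays >= 0.1
.sweep_start_times <- function(P) {
  G <- ncol(P)
  S <- P
  for (j in (G - 1L):1L) S[, j] <- pmin(P[, j], S[, j + 1L])
  ok <- P > 0.25 & S >= 0.1
  # first TRUE per row; every fixed trajectory has one (the fixed tail)
  max.col(ok, ties.method = "first") - 1L
}

#' @export
print.lateness_null <- function(x, ...) {
  q <- stats::quantile(x$start_times, c(0.5, 0.99, 0.999))
  cat(sprintf(
    "<lateness_null> s=%g, Ne=%d, p0=%.4g: %d/%d fixed\n",
    x$params$s, x$params$ne, x$params$p0, x$n_fixed, x$n_sims))
  cat(sprintf("  start-time quantiles: median %d, 99%% %d, 99.9%% %d\n",
              round(q[1]), round(q[2]), round(q[3])))
  invisible(x)
}

#' Pooled sequencing of simulated trajectories
#'
#' Turns the true allele-frequency trajectories of a [simulate_wf()] run
#' into pooled read counts with the two sampling stages of pool-seq:
#' first `pool_chromosomes` chromosomes are drawn without replacement from
#' the `2 N_t` in the population (hypergeometric), then per-site read depth
#' is drawn as `Poisson(mean_depth)` and alternate-read counts as
#' `Binomial(depth, pool frequency)`.
#'
#' @param result a [simulate_wf()] result.
#' @param generations generations to sequence (must have been simulated).
#' @param replicate_id sample label for the resulting columns.
#' @param pool_chromosomes chromosomes in the pool (e.g. 200 for 100
#'   diploid individuals); must not exceed `2 N_t`.
#' @param mean_depth mean sequencing depth per site.
#' @param seed optional RNG seed.
#' @return An [allele_counts()] object with one sample per generation.
#' @export
pool_sequence <- function(result, generations, replicate_id = "R1",
                          pool_chromosomes = 200, mean_depth = 100,
                          seed = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (!is.null(seed)) set.seed(seed)
  generations <- as.integer(generations)
  gi <- match(generations, result$generations)
  if (anyNA(gi))
    stop("generation(s) not simulated: ",
         paste(generations[is.na(gi)], collapse = ", "))
  L <- nrow(result$true_counts)
  ref <- alt <- matrix(0L, L, length(gi))
  for (j in seq_along(gi)) {
    n_chr <- result$pop_chromosomes[gi[j]]
    if (pool_chromosomes > n_chr)
      stop("pool_chromosomes (", pool_chromosomes,
           ") exceeds population chromosomes (", n_chr,
           ") at generation ", generations[j])
    k_true <- result$true_counts[, gi[j]]
    in_pool <- stats::rhyper(L, k_true, n_chr - k_true, pool_chromosomes)
    depth <- stats::rpois(L, mean_depth)
    alt[, j] <- stats::rbinom(L, depth, in_pool / pool_chromosomes)
    ref[, j] <- depth - alt[, j]
  }
  sites <- data.frame(chrom = result$config$chrom,
                      pos = result$config$positions,
                      ref_allele = "A", alt_allele = "T",
                      stringsAsFactors = FALSE)
  allele_counts(sites,
                data.frame(replicate = replicate_id, generation = generations,
                           pool_chromosomes = as.integer(pool_chromosomes),
                           stringsAsFactors = FALSE),
                ref, alt)
}

#' Small neutral example dataset
#'
#' Convenience generator used in examples: unlinked neutral drift at
#' `n_sites` sites in a population of `ne` diploids, pool-sequenced at
#' `generations` for one replicate.
#'
#' @param n_sites,ne,generations,depth,pool,seed simulation settings.
#' @return An [allele_counts()] object.
#' @export
sim_example_counts <- function(n_sites = 50, ne = 100,
                               generations = c(0, 10, 20, 30),
                               depth = 60, pool = 100, seed = 1) {
  set.seed(seed)
  p0 <- stats::rbeta(n_sites, 0.8, 2)
  P <- simulate_wf_locus(n_sites, p0, ne, 0, 0.5, max(generations),
                         keep_gens = generations)
  dp <- matrix(stats::rpois(length(P), depth), nrow(P))
  a <- matrix(stats::rbinom(length(P), dp, pmin(pmax(P, 0), 1)), nrow(P))
  sites <- data.frame(chrom = "sim1", pos = sort(sample.int(1e6, n_sites)),
                      ref_allele = "A", alt_allele = "T",
                      stringsAsFactors = FALSE)
  allele_counts(sites,
                data.frame(replicate = "R1", generation = generations,
                           pool_chromosomes = pool, stringsAsFactors = FALSE),
                dp - a, a)
}
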