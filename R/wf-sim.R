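#' Founder haplotypes with a neutral-equilibrium site spectrum
#'
#' Generates a 0/1 founder haplotype matrix in which each segregating site
#' is carried by `i` of the `n_founders` haplotypes with probability
#' proportional to `1/i` — the neutral-equilibrium allele-frequency
#' spectrum — so that linked hitchhiker clusters exist without coalescent
#' machinery. Emulates an experiment founded from a modest panel of
#' isofemale lines.
#'
#' @param n_founders number of distinct founder haplotypes (default 27).
#' @param n_loci number of segregating sites.
#' @return Integer matrix `n_founders` x `n_loci` of 0/1 alleles.
#' @export
make_founders <- function(n_founders = 27, n_loci = 400) {
  stopifnot(n_founders >= 2, n_loci >= 1)
  i_max <- n_founders - 1L
  w <- 1 / seq_len(i_max)
  carriers <- sample.int(i_max, n_loci, replace = TRUE, prob = w / sum(w))
  H <- matrix(0L, n_founders, n_loci)
  for (j in seq_len(n_loci))
    H[sample.int(n_founders, carriers[j]), j] <- 1L
  H
}

#' Forward simulation scenario description
#'
#' Describes a diploid Wright-Fisher population evolving with selection,
#' recombination, mutation and a (possibly time-varying) census size.
#' Usually built through [make_scenario()].
#'
#' @param n_generations number of generations to simulate (generation 0 is
#'   the founding population).
#' @param n_diploids census size per generation: scalar, or vector of
#'   length `n_generations + 1` (element 1 = generation 0).
#' @param founder_haplotypes 0/1 matrix (haplotypes x loci) of founder
#'   haplotypes, e.g. from [make_founders()]; generation 0 draws its
#'   chromosomes evenly from these rows.
#' @param positions 1-based integer positions of the loci on a single
#'   chromosome; strictly increasing.
#' @param genome_length chromosome length in bp (crossover positions are
#'   uniform on `[0, genome_length]`).
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Poisson, no interference). A 500-kb segment of the fly genome at
#'   ~2 cM/Mb corresponds to about 0.01.
#' @param mutation_rate per-site per-chromosome per-generation flip
#'   probability (default 0; scenario archetypes inject focal mutations
#'   explicitly instead).
#' @param selected_loci data.frame with columns `locus` (column index into
#'   `founder_haplotypes`), `s` (selection coefficient, > -1), `h`
#'   (dominance in `[0,1]`), `introduction` (generation at which a de novo
#'   allele is placed on one random chromosome; 0 = standing from the
#'   start) and `recurrent` (logical: re-inject if lost before
#'   establishment, emulating recurrent mutation). Genotype fitness per
#'   locus is 1, 1+hs, 1+s, multiplicative across loci.
#' @param founder_weights founding proportions of the founder haplotypes
#'   (default `NULL`: equal representation). Unequal weights model founder
#'   lines that contributed unequally to the base population.
#' @param chrom chromosome name used in derived site tables.
#' @param seed optional RNG seed stored with the config.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_generations, n_diploids, founder_haplotypes,
                       positions, genome_length,
                       recomb_rate = 0.01, mutation_rate = 0,
                       selected_loci = NULL, founder_weights = NULL,
                       chrom = "sim1", seed = NULL) {
  founder_haplotypes <- as.matrix(founder_haplotypes)
  storage.mode(founder_haplotypes) <- "integer"
  n_loci <- ncol(founder_haplotypes)
  positions <- as.integer(positions)
  stopifnot(length(positions) == n_loci, !is.unsorted(positions, strictly = TRUE),
            positions[1] >= 1, positions[n_loci] <= genome_length,
            recomb_rate >= 0, mutation_rate >= 0, mutation_rate < 1,
            n_generations >= 1)
  if (length(n_diploids) == 1L)
    n_diploids <- rep.int(as.integer(n_diploids), n_generations + 1L)
  if (length(n_diploids) != n_generations + 1L)
    stop("n_diploids must be scalar or length n_generations + 1")
  if (any(n_diploids < 1)) stop("census sizes must be >= 1")
  if (is.null(selected_loci))
    selected_loci <- data.frame(locus = integer(), s = numeric(),
                                h = numeric(), introduction = integer(),
                                recurrent = logical())
  selected_loci <- as.data.frame(selected_loci)
  if (nrow(selected_loci)) {
    if (is.null(selected_loci$h)) selected_loci$h <- 0.5
    if (is.null(selected_loci$introduction)) selected_loci$introduction <- 0L
    if (is.null(selected_loci$recurrent)) selected_loci$recurrent <- FALSE
    stopifnot(all(selected_loci$s > -1),
              all(selected_loci$h >= 0 & selected_loci$h <= 1),
              all(selected_loci$locus >= 1 & selected_loci$locus <= n_loci))
  }
  if (!is.null(founder_weights)) {
    stopifnot(length(founder_weights) == nrow(founder_haplotypes),
              all(founder_weights >= 0), sum(founder_weights) > 0)
    founder_weights <- founder_weights / sum(founder_weights)
  }
  structure(list(n_generations = as.integer(n_generations),
                 n_diploids = as.integer(n_diploids),
                 founder_haplotypes = founder_haplotypes,
                 founder_weights = founder_weights,
                 positions = positions,
                 genome_length = as.integer(genome_length),
                 recomb_rate = recomb_rate, mutation_rate = mutation_rate,
                 selected_loci = selected_loci, chrom = chrom, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d loci on %s (%d bp), %d generations\n",
    ncol(x$founder_haplotypes), x$chrom, x$genome_length, x$n_generations))
  cat(sprintf("  N (diploids): %d..%d; r = %g xo/meiosis; mu = %g\n",
              min(x$n_diploids), max(x$n_diploids), x$recomb_rate,
              x$mutation_rate))
  if (nrow(x$selected_loci)) {
    sl <- x$selected_loci
    cat(sprintf("  selected: locus %d @ pos %d (s=%.3g, h=%.2g, intro g%d)\n",
                sl$locus, x$positions[sl$locus], sl$s, sl$h, sl$introduction))
  } else cat("  neutral (no selected loci)\n")
  invisible(x)
}

#' Forward Wright-Fisher simulation
#'
#' Simulates the configured diploid population forward in time. Each
#' generation, `2 * N_t` gametes are produced by sampling parents with
#' probability proportional to multiplicative genotype fitness, recombining
#' each parent's two chromosomes with a Poisson number of crossovers at
#' uniform positions, then applying mutation. De novo selected alleles are
#' injected on a single random chromosome at their introduction generation
#' (and re-injected while lost, if `recurrent`).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; overrides `config$seed` when given.
#' @param stop_check optional early-abort hook
#'   `function(counts, generation, n_joinings)` called after every
#'   generation with the current per-locus allele counts; returning
#'   `TRUE` aborts the run (result flagged `aborted = TRUE`). Used by
#'   rejection samplers to discard doomed runs without simulating them
#'   to the end.
#' @return An object of class `"sim_result"`: list with `true_counts`
#'   (loci x generations+1 integer allele counts), `true_freqs` (allele
#'   frequencies, counts / 2N_t), `pop_chromosomes` (2N_t per generation),
#'   `haplotypes` (terminal-generation 0/1 matrix), `event_log`
#'   (data.frame of injections and of crossovers joining two favored
#'   alleles onto one chromosome), `extinct` flag and the `config`.
#' @examples
#' cfg <- make_scenario("hard", n_generations = 30, seed = 1)
#' res <- simulate_wf(cfg, seed = 2)
#' res$true_freqs[cfg$selected_loci$locus, c(1, 31)]
#' @export
simulate_wf <- function(config, seed = NULL, stop_check = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  else if (!is.null(config$seed)) set.seed(config$seed)

  L <- ncol(config$founder_haplotypes)
  G <- config$n_generations
  Ns <- config$n_diploids
  sl <- config$selected_loci
  pos <- config$positions
  glen <- config$genome_length
  r <- config$recomb_rate
  mu <- config$mutation_rate

  # generation 0: draw chromosomes from founder haplotypes (even
  # representation, or weighted founding proportions)
  n_chr0 <- 2L * Ns[1]
  nf <- nrow(config$founder_haplotypes)
  f_idx <- if (is.null(config$founder_weights))
    sample(rep_len(seq_len(nf), n_chr0))
  else {
    # deterministic rounding of the expected counts, remainder at random
    cnt <- floor(config$founder_weights * n_chr0)
    short <- n_chr0 - sum(cnt)
    if (short > 0)
      cnt <- cnt + tabulate(sample.int(nf, short, prob =
        pmax(config$founder_weights * n_chr0 - cnt, 1e-12)), nf)
    sample(rep(seq_len(nf), cnt))
  }
  # internal layout: loci x chromosomes (column operations on gametes
  # are contiguous and markedly faster than row operations)
  H <- t(config$founder_haplotypes)[, f_idx, drop = FALSE]

  counts <- matrix(0L, L, G + 1L)
  counts[, 1L] <- rowSums(H)
  events <- list(); n_ev <- 0L; n_join <- 0L
  add_event <- function(generation, type, position) {
    n_ev <<- n_ev + 1L
    if (type == "joining_crossover") n_join <<- n_join + 1L
    events[[n_ev]] <<- list(generation = generation, type = type,
                            position = position)
  }
  extinct <- FALSE
  aborted <- FALSE

  fav <- which(sl$s > 0)
  two_fav <- length(fav) >= 2L
  if (two_fav) {
    fa <- sl$locus[fav[1]]; fb <- sl$locus[fav[2]]
    if (pos[fa] > pos[fb]) { tmp <- fa; fa <- fb; fb <- tmp }
  }

  for (t in seq_len(G)) {
    # de novo injections (allele enters this generation's parent pool)
    if (nrow(sl)) {
      for (k in seq_len(nrow(sl))) {
        if (sl$introduction[k] == 0L) next
        loc <- sl$locus[k]
        due <- t - 1L >= sl$introduction[k]
        absent <- sum(H[loc, ]) == 0L
        if (absent && ((t - 1L == sl$introduction[k]) ||
                       (due && isTRUE(sl$recurrent[k])))) {
          chr <- sample.int(ncol(H), 1L)
          H[loc, chr] <- 1L
          counts[loc, t] <- counts[loc, t] + 1L
          add_event(t - 1L, "injection", pos[loc])
        }
      }
    }

    n_par <- ncol(H) %/% 2L
    w <- rep(1, n_par)
    if (nrow(sl)) {
      active <- sl$introduction <= t - 1L
      for (k in which(active)) {
        loc <- sl$locus[k]
        g <- H[loc, seq(1L, 2L * n_par, by = 2L)] +
             H[loc, seq(2L, 2L * n_par, by = 2L)]
        w <- w * c(1, 1 + sl$h[k] * sl$s[k], 1 + sl$s[k])[g + 1L]
      }
    }
    if (all(w <= 0)) { extinct <- TRUE; counts <- counts[, 1:t, drop = FALSE]; break }

    n_gam <- 2L * Ns[t + 1L]
    parents <- sample.int(n_par, n_gam, replace = TRUE, prob = w)
    r1 <- 2L * parents - 1L
    r2 <- 2L * parents
    phase <- sample.int(2L, n_gam, replace = TRUE) - 1L
    nxo <- stats::rpois(n_gam, r)

    take <- r1
    sw1 <- phase == 1L
    take[sw1] <- r2[sw1]
    newH <- H[, take, drop = FALSE]
    for (g in which(nxo > 0L)) {
      bp <- sort(stats::runif(nxo[g], 0, glen))
      seg <- findInterval(pos, bp)
      ph <- (phase[g] + seg) %% 2L
      gam <- H[, r1[g]]
      sw <- ph == 1L
      gam[sw] <- H[sw, r2[g]]
      newH[, g] <- gam
      if (two_fav && gam[fa] == 1L && gam[fb] == 1L &&
          !(H[fa, r1[g]] == 1L && H[fb, r1[g]] == 1L) &&
          !(H[fa, r2[g]] == 1L && H[fb, r2[g]] == 1L)) {
        mid <- bp[bp > pos[fa] & bp < pos[fb]]
        add_event(t, "joining_crossover",
                  if (length(mid)) round(mid[1]) else NA_integer_)
      }
    }

    if (mu > 0) {
      n_mut <- stats::rbinom(1L, n_gam * L, mu)
      if (n_mut > 0L) {
        cells <- sample.int(n_gam * L, n_mut)
        newH[cells] <- 1L - newH[cells]
      }
    }

    H <- newH
    counts[, t + 1L] <- rowSums(H)
    if (!is.null(stop_check) && stop_check(counts[, t + 1L], t, n_join)) {
      aborted <- TRUE
      counts <- counts[, 1:(t + 1L), drop = FALSE]
      break
    }
  }

  event_log <- if (n_ev) data.frame(
    generation = vapply(events[seq_len(n_ev)], `[[`, integer(1),
                        "generation"),
    type = vapply(events[seq_len(n_ev)], `[[`, character(1), "type"),
    position = vapply(events[seq_len(n_ev)],
                      function(e) as.integer(e$position), integer(1)),
    stringsAsFactors = FALSE)
  else data.frame(generation = integer(), type = character(),
                  position = integer(), stringsAsFactors = FALSE)

  pop_chr <- 2L * Ns[seq_len(ncol(counts))]
  structure(list(
    true_counts = counts,
    true_freqs = sweep(counts, 2L, pop_chr, "/"),
    pop_chromosomes = pop_chr,
    generations = seq_len(ncol(counts)) - 1L,
    haplotypes = t(H),
    event_log = event_log,
    extinct = extinct,
    aborted = aborted,
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d loci, generations 0..%d%s\n",
              nrow(x$true_counts), max(x$generations),
              if (x$extinct) " (EXTINCT)" else ""))
  if (nrow(x$event_log))
    cat("  events:", paste(sprintf("%s@g%d", x$event_log$type,
                                   x$event_log$generation), collapse = ", "),
        "\n")
  invisible(x)
}
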