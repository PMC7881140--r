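#' Simulate a pooled time-series dataset for one sweep archetype
#'
#' Builds a complete multi-replicate evolve-and-resequence dataset for one
#' of the [make_scenario()] archetypes: a shared founder panel, one
#' forward simulation per replicate, and pooled sequencing at the sampled
#' generations. Because an archetype dataset must actually exhibit its
#' archetype (a "de novo late" dataset without a fixed de novo allele is
#' not one), replicate simulations are redrawn until the defining event
#' occurs:
#'
#' * `hard` / `soft_standing`: the favored allele fixes in every
#'   replicate (near-certain at the default s; replicated sweep).
#' * `de_novo_late`: the injected allele fixes in the focal replicate;
#'   the other replicates evolve neutrally (the mutation arose in one
#'   population only).
#' * `fm_recombination`: the focal replicate shows at least one logged
#'   joining crossover and both favored loci fix; in the other replicates
#'   neither favored locus approaches fixation (the recombinant arose in
#'   one population only).
#'
#' @param kind archetype name, see [make_scenario()].
#' @param seed dataset seed (drives founder panel, replicate seeds,
#'   sequencing noise).
#' @param n_replicates number of replicate populations (default 3).
#' @param sample_generations pooled-sequencing generations.
#' @param pool_chromosomes,mean_depth pooled sequencing settings.
#' @param s selection advantage of the sweeping haplotype (see
#'   [make_scenario()]).
#' @param max_tries redraw limit per replicate.
#' @param fm_min_joining for `fm_recombination`: minimum generation of the
#'   first joining crossover (default 45). The archetype is a *late*
#'   sweep born by recombination; a joining early in the experiment
#'   produces an ordinary early sweep instead.
#' @param fm_fix_by for `fm_recombination`: generation by which the
#'   recombinant must have fixed (default 120), so the sweep completes
#'   inside the sampled window instead of trailing into the last samples.
#' @param ... passed to [make_scenario()] (e.g. `n_diploids`,
#'   `n_loci`, `recomb_rate`).
#' @return List with `acm` (combined [allele_counts()]), `kind`, `config`
#'   and `truth` (per-replicate fixation/establishment of the focal
#'   loci; for `fm_recombination` the generation and position of the
#'   first joining crossover in the focal replicate; `selection_onset`).
#' @export
simulate_archetype <- function(kind, seed, n_replicates = 3,
                               sample_generations = c(0, 7, 12, 31, 61,
                                                      114, 162, 180),
                               pool_chromosomes = 200, mean_depth = 100,
                               s = 0.5, max_tries = 200,
                               fm_min_joining = 45, fm_fix_by = 120, ...) {
  # NOTE: `s` is an explicit formal (not left to `...`) so that callers
  # writing `s = 0.5` can never partially match `seed` or
  # `sample_generations`
  set.seed(seed)
  cfg <- make_scenario(kind, s = s, seed = sample.int(1e8, 1), ...)
  sample_generations <- sample_generations[sample_generations <=
                                             cfg$n_generations]
  fav <- cfg$selected_loci$locus[cfg$selected_loci$s > 0]

  cfg_null <- cfg
  cfg_null$selected_loci <- cfg$selected_loci[0, ]

  ok_for <- function(res, r) {
    if (kind %in% c("hard", "soft_standing"))
      return(all(res$true_freqs[fav, ncol(res$true_freqs)] == 1))
    if (kind == "de_novo_late")
      return(r > 1L || res$true_freqs[fav, ncol(res$true_freqs)] == 1)
    if (kind == "fm_recombination") {
      fixed <- all(res$true_freqs[fav, ncol(res$true_freqs)] == 1)
      if (r == 1L) {
        jg <- res$event_log$generation[res$event_log$type ==
                                         "joining_crossover"]
        if (!(fixed && length(jg) > 0 && min(jg) >= fm_min_joining))
          return(FALSE)
        # the sweep must complete within the sampled window (not trail
        # into the final samples), and the two parental haplotypes must
        # actually sit at distinct frequencies while traceable -- a run
        # where they drift together is not an instance of the archetype
        g_done <- min(fm_fix_by, res$config$n_generations)
        if (!all(res$true_freqs[fav, g_done + 1L] >= 0.95)) return(FALSE)
        pf <- res$true_freqs[fav, , drop = FALSE]
        pre <- sample_generations[sample_generations <
                                    min(jg)][-1]  # sampled, pre-joining
        if (!length(pre)) return(FALSE)
        tr <- pre[length(pre)]
        return(abs(pf[1, tr + 1L] - pf[2, tr + 1L]) >= 0.12)
      }
      return(max(res$true_freqs[fav, ncol(res$true_freqs)]) < 0.9)
    }
    TRUE
  }

  # early-abort hooks so the rejection sampler discards doomed runs
  # cheaply (most of the recombination archetype's candidates can be
  # rejected long before generation 180)
  stop_for <- function(r) {
    if (kind != "fm_recombination") return(NULL)
    two_n <- 2 * cfg$n_diploids[1]
    fa <- fav[1]; fb <- fav[2]
    if (r > 1L) return(function(cnt, t, n_join)
      cnt[fa] >= 0.95 * two_n || cnt[fb] >= 0.95 * two_n)
    first_j <- NA_integer_
    function(cnt, t, n_join) {
      if (is.na(first_j) && n_join > 0L) first_j <<- t
      if (!is.na(first_j) && first_j < fm_min_joining) return(TRUE)
      f1 <- cnt[fa] / two_n; f2 <- cnt[fb] / two_n
      if ((f1 == 1 && f2 < 0.5) || (f2 == 1 && f1 < 0.5)) return(TRUE)
      if (t >= fm_fix_by - 45L && n_join == 0L) return(TRUE)
      if (t >= fm_fix_by && (f1 < 0.95 || f2 < 0.95)) return(TRUE)
      FALSE
    }
  }

  sims <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    use_cfg <- if (kind %in% c("de_novo_late", "fm_recombination") && r > 1L)
      cfg_null else cfg
    for (try in seq_len(max_tries)) {
      res <- simulate_wf(use_cfg, seed = sample.int(1e8, 1),
                         stop_check = stop_for(r))
      if (!res$extinct && !res$aborted && ok_for(res, r)) break
      if (try == max_tries)
        stop(kind, ": replicate ", r, " archetype condition not met in ",
             max_tries, " tries")
    }
    sims[[r]] <- res
  }

  acm <- combine_replicates(lapply(seq_len(n_replicates), function(r)
    pool_sequence(sims[[r]], sample_generations, paste0("R", r),
                  pool_chromosomes, mean_depth,
                  seed = sample.int(1e8, 1))))

  truth <- list(kind = kind, selection_onset = 0L,
                favored_positions = cfg$positions[fav])
  if (kind == "de_novo_late")
    truth$selection_onset <- 0L  # selection acts from g0; the ALLELE is late
  if (length(fav)) {
    truth$fixed <- vapply(sims, function(x)
      all(x$true_freqs[fav, ncol(x$true_freqs)] == 1), logical(1))
    tf <- sims[[1]]$true_freqs[fav[1], , drop = TRUE]
    truth$establishment <- if (tf[length(tf)] == 1)
      .sweep_start_times(matrix(tf, 1)) else NA_integer_
  }
  if (kind == "fm_recombination") {
    ev <- sims[[1]]$event_log
    j <- ev[ev$type == "joining_crossover", , drop = FALSE]
    truth$joining_generation <- j$generation[1]
    truth$breakpoint_true <- j$position[1]
    # any logged joining is a candidate ancestor of the fixed haplotype;
    # the first one need not be the lineage that won
    truth$breakpoints_all <- j$position[!is.na(j$position)]
  }
  list(acm = acm, kind = kind, config = cfg, truth = truth)
}

#' Family-wise window threshold from linked neutral genomes
#'
#' Sites in a window share founder haplotypes and drift together, so the
#' window statistic's genome-wide null is wider than under independent
#' sites ([neutral_threshold()]). This calibrator simulates whole neutral
#' genomes with the archetype generator, scans each exactly like data,
#' and takes the `1 - fwer` point of a Gumbel (extreme-value) tail
#' fitted to the per-genome maximum window `lr_stat` by moments — the
#' genome maximum is a maximum over many dependent window scores, so the
#' extreme-value form extrapolates beyond the simulated sample where a
#' small empirical quantile cannot. The result is the threshold at which
#' a fraction `fwer` of neutral datasets shows any call at all.
#'
#' @param n_genomes number of neutral genomes to simulate (default 25).
#' @param fwer target family-wise false-call rate (default 0.05).
#' @param seed RNG seed.
#' @param background scenario kind whose *selection-free* background the
#'   null genomes copy (founder proportions, recombination rate).
#'   `"neutral"` is the standard background; `"fm_recombination"` gives
#'   the low-recombination, weighted-founder background of the
#'   recombination archetype, whose long founder blocks drift coherently
#'   and need a wider null.
#' @param n_replicates,sample_generations,pool_chromosomes,mean_depth,
#'   time_spans,ne,max_states,n_loci study conditions; must match the
#'   analysis they calibrate.
#' @param ... passed to [make_scenario()].
#' @return Threshold (numeric scalar) with the per-genome maxima in
#'   `attr(, "max_scores")`.
#' @export
genomewide_threshold <- function(n_genomes = 25, fwer = 0.05, seed = 1,
                                 background = "neutral",
                                 n_replicates = 3,
                                 sample_generations = c(0, 7, 12, 31, 61,
                                                        114, 162, 180),
                                 pool_chromosomes = 200, mean_depth = 100,
                                 time_spans = list(c(0, 61),
                                                   c(61, 180)),
                                 ne = 200, max_states = 101, n_loci = 800,
                                 ...) {
  set.seed(seed)
  maxes <- vapply(seq_len(n_genomes), function(i) {
    cfg <- make_scenario(background, seed = sample.int(1e8, 1),
                         n_diploids = ne, n_loci = n_loci, ...)
    cfg$selected_loci <- cfg$selected_loci[0, ]   # background only
    acm <- combine_replicates(lapply(seq_len(n_replicates), function(r) {
      res <- simulate_wf(cfg, seed = sample.int(1e8, 1))
      pool_sequence(res, sample_generations, paste0("R", r),
                    pool_chromosomes, mean_depth,
                    seed = sample.int(1e8, 1))
    }))
    sc <- scan_selection(acm, time_spans, ne = ne,
                         max_states = max_states)
    max(sc$lr_stat)
  }, numeric(1))
  scale <- stats::sd(maxes) * sqrt(6) / pi
  loc <- mean(maxes) - 0.5772157 * scale
  th <- loc - scale * log(-log(1 - fwer))
  attr(th, "max_scores") <- maxes
  th
}

#' End-to-end mechanism classification experiment
#'
#' Simulates `n_per_class` archetype datasets per class, runs the full
#' detection-and-classification pipeline on each with a shared
#' empirical-null threshold (all datasets share the same study
#' conditions), and tabulates predicted against true mechanisms. A
#' dataset's prediction is taken from its strongest call: no call means
#' `neutral`; a replicated call maps to `hard` or `soft_standing`; an
#' individual late call maps to `de_novo_late` or `fm_recombination`; an
#' individual early call counts as a standing (non-archetype) prediction.
#' For true `fm_recombination` datasets the distance between the
#' estimated breakpoint and the logged first joining crossover is
#' recorded.
#'
#' @param n_per_class datasets per archetype (default 20).
#' @param seed master seed.
#' @param kinds archetype classes to include.
#' @param n_diploids,s,mean_depth,pool_chromosomes,n_replicates,
#'   sample_generations study conditions.
#' @param time_spans scan spans (default three 60-120-generation spans).
#' @param max_states HMM state cap used throughout the experiment (101:
#'   light binning of the Ne=200 chain, chosen for desk-scale runtime).
#' @param fwer family-wise false-call level for the calibrated
#'   thresholds (default 0.01, keeping the dataset-level false-call rate
#'   comfortably inside a 5% budget).
#' @param n_loci segregating founder sites per dataset.
#' @param ... passed to [simulate_archetype()] / [make_scenario()].
#' @return Object of class `"confusion_result"`: list with the confusion
#'   `table`, `accuracy` (overall, over archetype datasets),
#'   `neutral_false_rate`, `fm_breakpoint_frac` (FM datasets with
#'   breakpoint within 50 kb of truth), `threshold` and a per-dataset
#'   `details` data.frame.
#' @export
confusion_experiment <- function(n_per_class = 20, seed = 1,
                                 kinds = c("neutral", "hard",
                                           "soft_standing", "de_novo_late",
                                           "fm_recombination"),
                                 n_diploids = 200, s = 0.5,
                                 mean_depth = 100, pool_chromosomes = 200,
                                 n_replicates = 3,
                                 sample_generations = c(0, 7, 12, 31, 61,
                                                        114, 162, 180),
                                 time_spans = list(c(0, 61),
                                                   c(61, 180)),
                                 max_states = 101, fwer = 0.01,
                                 n_loci = 800, ...) {
  set.seed(seed)
  ds_seeds <- matrix(sample.int(1e8, n_per_class * length(kinds)),
                     nrow = length(kinds))

  # family-wise thresholds calibrated on independently seeded
  # selection-free genomes, one per linkage background: the standard
  # background, and (when the recombination archetype is included) its
  # low-recombination weighted-founder background whose long blocks
  # drift coherently and need a wider null
  threshold <- genomewide_threshold(
    n_genomes = 25, fwer = fwer, seed = sample.int(1e8, 1),
    n_replicates = n_replicates, sample_generations = sample_generations,
    pool_chromosomes = pool_chromosomes, mean_depth = mean_depth,
    time_spans = time_spans, ne = n_diploids, max_states = max_states,
    n_loci = n_loci, ...)
  threshold_fm <- if ("fm_recombination" %in% kinds)
    genomewide_threshold(
      n_genomes = 25, fwer = fwer, seed = sample.int(1e8, 1),
      background = "fm_recombination",
      n_replicates = n_replicates, sample_generations = sample_generations,
      pool_chromosomes = pool_chromosomes, mean_depth = mean_depth,
      time_spans = time_spans, ne = n_diploids, max_states = max_states,
      n_loci = n_loci, ...)
  else threshold

  details <- list()
  shared_nulls <- new.env(parent = emptyenv())
  for (ki in seq_along(kinds)) {
    for (d in seq_len(n_per_class)) {
      ds <- simulate_archetype(kinds[ki], ds_seeds[ki, d],
                               n_replicates = n_replicates,
                               sample_generations = sample_generations,
                               pool_chromosomes = pool_chromosomes,
                               mean_depth = mean_depth,
                               n_diploids = n_diploids, s = s,
                               n_loci = n_loci, ...)
      th_use <- if (kinds[ki] == "fm_recombination") threshold_fm
                else threshold
      calls <- run_esap(ds$acm, time_spans = time_spans, ne = n_diploids,
                        threshold = th_use, max_states = max_states,
                        seed = sample.int(1e8, 1),
                        null_cache = shared_nulls)
      pred <- "neutral"; bp_err <- NA_real_
      if (nrow(calls)) {
        top <- calls[which.max(calls$lr_max), ]
        pred <- if (top$status == "replicated") {
          if (identical(top$mechanism, "soft")) "soft_standing" else "hard"
        } else if (top$status == "individual") {
          if (identical(top$mechanism, "fm_recombination"))
            "fm_recombination"
          else if (identical(top$mechanism, "de_novo")) "de_novo_late"
          else "standing_individual"
        } else "partial"
        if (!is.na(top$breakpoint_pos) &&
            length(ds$truth$breakpoints_all))
          bp_err <- min(abs(top$breakpoint_pos - ds$truth$breakpoints_all))
      }
      details[[length(details) + 1L]] <- data.frame(
        kind = kinds[ki], dataset = d, predicted = pred,
        n_calls = nrow(calls), breakpoint_error = bp_err,
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)

  lev <- union(kinds, unique(details$predicted))
  tab <- table(truth = factor(details$kind, kinds),
               predicted = factor(details$predicted, lev))
  arche <- details$kind != "neutral"
  accuracy <- mean(details$predicted[arche] == details$kind[arche])
  neutral_false <- mean(details$predicted[details$kind == "neutral"] !=
                          "neutral")
  fm <- details[details$kind == "fm_recombination", ]
  fm_frac <- if (nrow(fm))
    mean(!is.na(fm$breakpoint_error) & fm$breakpoint_error <= 50000)
  else NA_real_

  structure(list(table = tab, accuracy = accuracy,
                 neutral_false_rate = neutral_false,
                 fm_breakpoint_frac = fm_frac, threshold = c(standard = as.numeric(threshold), fm_background = as.numeric(threshold_fm)),
                 details = details),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("<confusion_result>\n")
  print(x$table)
  cat(sprintf("\n  archetype accuracy %.2f; neutral false-call rate %.2f\n",
              x$accuracy, x$neutral_false_rate))
  if (!is.na(x$fm_breakpoint_frac))
    cat(sprintf("  FM breakpoint within 50 kb: %.2f of FM datasets\n",
                x$fm_breakpoint_frac))
  invisible(x)
}
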