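#' Classify the mechanism of one candidate sweep interval
#'
#' Runs the full decision tree on a candidate interval given the scan
#' results and the count data:
#'
#' 1. Replication: significant windows in all replicates (`replicated`),
#'    exactly one (`individual`), or some (`partial`; reported, not
#'    typed).
#' 2. Replicated sweeps are standing variation; [classify_hard_soft()]
#'    labels them `hard` or `soft` (majority over replicates).
#' 3. Individual sweeps are timed: [estimate_onset_and_fixation()] plus
#'    the [lateness_test()] against the standing-sweep null. Early
#'    individual sweeps are attributed to extant variation that failed to
#'    establish elsewhere (origin `standing`); late ones cannot be.
#' 4. Late individual sweeps are traced back in time
#'    ([traceback_clusters()]): two spatially segregated clusters
#'    ([spatial_separation_test()]) mean the fixed haplotype was born by a
#'    crossover uniting two haplotypes (`fm_recombination`); otherwise the
#'    sweep is attributed to a `de_novo` mutation. De novo calls are
#'    cross-checked against the de novo candidate site list
#'    ([filter_sites()] with `complement = TRUE`); disagreement is flagged
#'    in `notes`, not overridden.
#'
#' All computed statistics are recorded in the returned row regardless of
#' the branch taken.
#'
#' @param interval one-row data.frame (or list) with `chrom`, `start`,
#'   `end`, 0-based half-open.
#' @param acm the [allele_counts()] data.
#' @param scan a [scan_selection()] result covering the interval.
#' @param threshold window significance threshold (from
#'   [neutral_threshold()]).
#' @param ne diploid effective population size for the lateness null.
#' @param freqs optional precomputed [to_frequencies()] tensor.
#' @param selection_onset generation at which selection began (default 0).
#' @param lateness_threshold p(t, s) below which a sweep is late
#'   (default 1e-3).
#' @param y_threshold Y-statistic p-value below which traceback clusters
#'   count as spatially segregated (default 0.05; the segregation call additionally requires a breakpoint with under 40% misplaced sites).
#' @param n_sims_lateness Monte-Carlo size of the lateness null.
#' @param null_cache optional environment reusing lateness nulls across
#'   intervals.
#' @param seed seed for the lateness-null simulation (fixed by default so
#'   classification is deterministic for fixed inputs).
#' @param ... further arguments passed to [classify_hard_soft()].
#' @return A one-row data.frame (the sweep call), or `NULL` when no
#'   replicate shows a significant window in the interval.
#' @export
classify_mechanism <- function(interval, acm, scan, threshold, ne,
                               freqs = NULL, selection_onset = 0,
                               lateness_threshold = 1e-3,
                               y_threshold = 0.05,
                               n_sims_lateness = 10000,
                               null_cache = NULL, seed = 1, ...) {
  if (is.null(freqs)) freqs <- to_frequencies(acm)
  rs <- replication_status(interval, scan, threshold)
  if (rs$status == "none") return(NULL)

  call <- data.frame(
    chrom = interval$chrom, start = interval$start, end = interval$end,
    status = rs$status, replicates = paste(rs$replicates, collapse = ","),
    n_replicates = length(rs$replicates), mechanism = NA_character_,
    origin = NA_character_, onset_generation = NA_integer_,
    fixation_generation = NA_integer_, s_hat = NA_real_,
    lr_max = NA_real_, chi2_stat = NA_real_, chi2_p = NA_real_,
    z_stat = NA_real_, z_p = NA_real_, t_stat = NA_integer_,
    t_p = NA_real_, y_stat = NA_real_, y_p = NA_real_,
    breakpoint_pos = NA_real_, notes = "", stringsAsFactors = FALSE)

  # best supporting window per replicate within the interval
  hit <- scan[scan$chrom == interval$chrom & scan$start < interval$end &
              scan$end > interval$start & scan$replicate %in% rs$replicates, ]
  best_by_rep <- do.call(rbind, lapply(split(hit, hit$replicate),
                                       function(d) d[which.max(d$lr_stat), ]))
  focal <- best_by_rep$replicate[which.max(best_by_rep$lr_stat)]
  call$s_hat <- best_by_rep$s_hat[best_by_rep$replicate == focal]
  call$lr_max <- max(best_by_rep$lr_stat)

  onf <- tryCatch(estimate_onset_and_fixation(interval, freqs, focal),
                  error = function(e) NULL)
  if (is.null(onf)) {
    call$notes <- "no sweeping sites (detection without fixation)"
    return(call)
  }
  call$onset_generation <- onf$onset
  call$fixation_generation <- onf$fixation
  if (nzchar(onf$note)) call$notes <- onf$note

  note <- function(x) paste(c(call$notes[nzchar(call$notes)], x),
                            collapse = "; ")

  if (rs$status == "partial") {
    call$notes <- note("partial replication: not mechanism-typed")
    return(call)
  }

  if (rs$status == "replicated") {
    labs <- character(); hs_focal <- NULL
    for (r in rs$replicates) {
      hs <- tryCatch(classify_hard_soft(interval, acm, freqs, r, ...),
                     error = function(e) NULL)
      if (is.null(hs)) next
      labs <- c(labs, hs$label)
      if (r == focal || is.null(hs_focal)) hs_focal <- hs
    }
    call$chi2_stat <- hs_focal$chi2_stat; call$chi2_p <- hs_focal$chi2_p
    call$z_stat <- hs_focal$z_stat; call$z_p <- hs_focal$z_p
    lab <- names(sort(table(labs[labs != "unclassifiable"]),
                      decreasing = TRUE))[1]
    call$mechanism <- if (is.null(lab) || is.na(lab)) "hard" else lab
    call$origin <- "standing"
    if (any(labs == "unclassifiable"))
      call$notes <- note("unclassifiable in some replicate(s)")
    return(call)
  }

  ## individual sweep: hard/soft stats (informative), then lateness
  hs <- tryCatch(classify_hard_soft(interval, acm, freqs, focal, ...),
                 error = function(e) NULL)
  if (!is.null(hs)) {
    call$chi2_stat <- hs$chi2_stat; call$chi2_p <- hs$chi2_p
    call$z_stat <- hs$z_stat; call$z_p <- hs$z_p
  }

  # selection strength of the sweep for the lateness null: the strongest
  # s seen among the interval's significant windows (the fixation phase),
  # not the possibly slow pre-sweep phase of the top window
  s_sig <- hit$s_hat[hit$replicate == focal & hit$lr_stat >= threshold]
  s_use <- if (length(s_sig) && max(s_sig) > 0) max(s_sig)
           else if (!is.na(call$s_hat) && call$s_hat > 0) call$s_hat
           else 0.5
  sj0 <- which(freqs$samples$replicate == focal)[1]
  p0 <- stats::median(freqs$freq[onf$site_idx, sj0], na.rm = TRUE)
  if (!is.finite(p0) || p0 < 1 / (2 * ne)) p0 <- 1 / (2 * ne)
  # snap to a 0.02 grid: the null is insensitive at that resolution and
  # identical nulls can then be reused across intervals and datasets
  p0 <- min(max(round(p0 / 0.02) * 0.02, 1 / (2 * ne)), 0.5)

  null <- NULL
  if (!is.null(null_cache)) {
    key <- sprintf("s%.3f_p%.4f", s_use, p0)
    null <- null_cache[[key]]
  }
  lt <- lateness_test(onf$onset, selection_onset, s_use, ne, p0,
                      n_sims = n_sims_lateness, seed = seed, null = null)
  if (!is.null(null_cache)) null_cache[[key]] <- lt$null
  call$t_stat <- lt$t
  call$t_p <- lt$t_p

  if (lt$t_p >= lateness_threshold) {
    call$origin <- "standing"
    call$mechanism <- if (!is.null(hs) && hs$label == "soft") "soft" else "hard"
    call$notes <- note("early individual sweep: extant variation")
    return(call)
  }

  # trace over the focal replicate's broader sweep footprint: windows at
  # half the significance threshold, merged across short gaps, joined
  # with the confirmed interval. A recombinant haplotype's two parental
  # blocks need not both clear the stringent genome-wide threshold, but
  # both belong to the fixed haplotype being traced.
  win_bp <- stats::median(scan$end - scan$start)
  foot <- scan[scan$replicate == focal & scan$chrom == interval$chrom &
                 scan$lr_stat >= threshold / 2, , drop = FALSE]
  tb_int <- interval
  if (nrow(foot)) {
    mg <- merge_intervals(c(foot$chrom, interval$chrom),
                          c(foot$start, interval$start),
                          c(foot$end, interval$end), gap = 2L * win_bp)
    hitm <- mg$start < interval$end & mg$end > interval$start
    if (any(hitm)) {
      tb_int <- interval
      tb_int$start <- min(mg$start[hitm])
      tb_int$end <- max(mg$end[hitm])
    }
  }
  tb <- traceback_clusters(tb_int, freqs, focal, onf$fixation)
  if (!tb$single) {
    sp <- spatial_separation_test(tb$clusters$A, tb$clusters$B)
    call$y_stat <- sp$y_stat
    call$y_p <- sp$y_p
    call$breakpoint_pos <- sp$breakpoint_pos
    if (sp$y_p < y_threshold && !is.na(sp$breakpoint_pos)) {
      call$mechanism <- "fm_recombination"
      call$origin <- "recombination"
      return(call)
    }
  }
  call$mechanism <- "de_novo"
  call$origin <- "de_novo"
  dn <- tryCatch(filter_sites(acm, min_depth = 1, complement = TRUE),
                 error = function(e) NULL)
  if (!is.null(dn)) {
    in_int <- .sites_in_interval(dn$sites, interval)
    if (!length(in_int))
      call$notes <- note("no de novo candidate site supports the call")
  }
  call
}

#' Detect and classify selective sweeps in one run
#'
#' End-to-end driver: scans the data in sliding windows and time spans
#' ([scan_selection()]), computes an empirical neutral threshold matched
#' to the data ([neutral_threshold()]) with a family-wise Bonferroni
#' adjustment across all window tests, merges significant windows into
#' candidate intervals ([significant_intervals()]), and classifies each
#' interval's mechanism ([classify_mechanism()]).
#'
#' @param acm an [allele_counts()] object (>= 2 replicates for
#'   replication typing).
#' @param time_spans list of `c(g_start, g_end)` spans (default: sliding
#'   ~60-generation spans over the sampled range).
#' @param ne diploid effective population size (fixed mode), or
#'   `"estimate"`.
#' @param threshold window significance threshold; `NULL` (default)
#'   simulates it at family-wise level `fwer` across all windows tested.
#' @param fwer family-wise false-call level used when simulating the
#'   threshold (default 0.05).
#' @param selection_onset generation selection began (default 0).
#' @param window_bp,step_bp,s_grid,h,max_states passed to
#'   [scan_selection()].
#' @param n_windows_sim,n_site_pool passed to [neutral_threshold()].
#' @param seed seed for the threshold simulation and lateness nulls.
#' @param null_cache optional environment of precomputed lateness nulls,
#'   shared across calls to avoid re-simulating identical nulls.
#' @param ... passed to [classify_mechanism()].
#' @return Object of class `"sweep_calls"`: data.frame of interval calls
#'   (possibly 0 rows) with the scan, threshold and settings in
#'   attributes.
#' @export
run_esap <- function(acm, time_spans = NULL, ne = 200, threshold = NULL,
                     fwer = 0.05, selection_onset = 0,
                     window_bp = 50000, step_bp = 10000,
                     s_grid = c(0, -0.05, 0.05, -0.1, 0.1, 0.2, 0.3, 0.5,
                                0.8, 1),
                     h = 0.5, max_states = 201,
                     n_windows_sim = 20000, n_site_pool = 4000,
                     seed = NULL, null_cache = NULL, ...) {
  stopifnot(inherits(acm, "allele_counts"))
  gens <- sort(unique(acm$samples$generation))
  if (is.null(time_spans)) {
    # sliding spans of ~60 generations anchored at sampled generations
    time_spans <- list()
    for (g in gens) {
      upper <- gens[gens >= g + 30 & gens <= g + 120]
      if (length(upper))
        time_spans[[length(time_spans) + 1L]] <-
          c(g, upper[which.min(abs(upper - (g + 60)))])
    }
    time_spans <- unique(time_spans)
  }

  scan <- suppressWarnings(
    scan_selection(acm, time_spans, window_bp, step_bp, ne,
                   s_grid = s_grid, h = h, max_states = max_states))

  if (is.null(threshold)) {
    ne_thr <- if (identical(ne, "estimate")) round(stats::median(scan$ne_used))
              else ne
    f0 <- to_frequencies(acm)
    at0 <- f0$samples$generation == gens[1]
    p0_obs <- rowMeans(f0$freq[, at0, drop = FALSE], na.rm = TRUE)
    q <- 1 - fwer / nrow(scan)            # Bonferroni across window tests
    med_sites <- stats::median(scan$n_sites)
    depth <- stats::median((acm$ref + acm$alt)[(acm$ref + acm$alt) > 0])
    pool <- acm$samples$pool_chromosomes[1]
    if (is.na(pool)) pool <- 2 * ne_thr
    pool <- min(pool, 2 * ne_thr)
    span_max <- time_spans[[which.max(vapply(time_spans, diff, numeric(1)))]]
    span_gens <- gens[gens >= span_max[1] & gens <= span_max[2]]
    threshold <- neutral_threshold(ne_thr, depth, pool, span_gens,
                                   med_sites, n_windows_sim, q,
                                   p0 = p0_obs, n_site_pool = n_site_pool,
                                   seed = seed, s_grid = s_grid, h = h,
                                   max_states = max_states)
  }

  ints <- significant_intervals(scan, threshold, merge_gap = 2 * window_bp)
  cache <- if (is.null(null_cache)) new.env(parent = emptyenv()) else null_cache
  calls <- list()
  for (i in seq_len(nrow(ints))) {
    cl <- classify_mechanism(ints[i, ], acm, scan, threshold,
                             ne = if (identical(ne, "estimate"))
                               round(stats::median(scan$ne_used)) else ne,
                             selection_onset = selection_onset,
                             null_cache = cache, ...)
    if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               status = character(), replicates = character(),
               n_replicates = integer(), mechanism = character(),
               origin = character(), onset_generation = integer(),
               fixation_generation = integer(), s_hat = numeric(),
               lr_max = numeric(), chi2_stat = numeric(),
               chi2_p = numeric(), z_stat = numeric(), z_p = numeric(),
               t_stat = integer(), t_p = numeric(), y_stat = numeric(),
               y_p = numeric(), breakpoint_pos = numeric(),
               notes = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "scan") <- scan
  attr(res, "threshold") <- threshold
  attr(res, "time_spans") <- time_spans
  class(res) <- c("sweep_calls", "data.frame")
  res
}

#' @export
print.sweep_calls <- function(x, ...) {
  cat(sprintf("<sweep_calls> %d interval call(s); window threshold %.2f\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) {
    show <- x[, c("chrom", "start", "end", "status", "mechanism",
                  "onset_generation", "fixation_generation", "s_hat",
                  "lr_max")]
    print.data.frame(show, digits = 4)
  }
  invisible(x)
}
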