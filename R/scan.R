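#' Composite likelihood-ratio scan for selective sweeps
#'
#' Scans the genome for selection in sliding windows within sliding time
#' intervals, the core detection statistic for evolve-and-resequence time
#' series. For each replicate, time span and window, every site's hidden
#' Wright-Fisher likelihood ratio (see [site_lr()]) is maximized over a
#' selection-coefficient grid and the window statistic is the sum of the
#' per-site ratios,
#' `lr_stat = sum_i 2 (max_s log L_i(s) - log L_i(0))` —
#' a sweep drags hitchhikers up and displaces the alternative haplotypes,
#' so sites in a selected window contribute in both directions. The
#' window's `s_hat` is the grid value with the largest total
#' contribution. Because small populations drift strongly over long
#' intervals, spans of 30-120 generations are recommended rather than the
#' full experiment.
#'
#' @param acm an [allele_counts()] object.
#' @param time_spans list of `c(g_start, g_end)` spans; spans with fewer
#'   than 2 sampled generations for a replicate are skipped with a
#'   warning.
#' @param window_bp,step_bp sliding-window size and step (default
#'   50 kb / 10 kb).
#' @param ne fixed diploid effective population size, or `"estimate"` to
#'   call [estimate_ne()] per replicate and span first (adjusted-Ne mode;
#'   signals are expected to be concordant with the fixed mode).
#' @param s_grid selection-coefficient grid (must include 0).
#' @param h dominance.
#' @param max_states state-space cap; the scan default (201) bins the
#'   Ne = 200 chain lightly for speed with negligible effect at pool-seq
#'   depths.
#' @param ne_grid grid passed to [estimate_ne()] when `ne = "estimate"`.
#' @return A data.frame of class `"sweep_scan"` with one row per
#'   (replicate, span, window): `replicate`, `chrom`, `start`, `end`
#'   (0-based half-open), `g_start`, `g_end`, `n_sites`, `s_hat`,
#'   `lr_stat`, `ne_used`.
#' @export
scan_selection <- function(acm, time_spans, window_bp = 50000,
                           step_bp = 10000, ne = 200,
                           s_grid = c(0, -0.05, 0.05, -0.1, 0.1, 0.2, 0.3,
                                      0.5, 0.8, 1),
                           h = 0.5, max_states = 201,
                           ne_grid = round(exp(seq(log(25), log(1000),
                                                   length.out = 13)))) {
  stopifnot(inherits(acm, "allele_counts"))
  if (!any(s_grid == 0)) stop("s_grid must contain 0")
  if (!is.list(time_spans)) time_spans <- list(time_spans)
  reps <- unique(acm$samples$replicate)
  out <- list()

  for (r in reps) {
    for (span in time_spans) {
      sj <- which(acm$samples$replicate == r &
                  acm$samples$generation >= span[1] &
                  acm$samples$generation <= span[2])
      if (length(sj) < 2) {
        warning(sprintf("replicate %s: span %d..%d has <2 sampled generations; skipped",
                        r, span[1], span[2]))
        next
      }
      gens <- acm$samples$generation[sj]
      alt <- acm$alt[, sj, drop = FALSE]
      depth <- alt + acm$ref[, sj, drop = FALSE]
      use <- rowSums(alt) > 0 & rowSums(depth > 0) >= 2

      ne_r <- if (identical(ne, "estimate")) {
        est <- estimate_ne(acm[, acm$samples$replicate == r], span,
                           ne_grid = ne_grid, site_stride = 5,
                           max_states = max_states)
        est$ne_hat
      } else ne

      # per-site log-likelihood for every s on the grid, then the
      # per-site maximized likelihood ratio (each site may favor its own
      # s, so rising hitchhikers and displaced alleles both contribute)
      ll_by_s <- matrix(-Inf, nrow(acm$sites), length(s_grid))
      grid <- .state_freqs(as.integer(ne_r), max_states)
      em <- .emissions_for(alt[use, , drop = FALSE],
                           depth[use, , drop = FALSE], grid)
      for (k in seq_along(s_grid)) {
        step1 <- selection_transition_matrix(ne_r, s_grid[k], h, 1L,
                                             max_states)
        ll_by_s[use, k] <- .forward_loglik(alt[use, , drop = FALSE],
                                           depth[use, , drop = FALSE],
                                           gens, step1, emis_list = em)
      }
      best_k <- max.col(ll_by_s, ties.method = "first")
      site_lr <- pmax(0, 2 * (ll_by_s[cbind(seq_len(nrow(ll_by_s)), best_k)] -
                                ll_by_s[, s_grid == 0]))
      site_s <- s_grid[best_k]
      site_s[site_lr < 1e-9] <- 0

      for (chr in unique(acm$sites$chrom)) {
        on_chr <- acm$sites$chrom == chr
        pos0 <- acm$sites$pos - 1L   # 0-based
        starts <- seq(0L, max(pos0[on_chr]), by = step_bp)
        for (w0 in starts) {
          in_w <- which(on_chr & use & pos0 >= w0 & pos0 < w0 + window_bp)
          if (!length(in_w)) next
          lr <- sum(site_lr[in_w])
          # window s_hat: grid value with the largest total LR contribution
          contrib <- rowsum(site_lr[in_w], site_s[in_w])
          s_hat <- as.numeric(rownames(contrib))[which.max(contrib)]
          out[[length(out) + 1L]] <- data.frame(
            replicate = r, chrom = chr, start = w0,
            end = w0 + as.integer(window_bp),
            g_start = span[1], g_end = span[2],
            n_sites = length(in_w), s_hat = s_hat,
            lr_stat = lr, ne_used = ne_r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) stop("no windows scanned")
  res <- do.call(rbind, out)
  class(res) <- c("sweep_scan", "data.frame")
  res
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("<sweep_scan> %d windows, %d replicate(s), %d span(s)\n",
              nrow(x), length(unique(x$replicate)),
              nrow(unique(x[, c("g_start", "g_end")]))))
  top <- x[order(-x$lr_stat), ][seq_len(min(5, nrow(x))), ]
  rownames(top) <- NULL
  print.data.frame(top, digits = 4)
  invisible(x)
}

#' Empirical neutral significance threshold for window scores
#'
#' Simulates the scan's null: unlinked neutral Wright-Fisher trajectories
#' matched for span, depth and pool size, scored exactly like data sites;
#' windows are then formed by resampling sites from this null pool, and
#' the requested quantile of the window `lr_stat` distribution is
#' returned. Site resampling makes extreme quantiles affordable: the
#' composite window score has independent site contributions under the
#' null, so bootstrap windows from a large site pool are distributed as
#' freshly simulated ones.
#'
#' @param n_e diploid effective population size of the null.
#' @param depth mean sequencing depth (Poisson).
#' @param pool pool chromosomes sampled from the population.
#' @param time_span sampled generations of the span (vector, e.g.
#'   `c(0, 10, 20, 30)`).
#' @param n_sites_per_window sites per simulated window.
#' @param n_windows_sim number of bootstrap windows (default 20000).
#' @param quantile_p quantile to return (default 0.999).
#' @param p0 initial-frequency sampler: numeric vector to resample
#'   (e.g. the observed first-generation frequencies) or `NULL` for the
#'   founder-panel spectrum of [make_founders()].
#' @param n_site_pool size of the simulated null site pool.
#' @param seed optional RNG seed.
#' @inheritParams scan_selection
#' @return The threshold (numeric scalar); window scores' requested
#'   quantile, with commonly used quantiles in `attr(, "quantiles")`.
#' @export
neutral_threshold <- function(n_e, depth, pool, time_span,
                              n_sites_per_window, n_windows_sim = 20000,
                              quantile_p = 0.999, p0 = NULL,
                              n_site_pool = 4000, seed = NULL,
                              s_grid = c(0, -0.05, 0.05, -0.1, 0.1, 0.2,
                                         0.3, 0.5, 0.8, 1),
                              h = 0.5, max_states = 201) {
  stopifnot(quantile_p > 0, quantile_p < 1, length(time_span) >= 2)
  if (!any(s_grid == 0)) stop("s_grid must contain 0")
  if (!is.null(seed)) set.seed(seed)
  gens <- sort(as.integer(time_span))

  p_init <- if (is.null(p0)) {
    w <- 1 / (1:26)
    sample(1:26, n_site_pool, TRUE, w / sum(w)) / 27
  } else sample(p0[p0 > 0 & p0 < 1], n_site_pool, TRUE)

  P <- simulate_wf_locus(n_site_pool, p_init, n_e, 0, h,
                         max(gens) - gens[1], keep_gens = gens - gens[1])
  cnt <- round(P * 2 * n_e)
  in_pool <- matrix(stats::rhyper(length(cnt), cnt, 2 * n_e - cnt, pool),
                    nrow(cnt))
  dp <- matrix(stats::rpois(length(cnt), depth), nrow(cnt))
  alt <- matrix(stats::rbinom(length(cnt), dp, in_pool / pool), nrow(cnt))

  ll_by_s <- matrix(0, n_site_pool, length(s_grid))
  grid <- .state_freqs(as.integer(n_e), max_states)
  em <- .emissions_for(alt, dp, grid)
  for (k in seq_along(s_grid)) {
    step1 <- selection_transition_matrix(n_e, s_grid[k], h, 1L, max_states)
    ll_by_s[, k] <- .forward_loglik(alt, dp, gens, step1, emis_list = em)
  }

  site_lr <- pmax(0, 2 * (apply(ll_by_s, 1, max) - ll_by_s[, s_grid == 0]))
  pick <- sample.int(n_site_pool, n_windows_sim * n_sites_per_window,
                     replace = TRUE)
  scores <- rowsum(site_lr[pick],
                   rep(seq_len(n_windows_sim), each = n_sites_per_window))[, 1]
  th <- stats::quantile(scores, quantile_p, names = FALSE)
  attr(th, "quantiles") <- stats::quantile(scores,
                                           c(0.5, 0.95, 0.99, 0.999, 0.9999))
  attr(th, "n_windows") <- n_windows_sim
  attr(th, "scores") <- scores
  th
}

#' Merge significant scan windows into candidate sweep intervals
#'
#' Windows with `lr_stat >= threshold` are merged (union of overlapping or
#' adjacent windows) across spans within each replicate, then across
#' replicates into a non-redundant set of candidate intervals. Each
#' interval records which replicates support it.
#'
#' @param scan a [scan_selection()] result.
#' @param threshold significance threshold on `lr_stat`, e.g. from
#'   [neutral_threshold()].
#' @param merge_gap maximum gap (bp) across which significant windows are
#'   still merged into one interval (default 0: only overlapping or
#'   adjacent windows). One sweep's footprint can contain short
#'   sub-threshold valleys — e.g. the region between the two parental
#'   haplotype blocks of a recombinant sweep — so pipelines typically
#'   merge across up to two window widths.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `replicates` (comma-separated supporting replicates) and
#'   `n_replicates`.
#' @export
significant_intervals <- function(scan, threshold, merge_gap = 0) {
  sig <- scan[scan$lr_stat >= threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), replicates = character(),
                      n_replicates = integer(), stringsAsFactors = FALSE))
  merged <- merge_intervals(sig$chrom, sig$start, sig$end,
                            gap = as.integer(merge_gap))
  reps <- unique(scan$replicate)
  merged$replicates <- vapply(seq_len(nrow(merged)), function(i) {
    hit <- sig$chrom == merged$chrom[i] & sig$start < merged$end[i] &
           sig$end > merged$start[i]
    paste(sort(unique(sig$replicate[hit])), collapse = ",")
  }, character(1))
  merged$n_replicates <- lengths(strsplit(merged$replicates, ","))
  merged
}
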