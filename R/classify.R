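#' Replication status of a candidate sweep interval
#'
#' A sweep is `replicated` when significant scan windows overlap the
#' interval in every replicate population, `individual` when they do in
#' exactly one, and `partial` otherwise (e.g. 2 of 3; such intervals are
#' reported but not mechanism-typed).
#'
#' @param interval list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param scan a [scan_selection()] result over >= 2 replicates.
#' @param threshold significance threshold on window `lr_stat`.
#' @return List with `status` (`"replicated"`, `"individual"`,
#'   `"partial"` or `"none"`) and `replicates` (supporting replicate ids).
#' @export
replication_status <- function(interval, scan, threshold) {
  reps <- unique(scan$replicate)
  if (length(reps) < 2) stop("need >= 2 scanned replicates")
  hit <- scan$lr_stat >= threshold & scan$chrom == interval$chrom &
         scan$start < interval$end & scan$end > interval$start
  supp <- sort(unique(scan$replicate[hit]))
  status <- if (length(supp) == 0) "none"
    else if (length(supp) == length(reps)) "replicated"
    else if (length(supp) == 1) "individual"
    else "partial"
  list(status = status, replicates = supp)
}

# sites (row indices into freqs$sites) falling in a 0-based half-open interval
.sites_in_interval <- function(sites, interval) {
  which(sites$chrom == interval$chrom &
        sites$pos - 1L >= interval$start & sites$pos - 1L < interval$end)
}

# median frequency trajectory of a site set for one replicate;
# returns list(generations, median) using pooled per-sample frequencies
.median_trajectory <- function(freqs, site_idx, replicate) {
  sj <- which(freqs$samples$replicate == replicate)
  med <- apply(freqs$freq[site_idx, sj, drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  list(generations = freqs$samples$generation[sj], median = med)
}

#' Onset and fixation generation of a sweep
#'
#' Operational definition on sampled generations: the sweeping sites of an
#' interval are those whose final frequency reaches `fix_threshold` after
#' starting no higher than `start_max` (alleles already common at the
#' first sample carry no timing information). Fixation is the first
#' sampled generation at which their median frequency reaches
#' `fix_threshold`; onset is the last sampled generation before fixation
#' at which the median is still below `rise_threshold`. When the median
#' never visits `rise_threshold` (a haplotype lingering at intermediate
#' frequency before its final ascent, as after a late recombination
#' event), onset falls back to the last generation at which the median
#' was still within `plateau_slack` of its starting value (note
#' `"plateau_onset"`); if even that fails, the rise predates the first
#' sample (note `"pre_onset_unobserved"`).
#'
#' @param interval interval with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param freqs a [to_frequencies()] tensor.
#' @param replicate replicate id whose trajectory is used.
#' @param rise_threshold frequency below which the sweep has not started
#'   (default 0.1).
#' @param fix_threshold frequency treated as fixed (default 0.95).
#' @param start_max maximum first-sample frequency for a site to count as
#'   sweeping (default 0.5).
#' @param plateau_slack slack for the plateau fallback (default 0.1).
#' @return List with `onset`, `fixation` (sampled-generation labels),
#'   `note`, `n_sweeping`, `site_idx` and the median `trajectory`.
#' @export
estimate_onset_and_fixation <- function(interval, freqs, replicate,
                                        rise_threshold = 0.1,
                                        fix_threshold = 0.95,
                                        start_max = 0.5,
                                        plateau_slack = 0.1) {
  stopifnot(inherits(freqs, "freq_tensor"))
  idx <- .sites_in_interval(freqs$sites, interval)
  sj <- which(freqs$samples$replicate == replicate)
  if (length(sj) < 2) stop("replicate has < 2 samples")
  f <- freqs$freq[idx, sj, drop = FALSE]
  final <- f[, ncol(f)]
  first <- f[, 1L]
  sweeping <- !is.na(final) & final >= fix_threshold &
              (is.na(first) | first <= start_max)
  if (!any(sweeping)) stop("no sweep in interval")
  idx <- idx[sweeping]
  traj <- .median_trajectory(freqs, idx, replicate)
  g <- traj$generations; med <- traj$median

  fix_at <- which(med >= fix_threshold)[1]
  if (is.na(fix_at)) stop("no sweep in interval")
  note <- ""
  below <- which(med < rise_threshold & seq_along(med) < fix_at)
  if (length(below)) {
    onset <- g[max(below)]
  } else {
    plateau <- which(med <= med[1] + plateau_slack & seq_along(med) < fix_at)
    if (length(plateau)) { onset <- g[max(plateau)]; note <- "plateau_onset" }
    else { onset <- g[1]; note <- "pre_onset_unobserved" }
  }
  list(onset = onset, fixation = g[fix_at], note = note,
       n_sweeping = length(idx), site_idx = idx, trajectory = traj)
}

#' Hard versus soft sweep from final-frequency structure
#'
#' In a hard sweep every hitchhiker on the single carrier haplotype is
#' dragged to fixation; in a soft sweep from standing variation the
#' variants private to individual carrier haplotypes settle at the
#' carrier-haplotype frequencies instead. Among the interval's rising
#' sites (frequency increase >= `rise_min` across the sweep), a chi-square
#' statistic aggregates, over sites, the per-site goodness of fit of the
#' final counts to `Binomial(depth, 1 - eps)` — the hard-sweep null with
#' sequencing-error rate `eps`. If the null is rejected, the sites still
#' at intermediate frequency that never reach fixation at any later
#' sample are clustered (one-dimensional k-means, k = 2) and the sweep
#' is labelled soft only when the dominant
#' intermediate cluster is a coherent plateau: at least `min_cluster`
#' sites whose mean frequency sits away from both boundaries (Z statistic
#' against `eps` and `1 - eps` with the pooled binomial standard error)
#' and whose between-site dispersion is at most `overdispersion` times
#' binomial sampling variance — the signature of a shared haplotype.
#'
#' @param interval,freqs,replicate as in [estimate_onset_and_fixation()].
#' @param acm the [allele_counts()] object (final-generation depths are
#'   needed for the tests).
#' @param fixation_generation sampled generation at which the sweep is
#'   evaluated. Default `NULL`: the first sampled generation at which at
#'   least 30% of the sites that ever reach `fix_threshold` have done so —
#'   the completion of the sweep's shared component, where a soft
#'   plateau is freshest. (Mid-rise hitchhikers of a hard sweep cannot
#'   masquerade as a plateau because plateau candidates must never fix.)
#' @param rise_min minimum frequency increase for a site to enter the
#'   tests (default 0.25).
#' @param eps sequencing-error rate of the fixation null (default 0.01).
#' @param alpha rejection level for the chi-square and Z tests
#'   (default 1e-3).
#' @param min_cluster minimum plateau-cluster size (default 20).
#' @param overdispersion allowed variance inflation of the plateau
#'   (default 2).
#' @return List with `label` (`"hard"`, `"soft"` or `"unclassifiable"`),
#'   `chi2_stat`, `chi2_df`, `chi2_p`, `z_stat`, `z_p`, `n_rising`,
#'   `plateau_sites` (site indices) and `plateau_freq`.
#' @export
classify_hard_soft <- function(interval, acm, freqs, replicate,
                               fixation_generation = NULL, rise_min = 0.25,
                               eps = 0.01, alpha = 1e-3, min_cluster = 20,
                               overdispersion = 2, fix_threshold = 0.95) {
  idx <- .sites_in_interval(freqs$sites, interval)
  sj <- which(freqs$samples$replicate == replicate)
  gens <- freqs$samples$generation[sj]
  if (is.null(fixation_generation)) {
    f <- freqs$freq[idx, sj, drop = FALSE]
    ever <- which(apply(f >= fix_threshold, 1, any, na.rm = TRUE))
    if (!length(ever)) stop("no site reaches fix_threshold in interval")
    frac <- colMeans(f[ever, , drop = FALSE] >= fix_threshold, na.rm = TRUE)
    fixation_generation <- gens[which(frac >= 0.3)[1]]
  }
  jfix <- sj[match(fixation_generation, gens)]
  if (is.na(jfix)) stop("fixation_generation not sampled for replicate")
  j0 <- sj[1]
  # a site counts as a plateau candidate only if it never reaches
  # fixation at this or any later sample: the mid-rise sites of a hard
  # sweep all do, a drifting soft-sweep plateau does not
  later <- sj[match(fixation_generation, gens):length(sj)]
  fut_max <- apply(freqs$freq[idx, later, drop = FALSE], 1, max,
                   na.rm = TRUE)

  rise <- freqs$freq[idx, jfix] - freqs$freq[idx, j0]
  rising <- idx[!is.na(rise) & rise >= rise_min]
  out <- list(label = "unclassifiable", chi2_stat = NA_real_,
              chi2_df = NA_integer_, chi2_p = NA_real_,
              z_stat = NA_real_, z_p = NA_real_,
              n_rising = length(rising), plateau_sites = integer(),
              plateau_freq = NA_real_)
  if (length(rising) < 10) return(out)

  p_hat <- freqs$freq[rising, jfix]
  d <- freqs$depth[rising, jfix]
  z_site <- (p_hat - (1 - eps)) / sqrt(eps * (1 - eps) / d)
  out$chi2_stat <- sum(z_site^2)
  out$chi2_df <- length(rising)
  out$chi2_p <- stats::pchisq(out$chi2_stat, out$chi2_df, lower.tail = FALSE)

  if (out$chi2_p >= alpha) { out$label <- "hard"; return(out) }

  never_fix <- fut_max[match(rising, idx)] < fix_threshold
  inter <- p_hat < 0.9 & never_fix
  out$label <- "hard"   # rejected but no coherent plateau => heterogeneous
  if (sum(inter) >= min_cluster) {
    x <- p_hat[inter]
    dx <- d[inter]
    # candidate plateaus: the whole intermediate set first (a single
    # shared-haplotype plateau), then the two-component split (two
    # carrier lineages at distinct frequencies)
    cand <- list(rep(TRUE, length(x)))
    if (length(unique(round(x, 6))) > 1) {
      km <- stats::kmeans(x, 2, nstart = 10)
      ord <- order(-km$size)
      cand <- c(cand, list(km$cluster == ord[1], km$cluster == ord[2]))
    }
    for (sel in cand) {
      px <- x[sel]
      if (length(px) < min_cluster) next
      pbar <- mean(px)
      se <- sqrt(pbar * (1 - pbar) / sum(dx[sel]))
      z <- min(pbar - eps, (1 - eps) - pbar) / se
      z_p <- stats::pnorm(z, lower.tail = FALSE)
      if (is.na(out$z_stat)) { out$z_stat <- z; out$z_p <- z_p }
      binom_var <- mean(px * (1 - px) / dx[sel])
      if (z_p < alpha && stats::var(px) <= overdispersion * binom_var) {
        out$label <- "soft"
        out$plateau_sites <- rising[inter][sel]
        out$plateau_freq <- pbar
        out$z_stat <- z
        out$z_p <- z_p
        break
      }
    }
  }
  out
}

#' Lateness test for an individual sweep
#'
#' A sweep on extant (standing) variation under selection `s` should start
#' soon after the onset of selection; a sweep starting `t` generations
#' later than that is improbable under the standing null and points to a
#' de novo mutation or a recombination event. The p-value `t_p` is the
#' fraction of [lateness_null()] draws (standing variant at frequency
#' `p0`, selection `s`, conditioned on fixation) whose sweep-start time is
#' at least `t = onset_generation - selection_onset_generation`. The sweep
#' is called late when `t_p < 1e-3`.
#'
#' @param onset_generation observed sweep onset (sampled generation).
#' @param selection_onset_generation generation at which selection began
#'   (default 0, the start of the experiment).
#' @param s_hat selection coefficient of the sweep (> 0), e.g. the scan's
#'   maximizing `s`.
#' @param ne diploid effective population size.
#' @param p0 standing initial frequency of the null; defaults in the
#'   pipeline to the interval's median sweeping-site frequency at the
#'   first sampled generation, with fallback `1/(2 ne)`.
#' @param n_sims,seed Monte-Carlo settings.
#' @param null optional precomputed [lateness_null()] to reuse.
#' @return List with `t`, `t_p`, `late` (logical at the 1e-3 threshold)
#'   and the `null` object.
#' @export
lateness_test <- function(onset_generation, selection_onset_generation = 0,
                          s_hat, ne, p0, n_sims = 10000, seed = NULL,
                          null = NULL) {
  t_obs <- onset_generation - selection_onset_generation
  if (t_obs < 0) stop("onset precedes selection onset (t < 0)")
  if (is.null(null)) {
    stopifnot(s_hat > 0)
    null <- lateness_null(s_hat, ne, p0, n_sims = n_sims, seed = seed)
  }
  t_p <- mean(null$start_times >= t_obs)
  list(t = t_obs, t_p = t_p, late = t_p < 1e-3, null = null)
}

#' Trace a fixed haplotype back in time into founder clusters
#'
#' Takes the sites fixed at `fixation_generation` whose final ascent
#' happened during the sweep — still below 0.8 in the traced window, and
#' no higher than `max_initial_freq` at the first sample (alleles already
#' common at the start fix routinely and carry little haplotype
#' information) — and clusters their pre-fixation frequencies into two
#' components (k-means, k = 2, 10 restarts). Two well-separated clusters mean the fixed haplotype
#' existed as two distinct haplotypes earlier — the recombination
#' signature; a single cluster is consistent with one founding haplotype
#' (de novo origin). With an explicit `trace_generation` the clustering
#' is one-dimensional on that generation's frequencies; by default all
#' sampled pre-fixation generations at which the sites' mean frequency is
#' still below 0.8 are used jointly, which separates haplotypes whose
#' trajectories differ anywhere in that window rather than at one lucky
#' timepoint.
#'
#' @inheritParams estimate_onset_and_fixation
#' @param fixation_generation sampled generation of fixation.
#' @param trace_generation earlier sampled generation at which to look;
#'   default `NULL` clusters jointly over all sampled generations at
#'   which the fixed sites' mean frequency is below 0.8.
#' @param max_initial_freq bound on the first-sample frequency of traced
#'   sites (default 0.5).
#' @param min_cluster minimum sites per cluster (default 10).
#' @param min_sep minimum separation of cluster centres (default 0.1).
#' @param seed seed for the k-means restarts (fixed for determinism).
#' @return List with `single` (logical); when `FALSE`, `clusters` is a
#'   list of two lists (`site_idx`, `positions`, `freq`, `centre`).
#'   `trace_generation` is recorded either way.
#' @export
traceback_clusters <- function(interval, freqs, replicate,
                               fixation_generation, trace_generation = NULL,
                               fix_threshold = 0.95, max_initial_freq = 0.5,
                               min_cluster = 10, min_sep = 0.1, seed = 1) {
  idx <- .sites_in_interval(freqs$sites, interval)
  sj <- which(freqs$samples$replicate == replicate)
  gens <- freqs$samples$generation[sj]
  jfix <- match(fixation_generation, gens)
  if (is.na(jfix)) stop("fixation_generation not sampled")
  f <- freqs$freq[idx, sj, drop = FALSE]
  fixed <- !is.na(f[, jfix]) & f[, jfix] >= fix_threshold &
           (is.na(f[, 1]) | f[, 1] <= max_initial_freq)
  idx <- idx[fixed]
  f <- f[fixed, , drop = FALSE]
  if (!is.null(trace_generation)) {
    jt <- match(trace_generation, gens)
    if (is.na(jt)) stop("trace_generation not sampled")
    jt_use <- jt
  } else {
    mean_f <- colMeans(f, na.rm = TRUE)
    jt_use <- which(mean_f < 0.8 & seq_along(gens) < jfix)
    if (!length(jt_use))
      return(list(single = TRUE, trace_generation = NA_integer_,
                  reason = "no pre-fixation generation below 0.8"))
    trace_generation <- gens[max(jt_use)]
  }
  X <- f[, jt_use, drop = FALSE]
  # only sites whose final ascent happened during the traced sweep
  ascend <- !is.na(f[, jt_use[length(jt_use)]]) &
            f[, jt_use[length(jt_use)]] < 0.8
  ok <- stats::complete.cases(X) & ascend
  X <- X[ok, , drop = FALSE]; idx <- idx[ok]
  if (nrow(X) < 2 * min_cluster)
    return(list(single = TRUE, trace_generation = trace_generation,
                reason = "too few traceable sites"))
  if (nrow(unique(round(X, 6))) < 2)
    return(list(single = TRUE, trace_generation = trace_generation,
                reason = "identical frequencies"))
  # Cluster features: the centred trajectory (sites on one carrier
  # haplotype share its drift path through time) plus the mean level once
  # (not once per generation: a site's level is offset upward by every
  # additional background haplotype carrying it, so raw trajectories let
  # that nuisance gradient dominate the distance).
  feat <- if (ncol(X) > 1) {
    m <- rowMeans(X)
    cbind(X - m, m)
  } else X
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(feat, 2, nstart = 10)
  # robust trim: a haplotype's sites share one trajectory up to sampling
  # noise, while sites also carried on other backgrounds straggle between
  # the clusters; drop poor fits and re-cluster the coherent core
  d2 <- rowSums((feat - km$centers[km$cluster, , drop = FALSE])^2)
  keep <- d2 <= stats::median(d2) + 3 * stats::mad(d2) + 1e-12
  if (sum(keep) >= 2 * min_cluster) {
    km <- stats::kmeans(feat[keep, , drop = FALSE], 2, nstart = 10)
    X <- X[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  lab <- km$cluster
  cent <- rbind(colMeans(X[lab == 1L, , drop = FALSE]),
                colMeans(X[lab == 2L, , drop = FALSE]))
  sep <- max(abs(cent[1, ] - cent[2, ]))
  # two haplotypes are distinct if their frequency levels differ, or if
  # their trajectories are far apart relative to within-cluster spread
  # (levels can drift together while the paths remain distinguishable)
  d_feat <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
  s_within <- sqrt(km$tot.withinss / max(1, nrow(X) - 2))
  distinct <- sep >= min_sep || d_feat >= 2.5 * s_within
  if (!distinct || any(km$size < min_cluster))
    return(list(single = TRUE, trace_generation = trace_generation,
                reason = "clusters not separated"))
  mk <- function(g) list(site_idx = idx[lab == g],
                         positions = freqs$sites$pos[idx[lab == g]],
                         freq = X[lab == g, ncol(X)],
                         centre = unname(cent[g, ncol(X)]))
  list(single = FALSE, trace_generation = trace_generation,
       separation = sep, clusters = list(A = mk(1L), B = mk(2L)))
}

#' Spatial segregation of two traceback clusters
#'
#' A recombination-born haplotype is spatially structured: the sites
#' inherited from each parental haplotype lie on opposite sides of the
#' crossover. The Y statistic is a rank-sum comparison (normal
#' approximation, tie-corrected, two-sided) of the genomic positions of
#' the two clusters; the breakpoint estimate is the position boundary
#' minimizing the number of misplaced sites, with ties resolved at the
#' midpoint. If no boundary places more than 60% of sites correctly the
#' clusters are interleaved and no breakpoint is returned.
#'
#' @param cluster_a,cluster_b cluster entries from [traceback_clusters()]
#'   (or any lists with a `positions` field).
#' @return List with `y_stat` (the rank-sum z value), `y_p`,
#'   `breakpoint_pos` (1-based position or `NA`) and `misplaced_frac`.
#' @export
spatial_separation_test <- function(cluster_a, cluster_b) {
  pa <- sort(cluster_a$positions); pb <- sort(cluster_b$positions)
  if (!length(pa) || !length(pb)) stop("both clusters must be nonempty")
  na <- length(pa); nb <- length(pb); n <- na + nb
  r <- rank(c(pa, pb))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(pa, pb))
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (w - na * nb / 2) / sqrt(sig2) else 0
  y_p <- 2 * stats::pnorm(-abs(z))

  allp <- sort(unique(c(pa, pb)))
  cand <- c(allp[1] - 1, (allp[-length(allp)] + allp[-1]) / 2,
            allp[length(allp)] + 1)
  mis <- vapply(cand, function(b)
    min(sum(pa > b) + sum(pb < b), sum(pb > b) + sum(pa < b)), numeric(1))
  best <- which(mis == min(mis))
  bp <- stats::median(cand[best])
  frac <- min(mis) / n
  list(y_stat = z, y_p = y_p,
       breakpoint_pos = if (frac < 0.4) ceiling(bp) else NA_real_,
       misplaced_frac = frac)
}
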