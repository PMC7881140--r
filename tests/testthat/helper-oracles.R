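# Independent oracles used across tests. These are written as direct,
# slow re-derivations (stepwise vector recursions, explicit enumerations,
# closed forms) so they share no code path with the package internals
# they check.

# Hidden WF chain likelihood by stepwise single-generation propagation
# over the full count grid 0..2Ne, visiting every generation explicitly.
oracle_hmm_loglik <- function(alt, depth, gens, ne, s = 0, h = 0.5) {
  K <- 2 * ne + 1
  grid <- (0:(2 * ne)) / (2 * ne)
  q <- 1 - grid
  pstar <- if (s == 0) grid else
    (grid^2 * (1 + s) + grid * q * (1 + h * s)) /
    (grid^2 * (1 + s) + 2 * grid * q * (1 + h * s) + q^2)
  T1 <- outer(pstar, 0:(2 * ne), function(p, j) dbinom(j, 2 * ne, p))
  allg <- gens[1]:gens[length(gens)]
  obs <- match(allg, gens)
  v <- c(0, rep(1 / (K - 2), K - 2), 0)
  if (!is.na(obs[1]) && depth[obs[1]] > 0)
    v <- v * dbinom(alt[obs[1]], depth[obs[1]], grid)
  for (t in seq_along(allg)[-1]) {
    v <- as.vector(v %*% T1)
    k <- obs[t]
    if (!is.na(k) && depth[k] > 0) v <- v * dbinom(alt[k], depth[k], grid)
  }
  log(sum(v))
}

# likelihood by exhaustive enumeration over hidden states at the sampled
# generations (gap transitions built by explicit repeated multiplication)
oracle_hmm_enum <- function(alt, depth, gens, ne, s = 0, h = 0.5) {
  K <- 2 * ne + 1
  grid <- (0:(2 * ne)) / (2 * ne)
  q <- 1 - grid
  pstar <- if (s == 0) grid else
    (grid^2 * (1 + s) + grid * q * (1 + h * s)) /
    (grid^2 * (1 + s) + 2 * grid * q * (1 + h * s) + q^2)
  T1 <- outer(pstar, 0:(2 * ne), function(p, j) dbinom(j, 2 * ne, p))
  gap_mat <- lapply(diff(gens), function(g) {
    M <- diag(K)
    for (i in seq_len(g)) M <- M %*% T1
    M
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), length(gens))))
  prior <- c(0, rep(1 / (K - 2), K - 2), 0)
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    st <- paths[i, ]
    pr <- prior[st[1]]
    if (depth[1] > 0) pr <- pr * dbinom(alt[1], depth[1], grid[st[1]])
    for (t in seq_along(gap_mat)) {
      pr <- pr * gap_mat[[t]][st[t], st[t + 1]]
      if (depth[t + 1] > 0)
        pr <- pr * dbinom(alt[t + 1], depth[t + 1], grid[st[t + 1]])
    }
    tot <- tot + pr
  }
  log(tot)
}

# neutral unlinked pool-seq dataset on the count scale (loop-based)
oracle_neutral_acm <- function(n_sites, ne, gens, depth, pool, seed,
                               replicate = "R1", p0 = NULL) {
  set.seed(seed)
  if (is.null(p0)) {
    w <- 1 / (1:26)
    p0 <- sample(1:26, n_sites, TRUE, w / sum(w)) / 27
  }
  p0 <- rep_len(p0, n_sites)
  ref <- alt <- matrix(0L, n_sites, length(gens))
  for (i in seq_len(n_sites)) {
    cnt <- round(p0[i] * 2 * ne)
    g_prev <- gens[1]
    for (j in seq_along(gens)) {
      if (j > 1) for (g in seq_len(gens[j] - g_prev))
        cnt <- rbinom(1, 2 * ne, cnt / (2 * ne))
      g_prev <- gens[j]
      in_pool <- rhyper(1, cnt, 2 * ne - cnt, pool)
      d <- rpois(1, depth)
      a <- rbinom(1, d, in_pool / pool)
      ref[i, j] <- d - a; alt[i, j] <- a
    }
  }
  allele_counts(
    data.frame(chrom = "sim1", pos = seq_len(n_sites) * 1000L,
               ref_allele = "A", alt_allele = "T"),
    data.frame(replicate = replicate, generation = gens,
               pool_chromosomes = pool),
    ref, alt)
}

# frequency tensor built directly from a per-site trajectory matrix
# (sites x generations), one replicate, exact depths
make_freq_tensor <- function(traj, gens, positions = NULL,
                             replicate = "R1", depth = 100L,
                             chrom = "sim1") {
  n <- nrow(traj)
  if (is.null(positions)) positions <- seq_len(n) * 1000L
  alt <- round(traj * depth)
  acm <- allele_counts(
    data.frame(chrom = chrom, pos = as.integer(positions),
               ref_allele = "A", alt_allele = "T"),
    data.frame(replicate = replicate, generation = gens,
               pool_chromosomes = 200L),
    depth - alt, alt)
  list(acm = acm, freqs = to_frequencies(acm))
}

# fake one-window scan rows (class sweep_scan) for classifier branch tests
fake_scan <- function(replicates, lr, chrom = "sim1", start = 0L,
                      end = 60000L, s_hat = 0.5, g = c(0, 100)) {
  d <- data.frame(replicate = replicates, chrom = chrom, start = start,
                  end = end, g_start = g[1], g_end = g[2],
                  n_sites = 50L, s_hat = s_hat, lr_stat = lr,
                  ne_used = 200, stringsAsFactors = FALSE)
  class(d) <- c("sweep_scan", "data.frame")
  d
}
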