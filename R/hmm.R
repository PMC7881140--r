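# Hidden Wright-Fisher Markov chain: transition matrices over an
# allele-frequency state grid and binomial read-count emissions. The state
# space is the exact count grid 0..2Ne when 2Ne+1 <= max_states, otherwise
# a frequency grid of max_states points with mass-preserving linear
# binning of the binomial transition kernel.

.state_freqs <- function(n_e, max_states) {
  if (2L * n_e + 1L <= max_states) (0:(2L * n_e)) / (2L * n_e)
  else seq(0, 1, length.out = max_states)
}

# rows: Binomial(2Ne, f_i) over counts, binned onto the state grid
.wf_step_matrix <- function(n_e, freqs, grid) {
  two_ne <- 2L * n_e
  K <- length(grid)
  exact <- K == two_ne + 1L
  T1 <- matrix(0, length(freqs), K)
  if (exact) {
    for (i in seq_along(freqs))
      T1[i, ] <- stats::dbinom(0:two_ne, two_ne, freqs[i])
  } else {
    x <- (0:two_ne) / two_ne * (K - 1)   # fractional grid coordinate
    lo <- pmin(floor(x), K - 2)
    whi <- x - lo
    ilo <- lo + 1L
    for (i in seq_along(freqs)) {
      d <- stats::dbinom(0:two_ne, two_ne, freqs[i])
      row <- numeric(K)
      # split each count's mass between the bracketing grid points
      row[seq_len(K)] <- 0
      acc_lo <- rowsum(d * (1 - whi), ilo)
      acc_hi <- rowsum(d * whi, ilo + 1L)
      row[as.integer(rownames(acc_lo))] <- acc_lo
      idx <- as.integer(rownames(acc_hi))
      row[idx] <- row[idx] + acc_hi
      T1[i, ] <- row
    }
  }
  T1
}

.mat_pow <- function(M, n) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  R <- diag(nrow(M))
  P <- M
  while (n > 0L) {
    if (n %% 2L == 1L) R <- R %*% P
    n <- n %/% 2L
    if (n > 0L) P <- P %*% P
  }
  R
}

#' Neutral Wright-Fisher transition matrix
#'
#' Row-stochastic transition matrix of the neutral Wright-Fisher Markov
#' chain over allele-frequency states: from state with frequency `p`, the
#' next generation's allele count is `Binomial(2 n_e, p)`. States 0 and
#' `2 n_e` are absorbing. The `n_generations`-step matrix is computed by
#' repeated squaring. For `2 n_e + 1 > max_states` the chain is binned to
#' a `max_states`-point frequency grid with mass-preserving linear
#' interpolation.
#'
#' @param n_e diploid effective population size (>= 1).
#' @param n_generations number of generations (>= 0; 0 gives the identity).
#' @param max_states state-space cap (default 401, exact up to Ne = 200).
#' @return A `length(grid) x length(grid)` row-stochastic matrix with the
#'   state frequencies in `attr(, "freqs")`.
#' @export
wf_transition_matrix <- function(n_e, n_generations = 1, max_states = 401) {
  selection_transition_matrix(n_e, s = 0, h = 0.5,
                              n_generations = n_generations,
                              max_states = max_states)
}

#' Wright-Fisher transition matrix with selection
#'
#' As [wf_transition_matrix()], but the offspring allele count is drawn
#' around the post-selection frequency
#' \deqn{p^* = \frac{p^2(1+s) + p(1-p)(1+hs)}{p^2(1+s) + 2p(1-p)(1+hs) + (1-p)^2},}
#' i.e. genotype fitnesses 1, 1+hs, 1+s. `s = 0` reduces exactly to the
#' neutral chain; frequencies 0 and 1 remain absorbing for any `s`.
#'
#' @inheritParams wf_transition_matrix
#' @param s selection coefficient (> -1).
#' @param h dominance.
#' @export
selection_transition_matrix <- function(n_e, s, h = 0.5, n_generations = 1,
                                        max_states = 401) {
  if (n_e < 1) stop("n_e must be >= 1")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (s <= -1) stop("s must be > -1")
  n_e <- as.integer(n_e)
  grid <- .state_freqs(n_e, max_states)
  T1 <- .wf_step_matrix(n_e, .post_selection(grid, s, h), grid)
  Tn <- if (n_generations == 1L) T1 else .mat_pow(T1, n_generations)
  attr(Tn, "freqs") <- grid
  Tn
}

# Forward pass of the hidden WF chain for many sites at once.
# alt, depth: S x T matrices; gens: sampled generations (length T);
# step1: one-generation transition matrix with attr "freqs".
# Emission at a sampled generation is Binomial(depth, f_state); depth 0
# contributes nothing (missing data skipped, not imputed). The initial
# hidden state is uniform over non-absorbing states, conditioned on the
# first observation. Returns the per-site log-likelihood vector.
.forward_loglik <- function(alt, depth, gens, step1, emis_list = NULL) {
  grid <- attr(step1, "freqs")
  K <- length(grid)
  S <- nrow(alt)
  gaps <- diff(gens)
  if (any(gaps <= 0)) stop("generations must be strictly increasing")

  emis <- if (is.null(emis_list)) function(t) {
    E <- matrix(1, S, K)
    obs <- depth[, t] > 0
    if (any(obs)) {
      a <- alt[obs, t]; d <- depth[obs, t]
      E[obs, ] <- .emission_matrix(a, d, grid)
    }
    E
  } else function(t) emis_list[[t]]

  prior <- c(0, rep(1 / (K - 2), K - 2L), 0)
  Fm <- matrix(prior, S, K, byrow = TRUE) * emis(1L)
  sc <- rowSums(Fm)
  if (any(sc == 0)) stop("zero likelihood at first observation")
  ll <- log(sc)
  Fm <- Fm / sc

  # powers of the one-step matrix, cached per distinct gap
  pow <- new.env(parent = emptyenv())
  step_for <- function(g) {
    key <- as.character(g)
    if (is.null(pow[[key]])) pow[[key]] <- .mat_pow(step1, g)
    pow[[key]]
  }

  for (t in seq_along(gaps)) {
    Fm <- (Fm %*% step_for(gaps[t])) * emis(t + 1L)
    sc <- rowSums(Fm)
    bad <- sc == 0          # numerically impossible trajectory
    if (any(bad)) { sc[bad] <- .Machine$double.xmin; Fm[bad, ] <- 1 / K }
    ll <- ll + log(sc)
    Fm <- Fm / sc
  }
  ll
}

# emission probabilities, one dbinom call per state column
.emission_matrix <- function(a, d, grid) {
  vapply(grid, function(f) stats::dbinom(a, d, f), numeric(length(a)))
}

# precompute per-timepoint emission matrices (shared across s values)
.emissions_for <- function(alt, depth, grid) {
  K <- length(grid)
  lapply(seq_len(ncol(alt)), function(t) {
    E <- matrix(1, nrow(alt), K)
    obs <- depth[, t] > 0
    if (any(obs))
      E[obs, ] <- .emission_matrix(alt[obs, t], depth[obs, t], grid)
    E
  })
}

#' Hidden-Markov log-likelihood of one site's count trajectory
#'
#' Forward log-likelihood of observed pooled counts at one site across
#' sampled generations under the Wright-Fisher chain with selection
#' coefficient `s`: hidden true frequencies follow
#' [selection_transition_matrix()] raised to each inter-sample gap, and
#' each sampled generation emits `alt ~ Binomial(depth, f_state)` (pool
#' subsampling folded into the emission). The initial hidden state is
#' uniform over non-absorbing states, conditioned on the first
#' observation. Samples with depth 0 are skipped.
#'
#' @param ref,alt integer vectors of reference/alternate counts per
#'   sampled generation.
#' @param generations sampled generations (strictly increasing).
#' @param n_e diploid effective population size.
#' @param s,h selection coefficient and dominance of the hidden chain.
#' @param max_states state-space cap (see [wf_transition_matrix()]).
#' @return The log-likelihood (numeric scalar).
#' @export
site_log_likelihood <- function(ref, alt, generations, n_e, s = 0, h = 0.5,
                                max_states = 401) {
  depth <- ref + alt
  if (all(depth == 0)) stop("all depths are zero")
  if (sum(depth > 0) < 2) stop("need >= 2 generations with depth > 0")
  step1 <- selection_transition_matrix(n_e, s, h, 1L, max_states)
  .forward_loglik(matrix(alt, 1), matrix(depth, 1), generations, step1)
}

#' Per-site composite likelihood-ratio statistic for selection
#'
#' Maximizes the hidden-Markov likelihood of [site_log_likelihood()] over
#' a grid of selection coefficients and returns
#' `lr = 2 (max_s log L(s) - log L(0))` together with the maximizing `s`.
#' The grid must contain 0, so `lr >= 0`.
#'
#' @inheritParams site_log_likelihood
#' @param s_grid selection-coefficient grid including 0.
#' @return List with elements `lr` and `s_hat`.
#' @export
site_lr <- function(ref, alt, generations, n_e,
                    s_grid = c(0, -0.05, 0.05, -0.1, 0.1, 0.2, 0.3, 0.5,
                               0.8, 1),
                    h = 0.5, max_states = 401) {
  if (!any(s_grid == 0)) stop("s_grid must contain 0")
  ll <- vapply(s_grid, function(s)
    site_log_likelihood(ref, alt, generations, n_e, s, h, max_states),
    numeric(1))
  best <- which.max(ll)
  lr <- 2 * (ll[best] - ll[s_grid == 0])
  if (lr < 1e-9) { best <- which(s_grid == 0); lr <- 0 }
  list(lr = max(lr, 0), s_hat = s_grid[best])
}
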