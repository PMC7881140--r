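test_that("transition matrices are stochastic with absorbing boundaries", {
  for (ne in c(4, 25)) for (s in c(0, 0.5, -0.3)) {
    Tm <- selection_transition_matrix(ne, s, 0.5, 3)
    expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
    expect_equal(Tm[1, 1], 1)                  # frequency 0 absorbing
    expect_equal(Tm[nrow(Tm), ncol(Tm)], 1)    # frequency 1 absorbing
  }
  # s = 0 reduces exactly to the neutral chain
  expect_equal(unclass(selection_transition_matrix(10, 0, 0.5, 4)),
               unclass(wf_transition_matrix(10, 4)), tolerance = 0)
  # zero generations give the identity
  expect_equal(max(abs(wf_transition_matrix(5, 0) - diag(11))), 0)
  expect_error(wf_transition_matrix(0, 1))
  expect_error(selection_transition_matrix(10, -1, 0.5, 1), "s must be")
})

test_that("multi-generation matrix equals explicit stepwise products", {
  ne <- 4
  T1 <- wf_transition_matrix(ne, 1)
  T3 <- wf_transition_matrix(ne, 3)
  expect_lt(max(abs(T3 - T1 %*% T1 %*% T1)), 1e-12)
  Ts <- selection_transition_matrix(ne, 0.5, 0.5, 2)
  T1s <- selection_transition_matrix(ne, 0.5, 0.5, 1)
  expect_lt(max(abs(Ts - T1s %*% T1s)), 1e-12)
})

test_that("binned chain conserves mass and drift mean", {
  Tm <- wf_transition_matrix(500, 1, max_states = 201)
  expect_equal(length(attr(Tm, "freqs")), 201)
  expect_lt(max(abs(rowSums(Tm) - 1)), 1e-9)
  # binning is mass-preserving linear interpolation: E[p'] = p exactly
  f <- attr(Tm, "freqs")
  expect_equal(as.vector(Tm %*% f), f, tolerance = 1e-9)
})

test_that("site likelihood matches exhaustive path enumeration (2N = 8)", {
  alt <- c(2, 3, 4); depth <- c(5, 5, 5); gens <- c(0, 3, 7)
  for (s in c(0, 0.5)) {
    got <- site_log_likelihood(depth - alt, alt, gens, n_e = 4, s = s)
    want <- oracle_hmm_enum(alt, depth, gens, ne = 4, s = s)
    expect_equal(got, want, tolerance = 1e-9)
    # stepwise per-generation propagation agrees too
    expect_equal(got, oracle_hmm_loglik(alt, depth, gens, ne = 4, s = s),
                 tolerance = 1e-9)
  }
  # missing data (depth 0) skipped, not imputed
  got <- site_log_likelihood(c(3, 0, 1), c(2, 0, 4), gens, n_e = 4)
  want <- oracle_hmm_loglik(c(2, 0, 4), c(5, 0, 5), gens, ne = 4)
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(site_log_likelihood(c(0, 0), c(0, 0), c(0, 5), 4),
               "depths")
})

test_that("likelihood responds to drift magnitude in the expected direction", {
  # no change at high depth: larger Ne (less drift) fits better
  expect_gt(site_log_likelihood(c(50, 50), c(50, 50), c(0, 10), 1000),
            site_log_likelihood(c(50, 50), c(50, 50), c(0, 10), 10))
  # a 0.1 -> 0.9 jump: small Ne fits better
  expect_gt(site_log_likelihood(c(90, 10), c(10, 90), c(0, 10), 10),
            site_log_likelihood(c(90, 10), c(10, 90), c(0, 10), 1000))
})

test_that("per-site likelihood ratio behaves like a proper scan statistic", {
  gens <- c(0, 10, 20)
  rising <- site_lr(c(90, 50, 10), c(10, 50, 90), gens, 200)
  flat <- site_lr(c(50, 50, 50), c(50, 50, 50), gens, 200)
  expect_gt(rising$s_hat, 0)
  expect_gt(rising$lr, flat$lr)
  expect_equal(flat$s_hat, 0)
  expect_equal(flat$lr, 0, tolerance = 1e-6)
  expect_error(site_lr(c(5, 5), c(5, 5), c(0, 5), 200,
                       s_grid = c(0.1, 0.5)), "contain 0")
  # toy-size check against enumeration: lr from the same grid
  alt <- c(1, 3, 5); depth <- c(6, 6, 6); g <- c(0, 2, 4)
  sg <- c(0, 0.3, 0.8)
  ll <- vapply(sg, function(s) oracle_hmm_enum(alt, depth, g, 4, s),
               numeric(1))
  want_lr <- 2 * (max(ll) - ll[1])
  got <- site_lr(depth - alt, alt, g, 4, s_grid = sg)
  expect_equal(got$lr, want_lr, tolerance = 1e-9)
  expect_equal(got$s_hat, sg[which.max(ll)])
})
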