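# shared small dataset: one replicate, 25-generation hard sweep
local_sweep_acm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- make_scenario("hard", n_generations = 30, n_diploids = 200,
                           n_loci = 400, genome_length = 2e6, s = 0.8,
                           recomb_rate = 0.25, sel_position = 0.37,
                           seed = 90)
      for (i in 1:10) {
        res <- simulate_wf(cfg, seed = 900 + i)
        if (res$true_freqs[cfg$selected_loci$locus,
                           ncol(res$true_freqs)] > 0.9) break
      }
      acm <- pool_sequence(res, c(0, 10, 20, 30), "R1", 200, 100,
                           seed = 91)
      cache <<- list(acm = acm, cfg = cfg)
    }
    cache
  }
})

test_that("windows score the sweep locus highest and lr is nonnegative", {
  d <- local_sweep_acm()
  sc <- scan_selection(d$acm, list(c(0, 30)), window_bp = 2e5,
                       step_bp = 1e5, ne = 200, max_states = 101)
  expect_true(all(sc$lr_stat >= 0))
  expect_true(all(sc$s_hat %in% c(0, -0.05, 0.05, -0.1, 0.1, 0.2, 0.3,
                                  0.5, 0.8, 1)))
  top <- sc[which.max(sc$lr_stat), ]
  pos <- d$cfg$positions[d$cfg$selected_loci$locus]
  expect_true(pos - 1 >= top$start && pos - 1 < top$end)
  expect_gt(top$s_hat, 0)
})

test_that("window scores equal the sum of per-site likelihood ratios", {
  d <- local_sweep_acm()
  sc <- scan_selection(d$acm, list(c(0, 30)), 2e5, 2e5, 200,
                       max_states = 101)
  w <- sc[3, ]   # an arbitrary non-empty window
  idx <- which(d$acm$sites$pos - 1 >= w$start &
               d$acm$sites$pos - 1 < w$end &
               rowSums(d$acm$alt) > 0)
  manual <- sum(vapply(idx, function(i)
    site_lr(d$acm$ref[i, ], d$acm$alt[i, ], c(0, 10, 20, 30), 200,
            max_states = 101)$lr, numeric(1)))
  expect_equal(w$lr_stat, manual, tolerance = 1e-6)
  expect_equal(w$n_sites, length(idx))
})

test_that("fixed and span-estimated Ne flag the same top window", {
  d <- local_sweep_acm()
  fixed <- scan_selection(d$acm, list(c(0, 30)), 2e5, 1e5, ne = 200,
                          max_states = 101)
  est <- scan_selection(d$acm, list(c(0, 30)), 2e5, 1e5,
                        ne = "estimate", max_states = 101,
                        ne_grid = c(50, 100, 200, 400, 800))
  expect_equal(est$start[which.max(est$lr_stat)],
               fixed$start[which.max(fixed$lr_stat)])
})

test_that("spans without two sampled generations are skipped with warning", {
  d <- local_sweep_acm()
  expect_warning(
    sc <- scan_selection(d$acm, list(c(0, 30), c(25, 28)), 2e5, 1e5,
                         200, max_states = 101),
    "skipped")
  expect_true(all(sc$g_end == 30))
})

test_that("empirical null threshold has monotone quantiles", {
  th50 <- neutral_threshold(200, 100, 200, c(0, 10, 20, 30), 30,
                            n_windows_sim = 4000, quantile_p = 0.5,
                            n_site_pool = 1500, seed = 5,
                            max_states = 101)
  th999 <- neutral_threshold(200, 100, 200, c(0, 10, 20, 30), 30,
                             n_windows_sim = 4000, quantile_p = 0.999,
                             n_site_pool = 1500, seed = 5,
                             max_states = 101)
  expect_gt(th999, th50)
  q <- attr(th999, "quantiles")
  expect_true(all(diff(q) >= 0))
})

test_that("long spans widen the neutral null (small-Ne drift caveat)", {
  # Ne well below 200: drift over 120 generations produces much larger
  # frequency excursions than over 30, inflating the null quantiles
  short <- neutral_threshold(150, 100, 200, c(0, 10, 20, 30), 40,
                             n_windows_sim = 4000, quantile_p = 0.999,
                             p0 = 0.5, n_site_pool = 1500, seed = 6,
                             max_states = 101)
  long <- neutral_threshold(150, 100, 200, c(0, 40, 80, 120), 40,
                            n_windows_sim = 4000, quantile_p = 0.999,
                            p0 = 0.5, n_site_pool = 1500, seed = 6,
                            max_states = 101)
  expect_gt(long, short)
})

test_that("significant windows merge into replicate-annotated intervals", {
  sc <- fake_scan(rep(c("R1", "R2"), each = 3), lr = c(90, 10, 80, 95, 9, 8))
  sc$start <- c(0, 50000, 100000, 0, 50000, 100000)
  sc$end <- sc$start + 50000
  out <- significant_intervals(sc, 50)
  expect_equal(nrow(out), 2)
  expect_equal(out$replicates, c("R1,R2", "R1"))
  # a merge gap bridges the sub-threshold valley
  out2 <- significant_intervals(sc, 50, merge_gap = 60000)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$n_replicates, 2L)
  empty <- significant_intervals(sc, 1e9)
  expect_equal(nrow(empty), 0)
})
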