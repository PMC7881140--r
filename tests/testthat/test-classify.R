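test_that("replication status distinguishes replicated/individual/partial", {
  int <- list(chrom = "sim1", start = 0, end = 60000)
  sc <- fake_scan(c("R1", "R2", "R3"), lr = c(100, 90, 80))
  expect_equal(replication_status(int, sc, 50)$status, "replicated")
  expect_equal(replication_status(int, sc, 95)$status, "individual")
  expect_equal(replication_status(int, sc, 95)$replicates, "R1")
  expect_equal(replication_status(int, sc, 85)$status, "partial")
  expect_equal(replication_status(int, sc, 1e6)$status, "none")
  expect_error(replication_status(int, fake_scan("R1", 10), 5), ">= 2")
  # windows outside the interval do not count
  far <- list(chrom = "sim1", start = 1e6, end = 2e6)
  expect_equal(replication_status(far, sc, 50)$status, "none")
})

test_that("onset and fixation follow the sampled-generation definition", {
  d <- make_freq_tensor(matrix(c(0.05, 0.06, 0.40, 0.97), 1),
                        gens = c(0, 17, 34, 59))
  # single site rising 0.05 -> 0.97: onset = last generation below 0.1
  int <- list(chrom = "sim1", start = 0, end = 10000)
  o <- estimate_onset_and_fixation(int, d$freqs, "R1")
  expect_equal(o$onset, 17)
  expect_equal(o$fixation, 59)
  expect_equal(o$note, "")

  # already fixed at the first sample: flagged, onset = first generation
  d2 <- make_freq_tensor(matrix(c(0.97, 0.98, 1, 1), 1), c(0, 17, 34, 59))
  o2 <- estimate_onset_and_fixation(int, d2$freqs, "R1", start_max = 1)
  expect_equal(o2$onset, 0)
  expect_equal(o2$note, "pre_onset_unobserved")

  # intermediate plateau then late ascent: plateau fallback
  d3 <- make_freq_tensor(matrix(c(0.30, 0.33, 0.31, 0.35, 0.85, 0.99), 1),
                         c(0, 20, 40, 60, 80, 100))
  o3 <- estimate_onset_and_fixation(int, d3$freqs, "R1", start_max = 0.5)
  expect_equal(o3$onset, 60)
  expect_equal(o3$note, "plateau_onset")

  # nothing reaches fixation: error
  d4 <- make_freq_tensor(matrix(c(0.05, 0.2, 0.5, 0.6), 1), c(0, 17, 34, 59))
  expect_error(estimate_onset_and_fixation(int, d4$freqs, "R1"),
               "no sweep")
})

test_that("hard/soft classification reads the final-frequency structure", {
  set.seed(77)
  gens <- c(0, 20, 40, 60)
  int <- list(chrom = "sim1", start = 0, end = 1e6)
  depth <- 100L

  # hard: 60 rising sites all at fixation (sequencing error only)
  n <- 60
  traj <- cbind(runif(n, 0.02, 0.1), runif(n, 0.3, 0.5),
                runif(n, 0.85, 0.95), rbinom(n, depth, 0.995) / depth)
  d <- make_freq_tensor(traj, gens, depth = depth)
  hs <- classify_hard_soft(int, d$acm, d$freqs, "R1", 60)
  expect_equal(hs$label, "hard")
  expect_gt(hs$chi2_p, 1e-3)

  # soft: 40 sites fix, 30 plateau coherently near 0.45
  plat <- rbinom(30, depth, 0.45) / depth
  traj2 <- rbind(
    cbind(runif(40, 0.02, 0.1), runif(40, 0.3, 0.5),
          runif(40, 0.85, 0.95), rbinom(40, depth, 0.995) / depth),
    cbind(runif(30, 0.02, 0.1), runif(30, 0.2, 0.35),
          plat + rnorm(30, 0, 0.01), plat))
  d2 <- make_freq_tensor(traj2, gens, depth = depth)
  hs2 <- classify_hard_soft(int, d2$acm, d2$freqs, "R1", 60)
  expect_equal(hs2$label, "soft")
  expect_lt(hs2$chi2_p, 1e-3)
  expect_lt(hs2$z_p, 1e-3)
  expect_gte(length(hs2$plateau_sites), 20)
  expect_equal(hs2$plateau_freq, mean(plat), tolerance = 0.05)

  # fewer than 10 rising sites: unclassifiable
  d3 <- make_freq_tensor(traj[1:5, ], gens, depth = depth)
  expect_equal(classify_hard_soft(int, d3$acm, d3$freqs, "R1", 60)$label,
               "unclassifiable")
})

test_that("traceback separates two-haplotype history from one", {
  set.seed(78)
  gens <- c(0, 30, 60, 90, 120)
  int <- list(chrom = "sim1", start = 0, end = 1e6)
  noise <- function(n, p) rbinom(n, 100, p) / 100
  # two clusters: left sites near 0.2, right sites near 0.5, then joint rise
  n_half <- 15
  trajA <- cbind(noise(n_half, 0.15), noise(n_half, 0.15),
                 noise(n_half, 0.18), noise(n_half, 0.45), rep(1, n_half))
  trajB <- cbind(noise(n_half, 0.4), noise(n_half, 0.4),
                 noise(n_half, 0.42), noise(n_half, 0.7), rep(1, n_half))
  pos <- c(seq(1000, 150000, length.out = n_half),
           seq(300000, 450000, length.out = n_half))
  d <- make_freq_tensor(rbind(trajA, trajB), gens, positions = pos)
  tb <- traceback_clusters(int, d$freqs, "R1", 120)
  expect_false(tb$single)
  cents <- sort(c(tb$clusters$A$centre, tb$clusters$B$centre))
  expect_gt(diff(cents), 0.1)
  sp <- spatial_separation_test(tb$clusters$A, tb$clusters$B)
  expect_lt(sp$y_p, 1e-3)
  expect_true(sp$breakpoint_pos > 150000 && sp$breakpoint_pos <= 300000)

  # single haplotype: all sites share one trajectory
  traj1 <- cbind(noise(30, 0.15), noise(30, 0.18), noise(30, 0.2),
                 noise(30, 0.7), rep(1, 30))
  d1 <- make_freq_tensor(traj1, gens)
  tb1 <- traceback_clusters(int, d1$freqs, "R1", 120)
  expect_true(tb1$single)

  # identical earlier frequencies: single cluster by construction
  trajE <- cbind(rep(0.3, 25), rep(0.3, 25), rep(0.35, 25), rep(1, 25),
                 rep(1, 25))
  dE <- make_freq_tensor(trajE, gens)
  tbE <- traceback_clusters(int, dE$freqs, "R1", 90,
                            trace_generation = 30)
  expect_true(tbE$single)
  expect_error(traceback_clusters(int, d$freqs, "R1", 120,
                                  trace_generation = 45), "not sampled")
})

test_that("the rank-sum spatial test matches wilcox.test and finds breakpoints", {
  a <- list(positions = 1:50)
  b <- list(positions = 51:100)
  sp <- spatial_separation_test(a, b)
  expect_lt(sp$y_p, 1e-10)
  expect_equal(sp$misplaced_frac, 0)
  expect_true(sp$breakpoint_pos > 50 && sp$breakpoint_pos <= 51)

  inter <- list(positions = seq(1, 99, by = 2))
  other <- list(positions = seq(2, 100, by = 2))
  sp2 <- spatial_separation_test(inter, other)
  expect_gt(sp2$y_p, 0.5)
  expect_true(is.na(sp2$breakpoint_pos))

  # normal approximation agrees with wilcox.test on untied data
  set.seed(3)
  pa <- sample(1:1000, 40); pb <- sample(1001:1500, 30)
  sp3 <- spatial_separation_test(list(positions = pa),
                                 list(positions = pb))
  w <- stats::wilcox.test(pa, pb, correct = FALSE, exact = FALSE)
  expect_equal(sp3$y_p, w$p.value, tolerance = 1e-9)
})

test_that("the decision tree takes the documented branches", {
  set.seed(79)
  gens <- c(0, 20, 40, 60, 80, 100)
  depth <- 100L
  noise <- function(n, p) rbinom(n, depth, p) / depth
  n <- 50
  mk_data <- function(traj, pos, reps = "R1") {
    pieces <- lapply(reps, function(r)
      make_freq_tensor(traj, gens, positions = pos, replicate = r,
                       depth = depth)$acm)
    do.call(combine_replicates, pieces)
  }
  pos <- sort(sample(1:500000, n))
  int <- data.frame(chrom = "sim1", start = 0, end = 500000)

  # replicated, everything fixes -> hard
  traj_hard <- cbind(noise(n, 0.05), noise(n, 0.1), noise(n, 0.4),
                     noise(n, 0.9), noise(n, 0.995), noise(n, 0.995))
  acm <- mk_data(traj_hard, pos, c("R1", "R2", "R3"))
  sc <- fake_scan(c("R1", "R2", "R3"), c(500, 480, 460), end = 500000L,
                  g = c(0, 100))
  call <- classify_mechanism(int, acm, sc, threshold = 100, ne = 200)
  expect_equal(call$status, "replicated")
  expect_equal(call$mechanism, "hard")

  # replicated with a coherent plateau -> soft
  plat <- rbinom(25, depth, 0.5) / depth
  traj_soft <- rbind(traj_hard[1:25, ],
                     cbind(noise(25, 0.05), noise(25, 0.15), noise(25, 0.3),
                           noise(25, 0.45), plat + rnorm(25, 0, 0.01), plat))
  acm2 <- mk_data(traj_soft, pos, c("R1", "R2", "R3"))
  call2 <- classify_mechanism(int, acm2, sc, threshold = 100, ne = 200)
  expect_equal(call2$mechanism, "soft")
  expect_lt(call2$chi2_p, 1e-3)

  # individual + late + spatially segregated clusters -> FM recombination
  nh <- 25
  trajA <- cbind(noise(nh, 0.2), noise(nh, 0.2), noise(nh, 0.22),
                 noise(nh, 0.25), noise(nh, 0.7), rep(1, nh))
  trajB <- cbind(noise(nh, 0.42), noise(nh, 0.45), noise(nh, 0.42),
                 noise(nh, 0.45), noise(nh, 0.75), rep(1, nh))
  pos_seg <- c(sort(sample(1:200000, nh)), sort(sample(300000:500000, nh)))
  acm3 <- mk_data(rbind(trajA, trajB), pos_seg, "R1")
  sc3 <- fake_scan(c("R1", "R2"), c(500, 10), end = 500000L,
                   g = c(0, 100))
  call3 <- classify_mechanism(int, acm3, sc3, threshold = 100, ne = 200)
  expect_equal(call3$status, "individual")
  expect_lt(call3$t_p, 1e-3)
  expect_equal(call3$mechanism, "fm_recombination")
  expect_true(call3$breakpoint_pos > 200000 &&
              call3$breakpoint_pos <= 300000)

  # individual + late + interleaved positions -> de novo
  pos_mix <- sort(sample(1:500000, 2 * nh))
  reorder <- sample(2 * nh)
  acm4 <- mk_data(rbind(trajA, trajB)[reorder, ], pos_mix, "R1")
  call4 <- classify_mechanism(int, acm4, sc3, threshold = 100, ne = 200)
  expect_equal(call4$mechanism, "de_novo")

  # individual + early -> standing variation, no traceback fields
  traj_early <- cbind(noise(n, 0.08), noise(n, 0.5), noise(n, 0.9),
                      noise(n, 0.99), noise(n, 0.995), noise(n, 0.995))
  acm5 <- mk_data(traj_early, pos, "R1")
  call5 <- classify_mechanism(int, acm5, sc3, threshold = 100, ne = 200)
  expect_equal(call5$origin, "standing")
  expect_gte(call5$t_p, 1e-3)
  expect_true(is.na(call5$y_p))
})

test_that("classification is deterministic for fixed inputs and seeds", {
  set.seed(80)
  gens <- c(0, 20, 40, 60, 80, 100)
  n <- 40
  traj <- cbind(rbinom(n, 100, 0.2) / 100, rbinom(n, 100, 0.25) / 100,
                rbinom(n, 100, 0.3) / 100, rbinom(n, 100, 0.6) / 100,
                rbinom(n, 100, 0.9) / 100, rep(1, n))
  d <- make_freq_tensor(traj, gens)
  int <- data.frame(chrom = "sim1", start = 0, end = 1e6)
  sc <- fake_scan(c("R1", "R2"), c(400, 10), end = 1000000L,
                  g = c(0, 100))
  cache <- new.env()
  a <- classify_mechanism(int, d$acm, sc, 100, 200,
                          n_sims_lateness = 2000, null_cache = cache)
  b <- classify_mechanism(int, d$acm, sc, 100, 200,
                          n_sims_lateness = 2000, null_cache = cache)
  expect_identical(a, b)
})
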