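test_that("single-locus kernel is a neutral martingale with WF variance", {
  set.seed(11)
  n <- 5000; p0 <- 0.3; ne <- 100
  P <- simulate_wf_locus(n, p0, ne, 0, 0.5, 1)
  se <- stats::sd(P[, 2]) / sqrt(n)
  expect_lt(abs(mean(P[, 2]) - p0), 3 * se)
  v <- p0 * (1 - p0) / (2 * ne)
  expect_lt(abs(stats::var(P[, 2]) - v), 4 * v / sqrt(n / 2))
})

test_that("full simulator is a neutral martingale with heterozygosity decay", {
  set.seed(12)
  cfg <- make_scenario("neutral", n_generations = 15, n_diploids = 50,
                       n_loci = 100, seed = 21)
  p0 <- colSums(cfg$founder_haplotypes) / nrow(cfg$founder_haplotypes)
  n_rep <- 30
  finals <- het_ratio <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    r <- simulate_wf(cfg, seed = 100 + i)
    finals[i] <- mean(r$true_freqs[, 16])
    h0 <- mean(2 * r$true_freqs[, 1] * (1 - r$true_freqs[, 1]))
    ht <- mean(2 * r$true_freqs[, 16] * (1 - r$true_freqs[, 16]))
    het_ratio[i] <- ht / h0
  }
  se <- stats::sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - mean(p0)), 3 * se)
  want <- (1 - 1 / (2 * 50))^15
  se_h <- stats::sd(het_ratio) / sqrt(n_rep)
  expect_lt(abs(mean(het_ratio) - want), 3 * se_h)
})

test_that("fixation probability matches Kimura's diffusion formula", {
  # genotype fitnesses 1, 1+hs, 1+s with h = 0.5 give per-allele
  # advantage s/2, so u(p) = (1 - exp(-2*Ne*s*p)) / (1 - exp(-2*Ne*s))
  set.seed(13)
  ne <- 500; s <- 0.1; p0 <- 0.02
  n <- 1500
  fix <- mean(simulate_wf_locus(n, p0, ne, s, 0.5, 400,
                                keep_gens = 400)[, 1] == 1)
  want <- (1 - exp(-2 * ne * s * p0)) / (1 - exp(-2 * ne * s))
  expect_lt(abs(fix - want), 3 * sqrt(want * (1 - want) / n))
  # the haplotype simulator agrees with the locus kernel (dual route)
  cfg <- make_scenario("hard", n_generations = 150, n_diploids = 60,
                       n_loci = 12, s = 0.4, seed = 31)
  loc <- cfg$selected_loci$locus
  p0h <- mean(cfg$founder_haplotypes[, loc])
  full <- mean(vapply(1:150, function(i) {
    r <- simulate_wf(cfg, seed = 4000 + i)
    r$true_freqs[loc, ncol(r$true_freqs)] == 1
  }, logical(1)))
  kern <- mean(simulate_wf_locus(4000, p0h, 60, 0.4, 0.5, 150,
                                 keep_gens = 150)[, 1] == 1)
  pbar <- (150 * full + 4000 * kern) / 4150
  se_diff <- sqrt(pbar * (1 - pbar) * (1 / 150 + 1 / 4000))
  expect_lt(abs(full - kern), 4 * se_diff)
})

test_that("fixed seeds reproduce simulations exactly", {
  cfg <- make_scenario("soft_standing", n_generations = 25,
                       n_diploids = 60, n_loci = 60, seed = 41)
  a <- simulate_wf(cfg, seed = 7)
  b <- simulate_wf(cfg, seed = 7)
  expect_identical(a$true_counts, b$true_counts)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$event_log, b$event_log)
})

test_that("scenario archetypes have their defining structure", {
  cfg <- make_scenario("neutral", seed = 1)
  expect_equal(nrow(cfg$selected_loci), 0)
  cfg <- make_scenario("hard", seed = 1)
  expect_equal(sum(cfg$founder_haplotypes[, cfg$selected_loci$locus]), 1)
  cfg <- make_scenario("soft_standing", k = 3, seed = 1)
  expect_equal(sum(cfg$founder_haplotypes[, cfg$selected_loci$locus]), 3)
  expect_error(make_scenario("soft_standing", k = 99, seed = 1),
               "founder")
  cfg <- make_scenario("de_novo_late", introduction = 40, seed = 1)
  expect_equal(sum(cfg$founder_haplotypes[, cfg$selected_loci$locus]), 0)
  expect_equal(cfg$selected_loci$introduction, 40L)
  cfg <- make_scenario("fm_recombination", seed = 1)
  fav <- cfg$selected_loci[cfg$selected_loci$s > 0, ]
  expect_equal(nrow(fav), 2)
  carriers <- apply(cfg$founder_haplotypes[, fav$locus] == 1L, 2, which)
  expect_true(carriers[1] != carriers[2])  # distinct founder haplotypes
})

test_that("hard-sweep hitchhikers private to the carrier fix with it", {
  # tight linkage (r = 0): the whole carrier haplotype must fix
  set.seed(14)
  cfg <- make_scenario("hard", n_generations = 80, n_diploids = 100,
                       n_loci = 60, recomb_rate = 0, s = 0.8, seed = 51)
  loc <- cfg$selected_loci$locus
  carrier <- which(cfg$founder_haplotypes[, loc] == 1)
  private <- which(colSums(cfg$founder_haplotypes) == 1 &
                   cfg$founder_haplotypes[carrier, ] == 1)
  for (i in 1:10) {
    r <- simulate_wf(cfg, seed = 600 + i)
    if (r$true_freqs[loc, ncol(r$true_freqs)] == 1) {
      expect_true(all(r$true_freqs[private, ncol(r$true_freqs)] == 1))
      return(invisible())
    }
  }
  fail("favored allele never fixed in 10 runs at s = 0.8")
})

test_that("favored alleles never co-occur without a logged joining crossover", {
  set.seed(15)
  cfg <- make_scenario("fm_recombination", n_generations = 60,
                       n_diploids = 100, n_loci = 60, seed = 61)
  fav <- cfg$selected_loci$locus[cfg$selected_loci$s > 0]
  for (i in 1:8) {
    r <- simulate_wf(cfg, seed = 700 + i)
    both <- r$haplotypes[, fav[1]] == 1 & r$haplotypes[, fav[2]] == 1
    if (any(both))
      expect_true(any(r$event_log$type == "joining_crossover"))
  }
  # with r = 0 a joining is impossible
  cfg0 <- cfg; cfg0$recomb_rate <- 0
  for (i in 1:5) {
    r <- simulate_wf(cfg0, seed = 800 + i)
    expect_false(any(r$haplotypes[, fav[1]] == 1 &
                     r$haplotypes[, fav[2]] == 1))
  }
})

test_that("extinction is reported, not an error", {
  cfg <- make_scenario("hard", n_generations = 10, n_diploids = 20,
                       n_loci = 10, s = -0.999999, seed = 71)
  # make the favored (here: catastrophic) allele universal
  cfg$founder_haplotypes[, cfg$selected_loci$locus] <- 1L
  r <- simulate_wf(cfg, seed = 1)
  expect_true(r$extinct || all(r$true_freqs[cfg$selected_loci$locus, ] == 1))
})

test_that("pooled sequencing has the two-stage sampling moments", {
  set.seed(16)
  cfg <- make_scenario("neutral", n_generations = 2, n_diploids = 500,
                       n_loci = 30, seed = 81)
  r <- simulate_wf(cfg, seed = 2)
  # monomorphic sites give deterministic reads
  r$true_counts[1, ] <- 0L
  r$true_counts[2, ] <- r$pop_chromosomes
  acm <- pool_sequence(r, c(0, 2), "R1", pool_chromosomes = 200,
                       mean_depth = 60, seed = 3)
  expect_equal(unname(acm$alt[1, ]), c(0L, 0L))
  expect_equal(unname(acm$alt[2, ]), unname(acm$alt[2, ] + acm$ref[2, ]) -
                 unname(acm$ref[2, ]))
  expect_true(all(acm$ref[2, ] == 0))
  expect_error(pool_sequence(r, c(0, 2), "R1", pool_chromosomes = 2000),
               "exceeds")
  expect_error(pool_sequence(r, 99, "R1"), "not simulated")

  # law of total variance: alt fraction at true frequency 1/2 across
  # many sites, generated by pool_sequence on a synthetic population
  ne <- 400; pool <- 200; depth <- 100; n <- 20000
  res <- structure(list(
    true_counts = matrix(as.integer(ne), n, 1),
    pop_chromosomes = 2L * ne, generations = 0L,
    config = list(chrom = "sim1", positions = seq_len(n))),
    class = "sim_result")
  acm2 <- pool_sequence(res, 0, "R1", pool_chromosomes = pool,
                        mean_depth = depth, seed = 4)
  d <- acm2$ref[, 1] + acm2$alt[, 1]
  frac <- acm2$alt[d > 0, 1] / d[d > 0]
  v_want <- 0.25 * (1 / depth + (1 / pool) * (1 - 1 / depth) *
                      (2 * ne - pool) / (2 * ne - 1))
  expect_lt(abs(mean(frac) - 0.5), 3 * stats::sd(frac) / sqrt(length(frac)))
  expect_lt(abs(stats::var(frac) - v_want), 0.15 * v_want)
})

test_that("bottleneck schedules crash and recover gradually", {
  n <- bottleneck_schedule(150, base = 200, floor_n = 30, crash_at = 13,
                           recovery = 100)
  expect_length(n, 151)
  expect_equal(n[13], 200)
  expect_equal(n[14], 30)   # generation 13 (1-based index 14)
  expect_equal(n[151], 200)
  expect_true(all(diff(n[14:114]) >= 0))
})

test_that("archetype datasets respect their seed under fully named calls", {
  # regression: `s` must bind to the selection coefficient, never to
  # `seed` by partial matching, and different seeds give different data
  a <- simulate_archetype("hard", 1111, n_generations = 40, n_loci = 120,
                          s = 0.5)
  b <- simulate_archetype("hard", 1111, n_generations = 40, n_loci = 120,
                          s = 0.5)
  c <- simulate_archetype("hard", 2222, n_generations = 40, n_loci = 120,
                          s = 0.5)
  expect_identical(a$acm$alt, b$acm$alt)
  expect_false(identical(a$acm$alt, c$acm$alt))
})
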