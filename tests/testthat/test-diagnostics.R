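test_that("sample PCA separates selection regimes and conserves variance", {
  set.seed(91)
  gens <- c(0, 30, 60)
  n <- 150
  p0 <- rbinom(n, 100, 0.4) / 100
  # three conditions sharing initial frequencies: up-selected,
  # down-selected, neutral; one locus block responds per condition
  shift <- function(delta) cbind(p0, pmin(pmax(p0 + delta / 2, 0), 1),
                                 pmin(pmax(p0 + delta, 0), 1))
  mk <- function(traj, r) make_freq_tensor(
    pmin(pmax(traj + matrix(rnorm(3 * n, 0, 0.02), n), 0), 1), gens,
    replicate = r)$acm
  up <- shift(0.3); dn <- shift(-0.3); nt <- shift(0)
  acm <- combine_replicates(mk(up, "H1"), mk(up, "H2"), mk(dn, "L1"),
                            mk(dn, "L2"), mk(nt, "N1"), mk(nt, "N2"))
  emb <- pca_samples(to_frequencies(acm))
  expect_s3_class(emb, "sample_embedding")
  expect_equal(sum(emb$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(emb$var_explained) <= 1e-12))
  co <- emb$coordinates
  # final-generation samples of opposite regimes separate on PC1
  fin <- co[co$generation == 60, ]
  hx <- fin$PC1[grepl("^H", fin$replicate)]
  lx <- fin$PC1[grepl("^L", fin$replicate)]
  nx <- fin$PC1[grepl("^N", fin$replicate)]
  expect_true(all(hx < min(nx)) || all(hx > max(nx)))
  expect_true(all(sign(hx - mean(nx)) != sign(lx - mean(nx))))
})

test_that("identical samples embed with zero variance", {
  f <- make_freq_tensor(matrix(0.4, 50, 4), c(0, 10, 20, 30))$freqs
  emb <- suppressWarnings(pca_samples(f, site_set = "all"))
  expect_lt(max(abs(emb$coordinates$PC1)), 1e-10)
})

test_that("extant-only and all-site embeddings agree when de novo sites are few", {
  set.seed(92)
  acm <- sim_example_counts(n_sites = 200, ne = 150, seed = 93)
  # add a handful of de novo sites (absent at generation 0)
  dn <- 5
  ref <- rbind(acm$ref, matrix(60L, dn, 4))
  alt <- rbind(acm$alt, cbind(0L, matrix(rbinom(dn * 3, 20, 0.5), dn)))
  sites <- data.frame(chrom = "sim1",
                      pos = c(acm$sites$pos, max(acm$sites$pos) + 1:dn),
                      ref_allele = "A", alt_allele = "T")
  acm2 <- allele_counts(sites, acm$samples, ref, alt)
  f <- to_frequencies(acm2)
  a <- pca_samples(f, "extant")$coordinates
  b <- pca_samples(f, "all")$coordinates
  # Procrustes-style: compare up to sign per component
  for (pc in c("PC1", "PC2")) {
    r <- max(abs(cor(a[[pc]], b[[pc]])), na.rm = TRUE)
    expect_gt(r, 0.98)
  }
})

test_that("allele-frequency spectra follow the neutral 1/i decay", {
  set.seed(94)
  F <- make_founders(27, 3000)
  p <- colMeans(F)
  d <- 200L
  alt <- matrix(rbinom(3000, d, p), ncol = 1)
  acm <- allele_counts(
    data.frame(chrom = "c", pos = 1:3000, ref_allele = "A",
               alt_allele = "T"),
    data.frame(replicate = "R1", generation = 0, pool_chromosomes = 200),
    d - alt, alt)
  sp <- afs(acm, 0, n_bins = 10)
  expect_equal(sum(sp$count > 0), 10)
  expect_true(all(diff(sp$count[1:5]) < 0))      # decreasing low tail
  r <- cor(sp$count, 1 / sp$mid)
  expect_gt(r, 0.9)
})

test_that("a swept interval loses its intermediate-frequency alleles", {
  # post-sweep: alleles are fixed or lost, intermediate bins empty
  alt_fix <- matrix(c(rep(100L, 30), rep(0L, 30)), ncol = 1)
  acm <- allele_counts(
    data.frame(chrom = "c", pos = 1:60, ref_allele = "A",
               alt_allele = "T"),
    data.frame(replicate = "R1", generation = 180,
               pool_chromosomes = 200),
    100L - alt_fix, alt_fix)
  sp <- afs(acm, 180, n_bins = 10)
  expect_true(all(sp$count[sp$mid > 0.15 & sp$mid < 0.85] == 0))
  # empty interval: all-zero spectrum
  sp0 <- afs(acm, 180, interval = list(chrom = "c", start = 1e6,
                                       end = 2e6))
  expect_true(all(sp0$count == 0))
})

test_that("divergence is a metric with drift sqrt-of-time scaling", {
  set.seed(95)
  gens <- c(0, 30, 60, 120)
  ne <- 400
  p0 <- rbeta(4000, 2, 2)
  P <- simulate_wf_locus(4000, p0, ne, 0, 0.5, 120, keep_gens = gens)
  d <- make_freq_tensor(P, gens, depth = 2000L)  # high depth: noise small
  f <- d$freqs
  expect_equal(as.numeric(divergence(f, "R1", 0, 0)), 0)
  d1 <- divergence(f, "R1", 0, 30)
  d2 <- divergence(f, "R1", 30, 0)
  expect_equal(as.numeric(d1), as.numeric(d2))  # symmetry
  d03 <- divergence(f, "R1", 0, 60)
  d36 <- divergence(f, "R1", 60, 120)
  expect_lt(d03, divergence(f, "R1", 0, 30) + divergence(f, "R1", 30, 60))
  # pure drift: squared divergence grows ~linearly in time, so the
  # 0-120 vs 0-30 ratio is ~sqrt(4) within Monte-Carlo tolerance
  r <- divergence(f, "R1", 0, 120) / divergence(f, "R1", 0, 30)
  expect_gt(r, 2 * 0.8)
  expect_lt(r, 2 * 1.25)
  expect_equal(divergence_ratio(f, "R1", c(0, 120), c(0, 30)), r)
  # mean-absolute variant responds too
  expect_gt(divergence(f, "R1", 0, 120, method = "mean_abs"),
            divergence(f, "R1", 0, 30, method = "mean_abs"))
})

test_that("sweep-phase divergence exceeds post-fixation drift", {
  set.seed(96)
  cfg <- make_scenario("hard", n_generations = 120, n_diploids = 150,
                       n_loci = 300, s = 0.8, seed = 97)
  res <- NULL
  for (i in 1:10) {
    res <- simulate_wf(cfg, seed = 500 + i)
    if (res$true_freqs[cfg$selected_loci$locus, 61] == 1) break
  }
  acm <- pool_sequence(res, c(0, 60, 120), "R1", 200, 100, seed = 98)
  f <- to_frequencies(acm)
  expect_gt(divergence_ratio(f, "R1", c(0, 60), c(60, 120)), 1)
})
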