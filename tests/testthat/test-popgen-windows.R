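test_that("window grids tile chromosomes as enumerated", {
  g <- make_windows(c(chr1 = 250000), 100000, 50000)
  expect_equal(g$start, c(0, 50000, 100000, 150000))
  expect_equal(g$end, c(100000, 150000, 200000, 250000))

  g2 <- make_windows(c(chr1 = 70000), 100000, 50000)   # shorter than a window
  expect_equal(nrow(g2), 1)
  expect_equal(g2$end, 70000)

  g3 <- make_windows(c(chr1 = 200000), 50000, 50000)   # non-overlapping tiling
  expect_equal(g3$start, c(0, 50000, 100000, 150000))
  expect_equal(g3$end - g3$start, rep(50000, 4))

  g4 <- make_windows(c(chr1 = 230000), 100000, 50000)  # truncated tail window
  expect_equal(g4$end[nrow(g4)], 230000)
  expect_error(make_windows(c(chr1 = 1e6), 50000, 60000), "gaps")
})

test_that("windowed pi equals brute-force mean pairwise differences", {
  # single site: 2 alt / 2 ref alleles (two diploids) in a 100-bp window
  G <- make_gm(matrix(c(2, 0), ncol = 1), pos = 50L)
  grid <- make_windows(c(chr1 = 100), 100, 100)
  pw <- pi_windowed(G, 1:2, grid)
  expect_equal(pw$value, 2 * 2 * 2 / (4 * 3) / 100, tolerance = 1e-12)
  expect_equal(pw$value, oracle_site_pi(c(2, 0)) / 100, tolerance = 1e-12)

  # 50 random sites, 20 samples, incl. missing: match O(n^2) oracle to 1e-12
  pos <- sort(sample(1:9000, 50))
  G <- rand_gm(20, 50, seed = 31, missing = 0.1, pos = pos)
  grid <- make_windows(c(chr1 = 10000), 10000, 10000)
  got <- pi_windowed(G, 1:20, grid)$value
  want <- sum(vapply(seq_len(50), function(j) oracle_site_pi(G$calls[, j]),
                     numeric(1))) / 10000
  expect_equal(got, want, tolerance = 1e-12)

  # empty window
  g0 <- pi_windowed(make_gm(matrix(0:2, ncol = 1), pos = 15000L), 1:3,
                    make_windows(c(chr1 = 20000), 10000, 10000))
  expect_equal(g0$value[1], 0)
  expect_equal(g0$n_snps[1], 0)
})

test_that("pi is invariant to sample order and ref/alt relabeling", {
  G <- rand_gm(12, 30, seed = 8, missing = 0.05)
  grid <- make_windows(c(chr1 = 4000), 2000, 2000)
  a <- pi_windowed(G, 1:12, grid)$value
  b <- pi_windowed(G, sample(12), grid)$value
  expect_equal(a, b)
  Gf <- make_gm(2L - G$calls, pos = G$variants$pos)
  expect_equal(pi_windowed(Gf, 1:12, grid)$value, a)
})

test_that("Weir-Cockerham F_ST matches hand values and an independent oracle", {
  # fixed difference, n1 = n2 = 10, no hets -> F_ST = 1
  G <- make_gm(rbind(matrix(2, 10, 1), matrix(0, 10, 1)))
  grid <- make_windows(c(chr1 = 200), 200, 200)
  fw <- fst_windowed(G, 1:10, 11:20, grid)
  expect_equal(fw$value, 1)

  # no differentiation: same HWE frequencies in both halves
  G <- rand_gm(40, 100, seed = 21)
  fw <- fst_windowed(G, 1:20, 21:40, make_windows(c(chr1 = 10100), 10100, 10100))
  expect_lt(abs(fw$value), 0.05)

  # toy with unequal per-site sample sizes (missing data) vs textbook oracle
  set.seed(9)
  calls <- matrix(rbinom(30 * 25, 2, 0.35), nrow = 30)
  calls[matrix(runif(length(calls)) < 0.2, nrow = 30)] <- NA
  G <- make_gm(calls)
  A <- 1:14; B <- 15:30
  fw <- fst_windowed(G, A, B, make_windows(c(chr1 = 2600), 2600, 2600))
  comps <- vapply(seq_len(25), function(j) {
    oracle_wc_site(list(G$calls[A, j], G$calls[B, j]))
  }, numeric(3))
  keep <- is.finite(comps[1, ]) & colSums(abs(comps)) > 0
  want <- sum(comps[1, keep]) / sum(comps[, keep])
  expect_equal(fw$value, want, tolerance = 1e-10)
  expect_equal(attr(fw, "genome_mean"), want, tolerance = 1e-10)
})

test_that("F_ST is symmetric and single-site windows equal per-site values", {
  G <- rand_gm(30, 40, seed = 13, missing = 0.1)
  grid <- make_windows(c(chr1 = 4100), 4100, 4100)
  ab <- fst_windowed(G, 1:15, 16:30, grid)
  ba <- fst_windowed(G, 16:30, 1:15, grid)
  expect_equal(ab$value, ba$value, tolerance = 1e-12)

  G1 <- subset_genotypes(G, variants = 1)
  g1 <- make_windows(c(chr1 = 200), 200, 200)
  w1 <- fst_windowed(G1, 1:15, 16:30, g1)
  comp <- oracle_wc_site(list(G1$calls[1:15, 1], G1$calls[16:30, 1]))
  expect_equal(w1$value, comp[["a"]] / sum(comp), tolerance = 1e-12)

  # a window with no usable (polymorphic) site is flagged undefined
  Gm <- make_gm(matrix(0L, 8, 1))
  wm <- fst_windowed(Gm, 1:4, 5:8, make_windows(c(chr1 = 200), 200, 200))
  expect_true(is.na(wm$value))
  expect_equal(wm$flag, "undefined")
})

test_that("diversity comparison: identical windows give p ~ 1, shifts are detected", {
  grid <- make_windows(c(chr1 = 100 * 2000), 2000, 2000)
  base <- list(chrom = grid$chrom, start = grid$start, end = grid$end)
  mk <- function(v) structure(data.frame(base, n_snps = 1L, value = v,
                                         statistic = "pi", flag = ""),
                              class = c("window_stat", "data.frame"))
  set.seed(2)
  a <- mk(runif(100))
  expect_gte(diversity_test(a, a)$p_value, 0.99)

  v <- runif(100)
  r <- diversity_test(mk(c(v, v)[1:100]), mk(v + 0.5))
  expect_lt(r$p_value, 1e-10)
})

test_that("U-test p agrees with a permutation oracle within a factor of two", {
  set.seed(77)
  n <- 50
  grid <- make_windows(c(chr1 = n * 1000), 1000, 1000)
  base <- list(chrom = grid$chrom, start = grid$start, end = grid$end)
  mk <- function(v) structure(data.frame(base, n_snps = 1L, value = v,
                                         statistic = "pi", flag = ""),
                              class = c("window_stat", "data.frame"))
  a <- rnorm(n); b <- rnorm(n) + 0.55    # moderate effect -> testable p
  p_u <- diversity_test(mk(a), mk(b))$p_value
  r <- rank(c(a, b))
  obs <- sum(r[1:n])
  perm <- replicate(1e5, sum(sample(r, n)))
  p_perm <- mean(abs(perm - mean(r) * n) >= abs(obs - mean(r) * n) - 1e-9)
  expect_lt(p_u / p_perm, 2)
  expect_gt(p_u / p_perm, 0.5)
})
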