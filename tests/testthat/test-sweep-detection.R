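mk_stat <- function(start, end, value, chrom = "chr1", statistic = "rod",
                    n_snps = 10L) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       n_snps = n_snps, value = value, statistic = statistic,
                       flag = ""),
            class = c("window_stat", "data.frame"))
}

test_that("ROD is the ancestral/derived ratio with an epsilon floor", {
  grid <- make_windows(c(chr1 = 3000), 1000, 1000)
  mkpi <- function(v) mk_stat(grid$start, grid$end, v, statistic = "pi")
  rod <- rod_windowed(mkpi(c(0.004, 0.002, 0)), mkpi(c(0.001, 0.002, 0.003)))
  expect_equal(rod$value[1], 4)
  expect_equal(rod$value[2], 1)
  expect_true(is.na(rod$value[3]))          # zero ancestral pi -> undefined
  expect_equal(rod$flag[3], "undefined")

  # derived pi = 0 is floored at the 1st percentile of positive derived values
  set.seed(5)
  der <- c(runif(99, 0.001, 0.01), 0)
  anc <- rep(0.004, 100)
  g <- make_windows(c(chr1 = 100000), 1000, 1000)
  rod <- rod_windowed(mk_stat(g$start, g$end, anc, statistic = "pi"),
                      mk_stat(g$start, g$end, der, statistic = "pi"))
  eps <- quantile(der[der > 0], 0.01, type = 1)
  expect_equal(rod$value[100], 0.004 / unname(eps))
  expect_equal(rod$flag[100], "floored")
  expect_error(rod_windowed(mk_stat(0, 1000, 1), mk_stat(0, 2000, 1)), "grid")
})

test_that("outlier regions: threshold count, merging, and order invariance", {
  # 1000 windows (100-kb/50-kb sliding), two separated runs of 5 high windows
  n <- 1000
  start <- (seq_len(n) - 1) * 50000
  v <- seq(0.1, 0.9, length.out = n)[sample(n)]   # distinct background
  set.seed(42)
  hi1 <- 101:105; hi2 <- 501:505
  v[c(hi1, hi2)] <- 10 + seq_len(10) / 10
  st <- mk_stat(start, start + 100000, v)
  reg <- call_outlier_regions(st, 0.99)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_windows, c(5L, 5L))
  want <- oracle_interval_union(start[c(hi1, hi2)], start[c(hi1, hi2)] + 100000)
  expect_equal(reg$start, want[, 1])
  expect_equal(reg$end, want[, 2])

  # exactly top-1% windows selected over 1000 distinct values
  st2 <- mk_stat(start, start + 100000, seq_len(n) / n)
  reg2 <- call_outlier_regions(st2, 0.99, merge = FALSE)
  expect_equal(nrow(reg2), 10)
  expect_equal(sort(reg2$peak_value), (991:1000) / n)

  # input order invariance
  perm <- sample(n)
  reg3 <- call_outlier_regions(st[perm, ], 0.99)
  expect_equal(reg3$start, reg$start)
  expect_equal(reg3$end, reg$end)

  # monotonicity: raising the quantile never increases the called span
  span <- function(q) sum(call_outlier_regions(st, q)$end -
                            call_outlier_regions(st, q)$start)
  expect_true(span(0.995) <= span(0.99))
  expect_true(span(0.99) <= span(0.95))

  expect_warning(call_outlier_regions(mk_stat(start[1:1000], start[1:1000] + 1e5,
                                              rep(1, 1000))),
                 "identical")
})

test_that("gene annotation follows half-open overlap and matches brute force", {
  reg <- data.frame(chrom = c("chr1", "chr1"), start = c(1000, 5000),
                    end = c(2000, 6000))
  genes <- data.frame(gene_id = c("abut", "inside", "span"),
                      chrom = "chr1",
                      start = c(2000, 1500, 1900),
                      end = c(2500, 1600, 5100), strand = "+")
  ann <- annotate_regions(reg, genes)
  expect_equal(ann$genes[1], "inside,span")   # abutting gene NOT assigned
  expect_equal(ann$genes[2], "span")          # spanning gene in both regions

  set.seed(3)
  reg <- data.frame(chrom = "chr1", start = seq(0, 99000, 10000),
                    end = seq(0, 99000, 10000) + 5000)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                      start = sort(sample(0:104000, 100)), strand = "+")
  genes$end <- genes$start + sample(100:8000, 100, replace = TRUE)
  ann <- annotate_regions(reg, genes)
  brute <- vapply(seq_len(nrow(reg)), function(i) {
    hit <- genes$gene_id[genes$start < reg$end[i] & genes$end > reg$start[i]]
    paste(sort(hit), collapse = ",")
  }, character(1))
  expect_equal(ann$genes, brute)
})

test_that("genome fraction sums region spans and rejects overlap", {
  reg <- data.frame(chrom = "chr1", start = 0, end = 100000)
  gf <- genome_fraction(reg, c(chr1 = 5e6, chr2 = 5e6))
  expect_equal(gf$span_bp, 100000)
  expect_equal(gf$fraction, 0.01)
  expect_equal(genome_fraction(reg[0, ], c(chr1 = 1e6)),
               list(span_bp = 0, fraction = 0))
  bad <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(60000, 90000))
  expect_error(genome_fraction(bad, c(chr1 = 1e6)), "overlap")
})

test_that("composite scan is centred on neutral data and degrades gracefully", {
  # 500 neutral windows of HWE noise
  n_win <- 500; per <- 8
  pos <- as.integer(outer(seq(100, 4000, length.out = per),
                          (seq_len(n_win) - 1) * 5000, "+"))
  G <- rand_gm(30, n_win * per, seed = 10, pos = sort(pos))
  grid <- make_windows(c(chr1 = n_win * 5000), 5000, 5000)
  comp <- composite_sweep_scan(G, 1:30, grid)
  expect_equal(nrow(comp), n_win)
  expect_lt(abs(mean(comp$value)), 0.2)
  thr <- quantile(comp$value, 0.99)
  expect_lte(mean(comp$value > thr), 0.02)

  # window with no SNPs -> S1-only path, flagged
  G2 <- rand_gm(10, 6, seed = 2, pos = c(100L, 200L, 300L, 400L, 500L, 5100L))
  grid2 <- make_windows(c(chr1 = 15000), 5000, 5000)
  comp2 <- composite_sweep_scan(G2, 1:10, grid2)
  expect_equal(comp2$flag, c("", "low_snps", "low_snps"))
  expect_equal(comp2$n_snps, c(5L, 1L, 0L))

  expect_error(composite_sweep_scan(G2, 1:3, grid2), ">= 4")
  expect_error(composite_sweep_scan(G2, 1:10,
                                    make_windows(c(chr1 = 15000), 5000, 2500)),
               "non-overlapping")
})

test_that("region intersection utility returns common spans", {
  a <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(5000, 20000))
  b <- data.frame(chrom = "chr1", start = 3000, end = 12000)
  i <- intersect_regions(a, b)
  expect_equal(i$start, c(3000, 10000))
  expect_equal(i$end, c(5000, 12000))
})
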