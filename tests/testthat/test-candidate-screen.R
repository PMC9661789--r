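test_that("expression classification applies the two-ratio rule", {
  expr <- data.frame(
    gene_id = c("down_ex", "zero", "boundary", "up_inf", "plain"),
    rpkm_dw_sub = c(0.36, 0, 3.0, 2.0, 1.0),
    rpkm_ndw_sub = c(1.00, 0, 2.0, 0.0, 1.0),
    rpkm_after = c(0.62, 0, 4.0, 8.0, 1.0),
    rpkm_before = c(1.00, 0, 2.0, 2.0, 1.0))
  cl <- classify_expression(expr)
  # the printed example: ratios 0.36 and 0.62 -> down-regulated
  expect_equal(cl$label[1], "down")
  expect_equal(cl$ratio_dw[1], 0.36)
  expect_equal(cl$ratio_ab[1], 0.62)
  # all four RPKM zero -> excluded
  expect_equal(cl$label[2], "excluded")
  # ratio exactly 1.5 fails the strict inequality
  expect_equal(cl$label[3], "unclassified")
  # zero denominator with positive numerator counts as above the cut
  expect_equal(cl$label[4], "up")
  expect_equal(cl$label[5], "unclassified")
  expect_error(classify_expression(transform(expr, rpkm_after = -1)),
               "negative")
})

test_that("classification is monotone in the two ratios", {
  set.seed(44)
  base <- data.frame(gene_id = "g", rpkm_dw_sub = runif(200, 0, 3),
                     rpkm_ndw_sub = 1, rpkm_after = runif(200, 0, 3),
                     rpkm_before = 1)
  rank_of <- c(down = -1, unclassified = 0, excluded = 0, up = 1)
  l0 <- rank_of[classify_expression(base)$label]
  bumped <- transform(base, rpkm_dw_sub = rpkm_dw_sub * 2,
                      rpkm_after = rpkm_after * 2)
  l1 <- rank_of[classify_expression(bumped)$label]
  expect_true(all(l1 >= l0))
})

test_that("candidate screening joins regions, genes and expression labels", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), chrom = "chr1",
                      start = c(100, 1000, 2000, 9000),
                      end = c(600, 1500, 2400, 9500), strand = "+")
  regions <- data.frame(chrom = "chr1", start = 0, end = 2500)
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     rpkm_dw_sub = c(3, 1, 1), rpkm_ndw_sub = c(1, 1, 1),
                     rpkm_after = c(3, 1, 1), rpkm_before = c(1, 1, 1))
  out <- screen_candidates(regions, genes, expr)
  expect_equal(nrow(out), 3)            # g4 outside the region
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(screen_candidates(regions[0, ], genes, expr)), 0)
  # missing expression -> no-data, never dropped
  out2 <- screen_candidates(regions, genes, expr[-2, ])
  expect_equal(out2$label[out2$gene_id == "g2"], "no-data")
})

test_that("noise-free planted expression reproduces truth exactly", {
  cfg <- sim_config(seed = 5)
  genes <- simulate_genes(cfg)
  truth <- list(sweep_windows = data.frame(chrom = "chr1", start = 450000,
                                           end = 550000, target = "ecotype",
                                           status = "planted"))
  expr <- simulate_expression(genes, truth, fold_up = 3, fold_down = 0.36,
                              noise_sd = 0, zero_fraction = 0.05, seed = 9)
  de <- attr(expr, "de_genes")
  cl <- classify_expression(expr)
  # planted ratios are exact at noise_sd = 0
  down <- cl[cl$gene_id %in% de$gene_id[de$direction == "down"], ]
  expect_true(all(abs(down$ratio_dw - 0.36) < 1e-12))
  expect_true(all(abs(down$ratio_ab - 0.36) < 1e-12))
  # precision = recall = 1 against truth over the whole gene set
  called_de <- cl$gene_id[cl$label %in% c("up", "down")]
  expect_setequal(called_de, de$gene_id)
  got_dir <- cl$label[match(de$gene_id, cl$gene_id)]
  expect_equal(got_dir, de$direction)
  # candidates inside a region equal truth intersected with region genes
  region <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  out <- screen_candidates(region, genes, expr)
  in_region <- genes$gene_id[genes$chrom == "chr1" & genes$start < 1e6]
  expect_setequal(out$gene_id[out$candidate], intersect(de$gene_id, in_region))
})

test_that("haplotype strings are built, filled and counted per group", {
  calls <- rbind(c(0, 0, 0), c(0, 0, 0), c(2, 2, 2), c(2, 2, 2),
                 c(2, 2, 2), c(0, 1, 0))
  G <- make_gm(calls, pos = c(100L, 200L, 300L))
  groups <- data.frame(sample_id = G$samples,
                       group = rep(c("DW", "Or"), each = 3))
  ht <- haplotype_table(G, list(chrom = "chr1", start = 0, end = 1000), groups,
                        max_missing_frac = 0.4)
  expect_equal(sort(rownames(ht$counts)), c("AAA", "RAR", "RRR"))
  expect_equal(unname(ht$counts["AAA", c("DW", "Or")]), c(1, 2))
  expect_equal(unname(ht$counts["RRR", c("DW", "Or")]), c(2, 0))
  # het site of the last sample is filled with the region major allele (alt)
  expect_equal(ht$assignments$haplotype[6], "RAR")

  # accession over the het+missing tolerance (2/3 missing) is dropped
  calls[1, ] <- NA
  calls[1, 1] <- 0L
  G2 <- make_gm(calls, pos = c(100L, 200L, 300L))
  ht2 <- haplotype_table(G2, list(chrom = "chr1", start = 0, end = 1000),
                         groups, max_missing_frac = 0.4)
  expect_equal(ht2$dropped, "S01")
  expect_error(haplotype_table(G2, list(chrom = "chr1", start = 0, end = 1000),
                               groups[groups$sample_id == "S01", ],
                               max_missing_frac = 0.2),
               "tolerance")
})

test_that("haplotype differentiation: chi2 values and permutation p behave", {
  # 2x2 table (10,0 / 0,10): chi-square = 20, permutation p at its floor
  calls <- rbind(matrix(0, 10, 2), matrix(2, 10, 2))
  G <- make_gm(calls)
  groups <- data.frame(sample_id = G$samples,
                       group = rep(c("A", "B"), each = 10))
  ht <- haplotype_table(G, list(chrom = "chr1", start = 0, end = 1000), groups)
  hd <- haplotype_differentiation(ht, n_perm = 999, seed = 2)
  expect_equal(hd$chi2, 20)
  expect_equal(hd$p_perm, 1 / 1000)

  # identical haplotype distributions in both groups -> p = 1
  calls2 <- rbind(matrix(0, 5, 2), matrix(2, 5, 2),
                  matrix(0, 5, 2), matrix(2, 5, 2))
  G2 <- make_gm(calls2)
  groups2 <- data.frame(sample_id = G2$samples,
                        group = rep(c("A", "B"), each = 10))
  ht2 <- haplotype_table(G2, list(chrom = "chr1", start = 0, end = 1000), groups2)
  for (s in 1:3)
    expect_gte(haplotype_differentiation(ht2, n_perm = 499, seed = s)$p_perm, 0.2)

  # deterministic given seed; invariant to group column order
  hd2 <- haplotype_differentiation(ht, n_perm = 999, seed = 2)
  expect_identical(hd, hd2)
  ht_r <- ht
  ht_r$assignments <- ht_r$assignments[rev(seq_len(nrow(ht_r$assignments))), ]
  expect_equal(haplotype_differentiation(ht_r, n_perm = 999, seed = 2)$chi2,
               hd$chi2)

  one <- list(counts = matrix(5, 1, 2), assignments = data.frame(
    sample_id = letters[1:5], group = c("A", "A", "B", "B", "B"),
    haplotype = "AAA"))
  expect_warning(res <- haplotype_differentiation(one, 99, 1), "degenerate")
  expect_equal(res$p_perm, 1)
})
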