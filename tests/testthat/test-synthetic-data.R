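test_that("simulation is byte-identical for a fixed seed and validates config", {
  ds1 <- quick_sim(seed = 41)
  ds2 <- quick_sim(seed = 41)
  expect_identical(ds1$genotypes$calls, ds2$genotypes$calls)
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(config_hash(ds1), config_hash(ds2))
  ds3 <- quick_sim(seed = 42)
  expect_false(identical(ds1$genotypes$calls, ds3$genotypes$calls))

  expect_error(sim_config(mutation_rate = -1), "negative")
  expect_error(sim_config(selfing_rate = 1.2), "selfing_rate")
  expect_error(sim_config(sweep_loci = data.frame(chrom = 1, center_bp = 10,
                                                  width_bp = 1e5,
                                                  target = "ecotype")),
               "outside")
  expect_error(sim_config(sweep_loci = data.frame(chrom = 9, center_bp = 1e5,
                                                  width_bp = 1e4,
                                                  target = "ecotype")),
               "nonexistent")
})

test_that("missingness injection is Bernoulli at the requested rate", {
  G <- rand_gm(100, 1000, seed = 3)       # 1e5 genotypes
  expect_identical(inject_missing(G, 0, 1)$calls, G$calls)
  Gm <- inject_missing(G, 0.5, seed = 9)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(mean(is.na(Gm$calls)) - 0.5), sd3)
  expect_error(inject_missing(G, 1), "rate")
  expect_error(inject_missing(G, -0.1), "rate")
  expect_identical(inject_missing(G, 0.3, 5)$calls,
                   inject_missing(G, 0.3, 5)$calls)
})

test_that("near-complete selfing yields near-homozygous lines with rare hets", {
  ds <- quick_sim(seed = 55)
  het <- mean(ds$genotypes$calls == 1L, na.rm = TRUE)
  expect_lt(het, 0.05)
  expect_gt(het, 0)          # het-handling paths stay exercised
})

test_that("planted sweeps carve a diversity trough of roughly the stated depth", {
  # one 100-kb locus at strength 5: expected reduction ~ 1 - f^2 = 1/5,
  # plus post-sweep mutation influx; well under 0.4 x the genome median
  ratios <- vapply(1:5, function(s) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                      pop_sizes = c(wild = 60, progenitor = 60, ecotype = 60),
                      sample_sizes = c(wild = 20, progenitor = 20, ecotype = 30),
                      split_generations = c(wild_to_progenitor = 120,
                                            progenitor_to_ecotype = 60),
                      bottleneck_size = 20, bottleneck_duration = 10,
                      mutation_rate = 1.25e-6, recombination_rate = 5e-6,
                      sweep_loci = data.frame(chrom = 1, center_bp = 5e5,
                                              width_bp = 1e5,
                                              target = "ecotype"),
                      sweep_strength = 5, seed = 100 + s)
    ds <- simulate_dataset(cfg)
    stopifnot(ds$truth$sweep_windows$status == "planted")
    grid <- make_windows(c(chr1 = 1e6), 50000, 50000)
    pe <- pi_windowed(ds$genotypes, pop_ids(ds, "DW"), grid)
    sw <- ds$truth$sweep_windows
    inside <- pe$start >= sw$start & pe$end <= sw$end
    mean(pe$value[inside]) / median(pe$value)
  }, numeric(1))
  expect_lt(median(ratios), 0.4)
})

test_that("neutral wild-only runs calibrate to theta = 4 N mu within 15%", {
  # random mating for this check: theta = 4 N mu assumes no selfing
  N <- 40; mu <- 2e-6; L <- 2e5
  reps <- 50
  pis <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = L,
                      pop_sizes = c(wild = N, progenitor = 10, ecotype = 10),
                      sample_sizes = c(wild = 20, progenitor = 0, ecotype = 0),
                      split_generations = c(wild_to_progenitor = 0,
                                            progenitor_to_ecotype = 0),
                      mutation_rate = mu, selfing_rate = 0,
                      sweep_loci = NULL, missing_rate = 0, seed = 7000 + i)
    ds <- simulate_dataset(cfg)
    grid <- make_windows(c(chr1 = L), L, L)
    pi_windowed(ds$genotypes, seq_len(20), grid)$value
  }, numeric(1))
  theta <- 4 * N * mu
  expect_lt(abs(mean(pis) - theta) / theta, 0.15)
})

test_that("the founding bottleneck depresses progenitor diversity", {
  d <- vapply(1:20, function(i) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e5,
                      pop_sizes = c(wild = 50, progenitor = 50, ecotype = 10),
                      sample_sizes = c(wild = 20, progenitor = 20, ecotype = 0),
                      split_generations = c(wild_to_progenitor = 60,
                                            progenitor_to_ecotype = 0),
                      bottleneck_size = 8, bottleneck_duration = 30,
                      mutation_rate = 2e-6, sweep_loci = NULL,
                      missing_rate = 0, seed = 8000 + i)
    ds <- simulate_dataset(cfg)
    grid <- make_windows(c(chr1 = 2e5), 2e5, 2e5)
    pi_windowed(ds$genotypes, pop_ids(ds, "Or"), grid)$value -
      pi_windowed(ds$genotypes, pop_ids(ds, "IR-XI"), grid)$value
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("expression simulator honours folds, zeros and detectability bounds", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:150), chrom = "chr1",
                      start = (0:149) * 1000, end = (0:149) * 1000 + 500,
                      strand = "+")
  expect_error(simulate_expression(genes[0, ]), "empty")
  expect_error(simulate_expression(genes, fold_up = 1.4), "fold_up")
  expect_error(simulate_expression(genes, fold_down = 0.7), "fold_down")

  # 100 planted up genes at fold 3, noise 0.1 -> >= 95 recovered as up
  de <- data.frame(gene_id = genes$gene_id[1:100], direction = "up")
  expr <- simulate_expression(genes, truth = list(de_genes = de),
                              fold_up = 3, noise_sd = 0.1, zero_fraction = 0,
                              seed = 12)
  cl <- classify_expression(expr)
  expect_gte(sum(cl$label[1:100] == "up"), 95)

  # all-zero genes classify as excluded downstream
  expr0 <- simulate_expression(genes, fold_up = 3, noise_sd = 0.2,
                               zero_fraction = 0.1, seed = 13)
  cl0 <- classify_expression(expr0)
  zero_rows <- rowSums(expr0[, -1] == 0) == 4
  expect_equal(sum(zero_rows), 15)
  expect_true(all(cl0$label[zero_rows] == "excluded"))
})

test_that("fixtures round-trip and the manifest hash tracks config and seed", {
  ds <- quick_sim(seed = 61)
  ds$genes <- simulate_genes(ds$config)
  ds$expression <- simulate_expression(ds$genes, ds$truth, seed = 62)
  dir1 <- withr::local_tempdir()
  man1 <- write_fixture(ds, dir1)
  G2 <- read_vcf(file.path(dir1, "genotypes.vcf"))
  expect_identical(G2$calls, ds$genotypes$calls)
  expect_identical(G2$variants, ds$genotypes$variants)

  bed <- read.table(file.path(dir1, "genes.bed"), sep = "\t")
  expect_true(all(diff(bed$V2) >= 0))
  expect_equal(bed$V2, ds$genes$start)    # 0-based half-open starts

  # same config + seed -> same hash; different seed -> different hash
  man1b <- write_fixture(ds, withr::local_tempdir())
  expect_identical(man1$config_hash, man1b$config_hash)
  ds2 <- quick_sim(seed = 63)
  man2 <- write_fixture(ds2, withr::local_tempdir())
  expect_false(identical(man1$config_hash, man2$config_hash))
})
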