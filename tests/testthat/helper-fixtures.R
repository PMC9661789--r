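# shared fixture builders and independent oracles

# hand-built genotype matrix from a samples x variants integer matrix
make_gm <- function(calls, chrom = NULL, pos = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(calls)))
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
                  samples)
}

# random HWE genotypes, one allele frequency per variant, optional missingness
rand_gm <- function(n_samples, n_variants, seed = 1, maf = c(0.05, 0.5),
                    missing = 0, chrom = NULL, pos = NULL) {
  set.seed(seed)
  p <- runif(n_variants, maf[1], maf[2])
  calls <- vapply(p, function(pp) rbinom(n_samples, 2, pp), numeric(n_samples))
  if (missing > 0) calls[matrix(runif(length(calls)) < missing,
                                nrow = n_samples)] <- NA
  make_gm(calls, chrom = chrom, pos = pos)
}

# small simulated dataset shared by several suites (cached per session)
quick_sim <- function(seed = 7, ...) {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e5,
                    pop_sizes = c(wild = 60, progenitor = 60, ecotype = 60),
                    sample_sizes = c(wild = 20, progenitor = 20, ecotype = 20),
                    split_generations = c(wild_to_progenitor = 120,
                                          progenitor_to_ecotype = 60),
                    bottleneck_size = 20, bottleneck_duration = 10,
                    mutation_rate = 1e-6,
                    sweep_loci = data.frame(chrom = 1, center_bp = 2.5e5,
                                            width_bp = 6e4, target = "ecotype"),
                    seed = seed, ...)
  simulate_dataset(cfg)
}

pop_ids <- function(ds, grp) ds$samples$sample_id[ds$samples$group == grp]

# ---- independent oracles -------------------------------------------------

# per-site pi by explicit enumeration of every unordered allele pair
oracle_site_pi <- function(codes) {
  codes <- codes[!is.na(codes)]
  alleles <- unlist(lapply(codes, function(g) c(rep(1, g), rep(0, 2 - g))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) diff <- diff + (alleles[i] != alleles[j])
  diff / (n * (n - 1) / 2)
}

# textbook Weir & Cockerham (1984) per-site estimator, transcribed
# independently from the implementation (scalar, r populations)
oracle_wc_site <- function(pops) {
  r <- length(pops)
  n <- vapply(pops, function(g) sum(!is.na(g)), numeric(1))
  p <- vapply(pops, function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))),
              numeric(1))
  h <- vapply(pops, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# brute-force union of a set of [start, end) intervals on one chromosome
oracle_interval_union <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  us <- start[1]; ue <- end[1]; out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ue) ue <- max(ue, end[i])
    else { out <- rbind(out, c(us, ue)); us <- start[i]; ue <- end[i] }
  }
  rbind(out, c(us, ue))
}
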