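#' Configuration for the domestication simulator
#'
#' The stated world of the synthetic fixture: a wild ancestral population at
#' mutation-drift equilibrium (burn-in >= 8N generations), a progenitor
#' founded through a bottleneck, and a derived ecotype founded from the
#' progenitor through a second bottleneck. Mutation continues after the
#' splits (populating the "new mutation" class), lines are near-fully selfing,
#' and diversity-reducing sweeps are planted in the ecotype at fixed loci by
#' driving one haplotype along a deterministic logistic trajectory. Defaults
#' are desk-scale (2 x 2 Mb, N = 200), explicitly not genome scale; windows
#' scale down accordingly.
#'
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param pop_sizes named diploid sizes (`wild`, `progenitor`, `ecotype`).
#' @param sample_sizes named counts of accessions emitted per population.
#' @param split_generations generations on the wild->progenitor and
#'   progenitor->ecotype edges.
#' @param burnin_generations wild burn-in; default `8 * pop_sizes["wild"]`.
#' @param bottleneck_size,bottleneck_duration founding bottleneck (diploids,
#'   generations), applied at both splits.
#' @param mutation_rate per-bp per-generation; the wild equilibrium diversity
#'   is `theta = 4 N mu` per bp.
#' @param mutation_rate_post_burnin optional different rate after burn-in
#'   (0 freezes mutation, emptying the "new mutation" class).
#' @param recombination_rate per-bp per-generation crossover rate.
#' @param selfing_rate probability an offspring is produced by selfing
#'   (default 0.99: rice landraces are near-inbred, so heterozygotes are rare
#'   but present).
#' @param sweep_loci data.frame (`chrom`, `center_bp`, `width_bp`, `target`)
#'   of planted sweeps; `target` is a population name.
#' @param sweep_strength local diversity-reduction factor (>= 1); the sweep
#'   haplotype is driven to frequency `sqrt(1 - 1/strength)`.
#' @param sweep_generations length of the logistic trajectory; default
#'   `0.2 * N` of the target population.
#' @param missing_rate per-genotype missingness injected into the emitted
#'   calls.
#' @param labels group labels used in the sample table.
#' @param n_genes genes simulated along the genome.
#' @param seed master seed; all stages derive their own streams from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length_bp = 2e6,
                       pop_sizes = c(wild = 200, progenitor = 200, ecotype = 200),
                       sample_sizes = c(wild = 40, progenitor = 40, ecotype = 40),
                       split_generations = c(wild_to_progenitor = 400,
                                             progenitor_to_ecotype = 200),
                       burnin_generations = NULL,
                       bottleneck_size = 50, bottleneck_duration = 20,
                       mutation_rate = 2.5e-7,
                       mutation_rate_post_burnin = NULL,
                       recombination_rate = 1e-6,
                       selfing_rate = 0.99,
                       sweep_loci = data.frame(
                         chrom = c(1, 2), center_bp = c(5e5, 1.2e6),
                         width_bp = 1e5, target = "ecotype"),
                       sweep_strength = 5, sweep_generations = NULL,
                       missing_rate = 0.02,
                       labels = c(wild = "Or", progenitor = "IR-XI",
                                  ecotype = "DW"),
                       n_genes = 200, seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              pop_sizes = pop_sizes, sample_sizes = sample_sizes,
              split_generations = split_generations,
              burnin_generations = burnin_generations %||%
                as.integer(8 * pop_sizes[["wild"]]),
              bottleneck_size = as.integer(bottleneck_size),
              bottleneck_duration = as.integer(bottleneck_duration),
              mutation_rate = mutation_rate,
              mutation_rate_post_burnin = mutation_rate_post_burnin,
              recombination_rate = recombination_rate,
              selfing_rate = selfing_rate,
              sweep_loci = sweep_loci, sweep_strength = sweep_strength,
              sweep_generations = sweep_generations,
              missing_rate = missing_rate, labels = labels,
              n_genes = as.integer(n_genes), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_ok <- function(x) all(is.finite(x)) && all(x >= 0)
  if (!num_ok(unlist(cfg[c("chrom_length_bp", "mutation_rate",
                           "recombination_rate", "sweep_strength")])))
    stop("non-finite or negative simulation parameter")
  for (r in c("selfing_rate", "missing_rate"))
    if (!is.finite(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1)
      stop(r, " must be in [0, 1]")
  if (cfg$n_chromosomes < 1 || cfg$chrom_length_bp < 1)
    stop("lengths and counts must be positive")
  if (any(cfg$pop_sizes < 2)) stop("population sizes must be >= 2")
  if (cfg$sweep_strength < 1) stop("sweep_strength must be >= 1")
  sw <- cfg$sweep_loci
  if (!is.null(sw) && nrow(sw) > 0) {
    if (any(sw$chrom < 1 | sw$chrom > cfg$n_chromosomes))
      stop("sweep locus on nonexistent chromosome")
    if (any(sw$center_bp - sw$width_bp / 2 < 0 |
              sw$center_bp + sw$width_bp / 2 > cfg$chrom_length_bp))
      stop("sweep window outside chromosome")
    if (!all(sw$target %in% names(cfg$pop_sizes)))
      stop("sweep target must be a population name")
  }
  invisible(cfg)
}

#' Simulate a domestication dataset with ground truth
#'
#' Runs the forward Wright-Fisher engine (see [sim_config]), assembles the
#' emitted accessions into a [genotype_matrix] (monomorphic sites dropped,
#' missingness injected), builds the sample table with group labels and
#' ADMIXTURE-like Q values, and returns the ground truth needed by recovery
#' tests: planted sweep windows (with planted/skipped status), post-split
#' mutation sites surviving in the sample, causal SNPs and the liability-
#' derived binary phenotype. Deterministic for a fixed seed.
#'
#' @param config a [sim_config].
#' @return list with `genotypes`, `samples`, `truth`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config
  sw <- cfg$sweep_loci
  if (is.null(sw) || nrow(sw) == 0)
    sw <- data.frame(chrom = integer(), center_bp = numeric(),
                     width_bp = numeric(), target = character())
  pop_index <- c(wild = 0L, progenitor = 1L, ecotype = 2L)
  targ_n <- cfg$pop_sizes[match(sw$target, names(cfg$pop_sizes))]
  sweep_gens <- cfg$sweep_generations %||%
    (if (nrow(sw)) as.integer(round(0.2 * max(targ_n))) else 0L)
  raw <- .wf_sim_cpp(
    cfg$n_chromosomes, cfg$chrom_length_bp,
    cfg$pop_sizes[["wild"]], cfg$pop_sizes[["progenitor"]],
    cfg$pop_sizes[["ecotype"]],
    cfg$burnin_generations,
    as.integer(cfg$split_generations[["wild_to_progenitor"]]),
    as.integer(cfg$split_generations[["progenitor_to_ecotype"]]),
    cfg$bottleneck_size, cfg$bottleneck_duration,
    cfg$mutation_rate, cfg$recombination_rate, cfg$selfing_rate,
    as.integer(sw$chrom), as.numeric(sw$center_bp), as.numeric(sw$width_bp),
    pop_index[sw$target],
    cfg$sweep_strength, as.integer(sweep_gens),
    cfg$sample_sizes[["wild"]], cfg$sample_sizes[["progenitor"]],
    cfg$sample_sizes[["ecotype"]],
    derive_seed(cfg$seed, "wf"),
    if (is.null(cfg$mutation_rate_post_burnin)) -1 else cfg$mutation_rate_post_burnin)

  calls <- rbind(raw$wild, raw$prog, raw$eco)
  grp <- rep(cfg$labels[c("wild", "progenitor", "ecotype")],
             c(nrow(raw$wild), nrow(raw$prog), nrow(raw$eco)))
  r <- rle(as.character(grp))   # groups are contiguous blocks
  ids <- unlist(mapply(function(lab, n) sprintf("%s_%03d", lab, seq_len(n)),
                       r$values, r$lengths, SIMPLIFY = FALSE), use.names = FALSE)

  ord <- order(raw$chrom, raw$pos)
  calls <- calls[, ord, drop = FALSE]
  chrom <- paste0("chr", raw$chrom[ord] + 1L)
  pos <- raw$pos[ord]
  opop <- raw$origin_pop[ord]; ogen <- raw$origin_gen[ord]
  ac <- colSums(calls)
  poly <- ac > 0 & ac < 2 * nrow(calls)
  calls <- calls[, poly, drop = FALSE]
  chrom <- chrom[poly]; pos <- pos[poly]
  opop <- opop[poly]; ogen <- ogen[poly]
  bases <- c("A", "C", "G", "T")
  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = bases[pos %% 4 + 1],
                         alt = bases[(pos + 1) %% 4 + 1],
                         stringsAsFactors = FALSE)
  G <- genotype_matrix(calls, variants, ids)
  if (cfg$missing_rate > 0)
    G <- inject_missing(G, cfg$missing_rate, derive_seed(cfg$seed, "missing"))

  cultivated <- grp != cfg$labels[["wild"]]
  q <- rep(NA_real_, length(grp))
  q[cultivated] <- with_seed(derive_seed(cfg$seed, "q"), {
    n <- sum(cultivated)
    v <- round(runif(n, 0.82, 1), 3)
    lo <- sample(n, max(0L, floor(0.05 * n)))
    v[lo] <- round(runif(length(lo), 0.4, 0.8), 3)
    v
  })
  samples <- data.frame(sample_id = ids, group = unname(grp), q_value = q,
                        stringsAsFactors = FALSE)

  sweep_windows <- if (nrow(sw)) data.frame(
    chrom = paste0("chr", sw$chrom),
    start = pmax(0, sw$center_bp - sw$width_bp / 2),
    end = pmin(cfg$chrom_length_bp, sw$center_bp + sw$width_bp / 2),
    target = sw$target,
    status = c("skipped", "planted")[pmax(raw$sweep_status, 0) + 1L],
    stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  target = character(), status = character())

  new_mut <- data.frame(
    chrom = chrom, pos = pos,
    population = c("wild", "progenitor", "ecotype")[opop + 1L],
    origin_gen = ogen, stringsAsFactors = FALSE)
  new_mut <- new_mut[(new_mut$population == "progenitor" &
                        ogen > raw$split_prog_gen) |
                       (new_mut$population == "ecotype" &
                          ogen > raw$split_eco_gen), , drop = FALSE]
  rownames(new_mut) <- NULL

  pheno <- if (sum(cultivated) >= 10)
    tryCatch(simulate_binary_trait(G, samples$sample_id[cultivated],
                                   seed = derive_seed(cfg$seed, "pheno")),
             error = function(e) NULL)
  truth <- list(sweep_windows = sweep_windows,
                new_mutation_sites = new_mut,
                causal_snps = pheno$causal,
                phenotype = pheno$y,
                de_genes = NULL)
  list(genotypes = G, samples = samples, truth = truth, config = cfg)
}

#' Inject missing genotypes
#'
#' Each call is independently set to missing with probability `rate`;
#' reproducible for a fixed seed.
#'
#' @param G a [genotype_matrix].
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a [genotype_matrix].
#' @export
inject_missing <- function(G, rate, seed = 1) {
  if (!is.finite(rate) || rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)")
  if (rate == 0) return(G)
  calls <- G$calls
  mask <- with_seed(seed,
                    matrix(runif(length(calls)) < rate, nrow = nrow(calls)))
  calls[mask] <- NA_integer_
  genotype_matrix(calls, G$variants, G$samples)
}

#' Simulate a causal binary trait on top of simulated genotypes
#'
#' Picks `n_causal` well-separated SNPs with intermediate frequency, builds a
#' liability from their standardized dosages plus Gaussian noise, and labels
#' the top `prevalence` fraction of samples as cases -- the "ecotype
#' membership driven by a few planted SNPs plus background" scenario used by
#' GWAS recovery tests.
#'
#' @param G a [genotype_matrix].
#' @param samples sample ids entering the trait (e.g. cultivated accessions).
#' @param n_causal number of causal SNPs.
#' @param effect per-SNP liability effect (in liability SDs).
#' @param noise_sd residual liability noise.
#' @param prevalence case fraction.
#' @param min_sep_bp minimum separation between causal SNPs.
#' @param maf_range acceptable causal-SNP MAF window.
#' @param seed integer seed.
#' @return `list(y = named 0/1 vector over samples, causal = data.frame)`.
#' @export
simulate_binary_trait <- function(G, samples, n_causal = 3, effect = 1.5,
                                  noise_sd = 0.5, prevalence = 0.3,
                                  min_sep_bp = NULL, maf_range = c(0.2, 0.5),
                                  seed = 1) {
  if (is.null(min_sep_bp)) {  # scale with the simulated genome
    span <- sum(tapply(G$variants$pos, G$variants$chrom, max))
    min_sep_bp <- min(3e5, span / (4 * n_causal))
  }
  maf <- variant_maf(G, samples)
  cand <- which(!is.na(maf) & maf >= maf_range[1] & maf <= maf_range[2])
  if (length(cand) < n_causal) stop("too few intermediate-frequency SNPs")
  v <- G$variants
  si0 <- match(samples, G$samples)
  with_seed(seed, {
    # draw well-separated candidate triples, then require that no planted
    # SNP's marginal effect is cancelled by LD with the others: for each
    # causal k, 1 + sum_j r_kj must stay positive with margin. In small
    # panels relatedness correlates even unlinked loci, and a cancelled
    # marginal would mean the SNP does not detectably "drive" the trait.
    draw_triple <- function() {
      cs <- sample(cand)
      picked <- integer(0)
      for (i in cs) {
        if (length(picked) == n_causal) break
        far <- all(v$chrom[picked] != v$chrom[i] |
                     abs(v$pos[picked] - v$pos[i]) >= min_sep_bp)
        if (far) picked <- c(picked, i)
      }
      if (length(picked) < n_causal) NULL else picked
    }
    picked <- NULL
    for (try in seq_len(200)) {
      p <- draw_triple()
      if (is.null(p)) next
      R <- suppressWarnings(cor(G$calls[si0, p, drop = FALSE],
                                use = "pairwise.complete.obs"))
      R[is.na(R)] <- 0
      if (min(rowSums(R)) >= 0.6) { picked <- p; break }
    }
    if (is.null(picked))
      stop("could not place ", n_causal,
           " causal SNPs with non-cancelling marginal effects")
    picked <- sort(picked)
    si <- match(samples, G$samples)
    X <- G$calls[si, picked, drop = FALSE]
    storage.mode(X) <- "double"
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    Z <- scale(X)
    liab <- drop(Z %*% rep(effect, n_causal)) + rnorm(length(si), 0, noise_sd)
    y <- as.numeric(liab >= quantile(liab, 1 - prevalence))
    names(y) <- samples
    list(y = y,
         causal = data.frame(chrom = v$chrom[picked], pos = v$pos[picked],
                             effect = effect, stringsAsFactors = FALSE))
  })
}

#' Simulate a gene annotation along the genome
#'
#' Evenly spaced genes with jittered starts, 3 kb long, one strand
#' alternating -- enough structure to exercise overlap annotation and the
#' candidate screen.
#'
#' @param config a [sim_config].
#' @param gene_length_bp gene body length.
#' @return gene table (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   0-based half-open, sorted.
#' @export
simulate_genes <- function(config, gene_length_bp = 3000) {
  cfg <- config
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  gap0 <- cfg$chrom_length_bp / per_chrom
  gene_length_bp <- max(200, min(gene_length_bp, floor(gap0 / 2)))
  with_seed(derive_seed(cfg$seed, "genes"), {
    rows <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
      gap <- cfg$chrom_length_bp / per_chrom
      start <- pmin(pmax(0, round((seq_len(per_chrom) - 1) * gap +
                                    runif(per_chrom, 0, gap - gene_length_bp))),
                    cfg$chrom_length_bp - gene_length_bp)
      data.frame(chrom = paste0("chr", ci), start = sort(start),
                 end = sort(start) + gene_length_bp,
                 strand = rep(c("+", "-"), length.out = per_chrom),
                 stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, rows)[seq_len(cfg$n_genes), , drop = FALSE]
    g$gene_id <- sprintf("g%04d", seq_len(nrow(g)))
    g[, c("gene_id", "chrom", "start", "end", "strand")]
  })
}

#' Simulate the four-condition RPKM expression table
#'
#' Per gene, four RPKM values (deepwater submerged, non-deepwater submerged,
#' deepwater after submergence, deepwater before submergence) drawn
#' log-normally around a shared baseline. Planted differentially expressed
#' genes have both relevant ratios shifted by `fold_up` / `fold_down`; a
#' `zero_fraction` of genes has all four values exactly zero (unexpressed
#' retrotransposon-like genes, "excluded" downstream). With `noise_sd = 0`
#' the planted ratios are exact.
#'
#' @param genes gene table.
#' @param truth optional truth list; if it carries `de_genes` those are
#'   planted, otherwise `de_fraction` of genes (sweep-window genes first) are
#'   drawn and reported back via `attr(, "de_genes")`.
#' @param fold_up,fold_down planted fold changes; must be detectable by the
#'   1.5 / 0.67 rule (`fold_up > 1.5`, `fold_down < 0.67`).
#' @param noise_sd log-scale noise SD.
#' @param zero_fraction fraction of all-zero genes.
#' @param de_fraction fraction of genes planted as DE when truth gives none.
#' @param seed integer seed.
#' @return expression table with attribute `de_genes` (`gene_id`,
#'   `direction`).
#' @export
simulate_expression <- function(genes, truth = NULL, fold_up = 3,
                                fold_down = 0.3, noise_sd = 0.25,
                                zero_fraction = 0.02, de_fraction = 0.1,
                                seed = 1) {
  if (is.null(genes) || nrow(genes) == 0) stop("empty gene set")
  if (fold_up <= 1.5) stop("fold_up must exceed 1.5 to be detectable")
  if (fold_down >= 0.67) stop("fold_down must be below 0.67 to be detectable")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(genes)
  de <- truth$de_genes
  with_seed(seed, {
    if (is.null(de) || nrow(de) == 0) {
      n_de <- max(2L, round(de_fraction * n))
      in_sweep <- rep(FALSE, n)
      swt <- truth$sweep_windows
      if (!is.null(swt) && nrow(swt) > 0)
        for (i in seq_len(nrow(swt)))
          in_sweep <- in_sweep | (genes$chrom == swt$chrom[i] &
                                    genes$start < swt$end[i] &
                                    genes$end > swt$start[i])
      pool <- c(which(in_sweep), sample(which(!in_sweep)))
      ids <- genes$gene_id[pool[seq_len(min(n_de, length(pool)))]]
      de <- data.frame(gene_id = ids,
                       direction = rep(c("up", "down"), length.out = length(ids)),
                       stringsAsFactors = FALSE)
    }
    fold <- rep(1, n)
    fold[match(de$gene_id[de$direction == "up"], genes$gene_id)] <- fold_up
    fold[match(de$gene_id[de$direction == "down"], genes$gene_id)] <- fold_down
    base <- rlnorm(n, meanlog = 2, sdlog = 1)
    eps <- function() if (noise_sd == 0) rep(1, n) else rlnorm(n, 0, noise_sd)
    expr <- data.frame(
      gene_id = genes$gene_id,
      rpkm_dw_sub = base * fold * eps(),
      rpkm_ndw_sub = base * eps(),
      rpkm_after = base * fold * eps(),
      rpkm_before = base * eps(),
      stringsAsFactors = FALSE)
    nz <- round(zero_fraction * n)
    if (nz > 0) {
      zi <- sample(setdiff(seq_len(n), match(de$gene_id, genes$gene_id)), nz)
      expr[zi, -1] <- 0
    }
    attr(expr, "de_genes") <- de
    expr
  })
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits VCF (v4.2, GT-only), sample TSV, gene BED, expression TSV and the
#' truth tables, plus a `manifest.json` listing every file with its md5, the
#' master seed and the configuration hash.
#'
#' @param dataset list from [simulate_dataset], optionally extended with
#'   `genes` and `expression`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("cannot write to ", out_dir)
  cfg <- dataset$config
  cl <- NULL
  if (!is.null(cfg))
    cl <- stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes),
                          paste0("chr", seq_len(cfg$n_chromosomes)))
  paths <- character(0)
  put <- function(writer, x, name) {
    p <- file.path(out_dir, name)
    writer(x, p)
    paths[[name]] <<- p
  }
  put(function(x, p) write_vcf(x, p, chrom_lengths = cl),
      dataset$genotypes, "genotypes.vcf")
  put(write_tsv, dataset$samples, "samples.tsv")
  if (!is.null(dataset$genes)) put(write_bed, dataset$genes, "genes.bed")
  if (!is.null(dataset$expression))
    put(write_tsv, dataset$expression, "expression.tsv")
  tr <- dataset$truth
  if (!is.null(tr)) {
    put(write_tsv, tr$sweep_windows, "truth_sweeps.tsv")
    put(write_tsv, tr$new_mutation_sites, "truth_new_mutations.tsv")
    if (!is.null(tr$causal_snps))
      put(write_tsv, tr$causal_snps, "truth_causal.tsv")
    if (!is.null(tr$phenotype))
      put(write_tsv, data.frame(sample_id = names(tr$phenotype),
                                phenotype = unname(tr$phenotype)),
          "truth_phenotype.tsv")
    de <- tr$de_genes %||% attr(dataset$expression, "de_genes")
    if (!is.null(de)) put(write_tsv, de, "truth_de_genes.tsv")
  }
  if (!is.null(cl))
    put(write_tsv, data.frame(chrom = names(cl), length = unname(cl)),
        "chrom_lengths.tsv")
  manifest <- list(seed = cfg$seed %||% NA_integer_,
                   config_hash = if (is.null(cfg)) NA_character_
                   else config_hash(unclass(cfg)),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(unlist(paths))), names(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
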