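#' Pipeline configuration
#'
#' One structured config drives every stage; each published analysis
#' parameter surfaces as a named key with its conventional value as default:
#' 100 kb / 50 kb windows, top 1% outlier quantile, missing <= 0.5 and
#' MAF >= 0.05 variant filters, Q > 0.8 core-sample filter, 50/5/0.3 LD
#' pruning, alpha = 0.01 threshold, 1.5 / 0.67 expression cutoffs. Overrides
#' may be a (possibly nested) list or a JSON file with the same shape.
#'
#' @param overrides list or path to a JSON file.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    sim = NULL,                      # filled with sim_config() when simulating
    inputs = list(vcf = NULL, samples = NULL, genes = NULL, expression = NULL,
                  chrom_lengths = NULL),
    groups = list(ecotype = "DW", progenitor = "IR-XI", wild = "Or"),
    min_q = 0.8,
    filters = list(max_missing_rate = 0.5, min_maf = 0.05),
    windows = list(size = 100000, step = 50000),
    composite_window = 50000,
    quantile = 0.99,
    gwas = list(alpha = 0.01, prune = c(50, 5, 0.3), n_pcs = 3,
                merge_distance_bp = 200000, threshold_mode = "floor"),
    expression = list(up_cut = 1.5, down_cut = 0.67),
    haplotype = list(flank_bp = 0, max_missing_frac = 0.2, n_perm = 1000))
  if (is.character(overrides)) overrides <- jsonlite::read_json(overrides,
                                                                simplifyVector = TRUE)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  if (is.null(cfg$sim) && is.null(cfg$inputs$vcf))
    cfg$sim <- sim_config(seed = cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_order <- c("simulate", "filter", "windows", "sweeps", "classify",
                 "gwas", "candidates")

stage_requires <- list(
  simulate = character(0),
  filter = "simulate",
  windows = "filter",
  sweeps = "windows",
  classify = "filter",
  gwas = "filter",
  candidates = c("gwas", "sweeps"))

stage_outputs <- list(
  simulate = c("data/genotypes.vcf", "data/samples.tsv", "data/chrom_lengths.tsv"),
  filter = c("filter/filtered.vcf", "filter/samples.tsv", "filter/counts.tsv"),
  windows = c("windows/pi_ecotype.tsv", "windows/pi_progenitor.tsv",
              "windows/pi_wild.tsv", "windows/fst.tsv"),
  sweeps = c("sweeps/rod_windows.tsv", "sweeps/rod_regions.tsv",
             "sweeps/fst_regions.tsv", "sweeps/composite_windows.tsv",
             "sweeps/composite_regions.tsv"),
  classify = c("classify/variant_classes.tsv", "classify/afd_summary.tsv"),
  gwas = c("gwas/assoc.tsv", "gwas/qtls.tsv", "gwas/meta.json"),
  candidates = c("candidates/candidates.tsv"))

#' Run one pipeline stage
#'
#' Stages are idempotent: re-running with the same config and seed overwrites
#' outputs identically. A stage whose upstream outputs are missing aborts
#' with an error naming the stage to run first.
#'
#' @param name one of `simulate`, `filter`, `windows`, `sweeps`, `classify`,
#'   `gwas`, `candidates`.
#' @param config a [pipeline_config].
#' @param out_dir run directory.
#' @return named md5 vector of the stage's outputs (the manifest delta),
#'   invisibly.
#' @export
run_stage <- function(name, config, out_dir) {
  name <- match.arg(name, stage_order)
  for (up in stage_requires[[name]]) {
    need <- file.path(out_dir, stage_outputs[[up]])
    if (up == "simulate" && !is.null(config$inputs$vcf)) next
    if (!all(file.exists(need)))
      stop("stage '", name, "' needs outputs of stage '", up,
           "'; run that stage first")
  }
  dir.create(file.path(out_dir, dirname(stage_outputs[[name]][1])),
             recursive = TRUE, showWarnings = FALSE)
  get(paste0("stage_", name))(config, out_dir)
  files <- file.path(out_dir, stage_outputs[[name]])
  files <- files[file.exists(files)]
  delta <- tools::md5sum(files)
  names(delta) <- substring(files, nchar(out_dir) + 2)
  log_line(out_dir, name, "done")
  invisible(delta)
}

log_line <- function(out_dir, stage, msg) {
  cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              stage, msg),
      file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run the whole pipeline
#'
#' simulate (or ingest) -> filter -> windows (pi, F_ST) -> sweeps (ROD,
#' F_ST outliers, composite) -> variant typing -> GWAS -> candidate screen,
#' then writes `manifest.json` (config hash, seed, per-stage file md5s; no
#' timestamps, so two runs with identical config and seed produce
#' byte-identical manifests). Timing information goes to `run.log` instead.
#'
#' @param config a [pipeline_config].
#' @param out_dir run directory.
#' @return the manifest list, invisibly.
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "run.log"))
  stages <- stage_order
  if (!is.null(config$inputs$vcf)) stages <- setdiff(stages, "simulate")
  manifest <- list(config_hash = config_hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(packageVersion("riceeco")),
                   stages = list())
  for (st in stages)
    manifest$stages[[st]] <- as.list(run_stage(st, config, out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# ---- stage implementations ----------------------------------------------

stage_simulate <- function(config, out_dir) {
  ds <- simulate_dataset(config$sim)
  ds$genes <- simulate_genes(config$sim)
  ds$expression <- simulate_expression(ds$genes, ds$truth,
                                       seed = derive_seed(config$seed, "expr"))
  ds$truth$de_genes <- attr(ds$expression, "de_genes")
  write_fixture(ds, file.path(out_dir, "data"))
}

pipeline_paths <- function(config, out_dir) {
  ins <- config$inputs
  list(vcf = ins$vcf %||% file.path(out_dir, "data/genotypes.vcf"),
       samples = ins$samples %||% file.path(out_dir, "data/samples.tsv"),
       genes = ins$genes %||% {
         p <- file.path(out_dir, "data/genes.bed")
         if (file.exists(p)) p else NULL
       },
       expression = ins$expression %||% {
         p <- file.path(out_dir, "data/expression.tsv")
         if (file.exists(p)) p else NULL
       },
       chrom_lengths = ins$chrom_lengths %||%
         file.path(out_dir, "data/chrom_lengths.tsv"))
}

read_chrom_lengths <- function(config, out_dir, G) {
  p <- pipeline_paths(config, out_dir)$chrom_lengths
  if (!is.null(p) && file.exists(p)) {
    tab <- read_tsv(p)
    stats::setNames(tab$length, tab$chrom)
  } else {  # infer: round the last SNP up to a window boundary
    sz <- config$windows$size
    vapply(split(G$variants$pos, G$variants$chrom),
           function(p) ceiling(max(p) / sz) * sz, numeric(1))
  }
}

stage_filter <- function(config, out_dir) {
  p <- pipeline_paths(config, out_dir)
  G <- read_vcf(p$vcf)
  tab <- read_sample_table(p$samples)
  n0 <- n_variants(G)
  core <- select_core_samples(tab, config$min_q, keep_no_q = TRUE)
  G <- subset_genotypes(G, samples = core$sample_id)
  G <- filter_variants(G, config$filters$max_missing_rate, config$filters$min_maf)
  write_vcf(G, file.path(out_dir, "filter/filtered.vcf"))
  write_tsv(core, file.path(out_dir, "filter/samples.tsv"))
  write_tsv(data.frame(step = c("input_snps", "kept_snps",
                                "input_samples", "kept_samples"),
                       n = c(n0, n_variants(G), nrow(tab), nrow(core))),
            file.path(out_dir, "filter/counts.tsv"))
}

pipeline_populations <- function(config, tab) {
  lapply(config$groups, function(g) tab$sample_id[tab$group %in% g])
}

stage_windows <- function(config, out_dir) {
  G <- read_vcf(file.path(out_dir, "filter/filtered.vcf"))
  tab <- read_sample_table(file.path(out_dir, "filter/samples.tsv"))
  pops <- pipeline_populations(config, tab)
  cl <- read_chrom_lengths(config, out_dir, G)
  grid <- make_windows(cl, config$windows$size, config$windows$step)
  for (nm in c("ecotype", "progenitor", "wild")) {
    pw <- pi_windowed(G, pops[[nm]], grid)
    write_tsv(pw, file.path(out_dir, sprintf("windows/pi_%s.tsv", nm)))
  }
  fst <- fst_windowed(G, pops$ecotype, pops$progenitor, grid)
  fst$genome_mean <- attr(fst, "genome_mean")
  write_tsv(fst, file.path(out_dir, "windows/fst.tsv"))
}

reread_window_stat <- function(path, statistic) {
  tab <- read_tsv(path)
  class(tab) <- c("window_stat", "data.frame")
  tab
}

stage_sweeps <- function(config, out_dir) {
  pi_w <- reread_window_stat(file.path(out_dir, "windows/pi_wild.tsv"), "pi")
  pi_e <- reread_window_stat(file.path(out_dir, "windows/pi_ecotype.tsv"), "pi")
  fst <- reread_window_stat(file.path(out_dir, "windows/fst.tsv"), "fst")
  genes <- NULL
  p <- pipeline_paths(config, out_dir)
  if (!is.null(p$genes)) genes <- read_genes(p$genes)
  rod <- rod_windowed(pi_w, pi_e)
  write_tsv(rod, file.path(out_dir, "sweeps/rod_windows.tsv"))
  rr <- annotate_regions(call_outlier_regions(rod, config$quantile), genes)
  write_tsv(rr, file.path(out_dir, "sweeps/rod_regions.tsv"))
  fr <- annotate_regions(call_outlier_regions(fst, config$quantile), genes)
  write_tsv(fr, file.path(out_dir, "sweeps/fst_regions.tsv"))
  G <- read_vcf(file.path(out_dir, "filter/filtered.vcf"))
  tab <- read_sample_table(file.path(out_dir, "filter/samples.tsv"))
  pops <- pipeline_populations(config, tab)
  cl <- read_chrom_lengths(config, out_dir, G)
  cgrid <- make_windows(cl, config$composite_window, config$composite_window)
  comp <- composite_sweep_scan(G, pops$ecotype, cgrid)
  write_tsv(comp, file.path(out_dir, "sweeps/composite_windows.tsv"))
  cr <- annotate_regions(call_outlier_regions(comp, config$quantile), genes)
  write_tsv(cr, file.path(out_dir, "sweeps/composite_regions.tsv"))
}

stage_classify <- function(config, out_dir) {
  G <- read_vcf(file.path(out_dir, "filter/filtered.vcf"))
  tab <- read_sample_table(file.path(out_dir, "filter/samples.tsv"))
  pops <- pipeline_populations(config, tab)
  cls <- classify_variants(G, pops$ecotype, pops$progenitor)
  write_tsv(cls, file.path(out_dir, "classify/variant_classes.tsv"))
  write_tsv(afd_summary(cls), file.path(out_dir, "classify/afd_summary.tsv"))
}

stage_gwas <- function(config, out_dir) {
  G <- read_vcf(file.path(out_dir, "filter/filtered.vcf"))
  tab <- read_sample_table(file.path(out_dir, "filter/samples.tsv"))
  cult <- tab[!is.na(tab$q_value), , drop = FALSE]   # wild excluded from GWAS
  G <- subset_genotypes(G, samples = cult$sample_id)
  G <- filter_variants(G, config$filters$max_missing_rate, config$filters$min_maf)
  y <- encode_phenotype(cult, config$groups$ecotype)
  pr <- config$gwas$prune
  kept <- ld_prune(G, pr[1], pr[2], pr[3])
  n_eff <- attr(kept, "n_independent")
  thr <- suggestive_threshold(n_eff, config$gwas$alpha,
                              config$gwas$threshold_mode)
  pcs <- pca_covariates(subset_genotypes(G, variants = kept),
                        config$gwas$n_pcs)
  K <- grm(G)
  assoc <- lmm_scan(G, y, covariates = pcs, K = K)
  genes <- NULL
  p <- pipeline_paths(config, out_dir)
  if (!is.null(p$genes)) genes <- read_genes(p$genes)
  qtls <- call_qtls(assoc, thr, config$gwas$merge_distance_bp, genes)
  write_tsv(assoc, file.path(out_dir, "gwas/assoc.tsv"))
  write_tsv(qtls, file.path(out_dir, "gwas/qtls.tsv"))
  jsonlite::write_json(list(n_independent = n_eff, threshold = thr,
                            delta = attr(assoc, "delta"),
                            n_snps = n_variants(G), n_samples = nrow(cult)),
                       file.path(out_dir, "gwas/meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_candidates <- function(config, out_dir) {
  p <- pipeline_paths(config, out_dir)
  if (is.null(p$genes) || is.null(p$expression)) {
    write_tsv(data.frame(), file.path(out_dir, "candidates/candidates.tsv"))
    return(invisible())
  }
  genes <- read_genes(p$genes)
  expr <- classify_expression(read_expression(p$expression),
                              config$expression$up_cut,
                              config$expression$down_cut)
  qtls <- read_tsv(file.path(out_dir, "gwas/qtls.tsv"))
  rod <- read_tsv(file.path(out_dir, "sweeps/rod_regions.tsv"))
  regions <- rbind(qtls[, c("chrom", "start", "end")],
                   rod[, c("chrom", "start", "end")])
  cand <- screen_candidates(regions, genes, expr)
  if (nrow(cand) > 0) {
    G <- read_vcf(file.path(out_dir, "filter/filtered.vcf"))
    tab <- read_sample_table(file.path(out_dir, "filter/samples.tsv"))
    hp <- config$haplotype
    stat <- t(vapply(unique(cand$gene_id[cand$candidate]), function(gid) {
      g <- genes[genes$gene_id == gid, ]
      reg <- list(chrom = g$chrom, start = max(0, g$start - hp$flank_bp),
                  end = g$end + hp$flank_bp)
      ht <- tryCatch(haplotype_table(G, reg, tab, hp$max_missing_frac),
                     error = function(e) NULL)
      if (is.null(ht)) return(c(NA_real_, NA_real_))
      hd <- suppressWarnings(
        haplotype_differentiation(ht, hp$n_perm,
                                  derive_seed(config$seed, paste0("hap_", gid))))
      c(hd$chi2, hd$p_perm)
    }, numeric(2)))
    if (length(stat)) {
      mi <- match(cand$gene_id, rownames(stat))
      cand$hap_chi2 <- stat[mi, 1]
      cand$hap_p_perm <- stat[mi, 2]
    }
  }
  write_tsv(cand, file.path(out_dir, "candidates/candidates.tsv"))
}
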