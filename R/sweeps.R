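#' Reduction of diversity (ROD) per window
#'
#' ROD is the ratio of ancestral to derived windowed diversity,
#' `pi_anc / pi_der` (e.g. pi_wild / pi_ecotype); large values mark windows
#' where the derived population lost diversity, the classic domestication
#' sweep signal. Zero-diversity derived windows would be infinite, so the
#' derived value is floored at epsilon = the 1st percentile of the positive
#' derived-pi values; floored windows are flagged `"floored"`. Windows with
#' zero ancestral diversity are flagged `"undefined"` (value `NA`) and are
#' excluded from outlier ranking.
#'
#' @param pi_ancestral,pi_derived `window_stat` tables from [pi_windowed] on
#'   the same grid.
#' @return a `window_stat` data.frame with `statistic = "rod"`.
#' @export
rod_windowed <- function(pi_ancestral, pi_derived) {
  if (!same_grid(pi_ancestral, pi_derived)) stop("window grids differ")
  pa <- pi_ancestral$value; pd <- pi_derived$value
  pos <- pd[pd > 0 & !is.na(pd)]
  eps <- if (length(pos)) as.numeric(quantile(pos, 0.01, type = 1))
         else .Machine$double.eps
  floored <- !is.na(pd) & pd < eps
  val <- pa / pmax(pd, eps)
  undef <- is.na(pa) | pa == 0
  val[undef] <- NA_real_
  flag <- ifelse(undef, "undefined", ifelse(floored, "floored", ""))
  out <- window_stats(pi_ancestral[, c("chrom", "start", "end")],
                      val, pi_derived$n_snps, "rod", flag)
  attr(out, "epsilon") <- eps
  out
}

#' Call top-quantile outlier regions from a window scan
#'
#' Ranks finite window values, keeps the top `1 - quantile` fraction
#' (`floor((1 - q) * M)` windows, at least one; ties at the threshold value
#' are included), and merges selected windows whose intervals overlap or are
#' bookended into single candidate regions -- so the overlapping sliding
#' windows of one sweep collapse to one span.
#'
#' @param stats a `window_stat` data.frame.
#' @param quantile empirical quantile defining the threshold (default top 1%).
#' @param merge merge adjacent selected windows into regions?
#' @return a data.frame of regions (`chrom`, `start`, `end`, `peak_value`,
#'   `mean_value`, `n_windows`, `scan`), sorted and non-overlapping, with
#'   attribute `threshold`.
#' @export
call_outlier_regions <- function(stats, quantile = 0.99, merge = TRUE) {
  stopifnot(quantile > 0, quantile < 1)
  s <- stats[!is.na(stats$value), , drop = FALSE]
  M <- nrow(s)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_value = numeric(), mean_value = numeric(),
                      n_windows = integer(), scan = character())
  if (M == 0) return(empty)
  if (M < 100) warning("only ", M, " ranked windows; top-quantile threshold is coarse")
  if (length(unique(s$value)) == 1L) {
    warning("all window values identical; no outlier regions called")
    return(empty)
  }
  k <- max(1L, floor((1 - quantile) * M))
  thr <- sort(s$value, decreasing = TRUE)[k]
  sel <- s[s$value >= thr, , drop = FALSE]
  scan_name <- s$statistic[1]
  if (!merge) {
    out <- data.frame(chrom = sel$chrom, start = sel$start, end = sel$end,
                      peak_value = sel$value, mean_value = sel$value,
                      n_windows = 1L, scan = scan_name)
  } else {
    out <- do.call(rbind, lapply(split(sel, sel$chrom), function(ss) {
      ir <- IRanges::IRanges(ss$start + 1, ss$end)  # 1-based closed
      red <- IRanges::reduce(ir)                     # merges overlap + bookend
      hit <- IRanges::findOverlaps(ir, red)
      grp <- S4Vectors::subjectHits(hit)
      data.frame(chrom = ss$chrom[1],
                 start = IRanges::start(red) - 1,
                 end = IRanges::end(red),
                 peak_value = as.numeric(tapply(ss$value, grp, max)),
                 mean_value = as.numeric(tapply(ss$value, grp, mean)),
                 n_windows = as.integer(tapply(ss$value, grp, length)),
                 scan = scan_name)
    }))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "quantile") <- quantile
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Composite multi-signature sweep scan
#'
#' A parameter-light stand-in for mu-statistic-style sweep detectors, run on a
#' non-overlapping grid. Three window-level signatures are each converted to a
#' genome-wide rank-based normal score z and summed:
#' S1 = -z(pi), the diversity deficit; S2 = z(f_tail), where f_tail is the
#' fraction of in-window SNPs whose minor-allele count is at most 2 or whose
#' alt frequency reaches 1 - 2/n (the SFS distortion a sweep leaves, counted
#' over sites segregating in the population); S3 = z(LD ratio), where
#' the LD ratio is (mean r-squared within the left half + within the right
#' half) / (mean cross-half r-squared + 0.01), capturing the LD block
#' structure flanking a swept site. Windows with fewer than 5 SNPs get
#' composite = S1 only and are flagged `"low_snps"`.
#'
#' @param G a [genotype_matrix].
#' @param samples population sample ids/indices (>= 4 samples; pairwise
#'   r-squared is unstable below that).
#' @param grid a non-overlapping [make_windows] grid (step == size).
#' @return a `window_stat` data.frame with `statistic = "composite"`.
#' @export
composite_sweep_scan <- function(G, samples, grid) {
  if (attr(grid, "step") != attr(grid, "window_size"))
    stop("composite scan requires a non-overlapping grid (step == size)")
  si <- if (is.character(samples)) match(samples, G$samples) else samples
  if (anyNA(si)) stop("unknown sample id(s)")
  if (length(si) < 4) stop("population too small for r^2 (need >= 4 samples)")
  sc <- site_counts(G, si)
  n <- sc$n_called
  mac <- pmin(sc$alt, n - sc$alt)
  # only sites segregating in the scanned population are its SNPs; sites
  # fixed here (but variable in other populations) carry no sweep signal
  seg <- n >= 2L & mac >= 1L
  p <- sc$alt / pmax(n, 1)
  tail_site <- seg & (mac <= 2 | p >= 1 - 2 / pmax(n, 1))
  v <- G$variants
  pi_w <- pi_windowed(G, si, grid)$value
  wtail <- window_sums(grid, v$chrom, v$pos, as.numeric(tail_site), seg)
  n_snps <- wtail[, "n"]
  f_tail <- ifelse(n_snps > 0, wtail[, "sum"] / n_snps, NA_real_)

  ld_ratio <- rep(NA_real_, nrow(grid))
  cc <- G$calls[si, , drop = FALSE]
  for (w in which(n_snps >= 5)) {
    idx <- which(v$chrom == grid$chrom[w] & v$pos - 1 >= grid$start[w] &
                   v$pos - 1 < grid$end[w] & seg)
    idx <- idx[order(v$pos[idx])]
    half <- length(idx) %/% 2
    X <- cc[, idx, drop = FALSE]
    r2 <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))^2
    li <- seq_len(half); ri <- (half + 1):length(idx)
    m_within <- mean(r2[li, li][upper.tri(r2[li, li])], na.rm = TRUE) +
      mean(r2[ri, ri][upper.tri(r2[ri, ri])], na.rm = TRUE)
    m_cross <- mean(r2[li, ri], na.rm = TRUE)
    if (is.finite(m_within) && is.finite(m_cross))
      ld_ratio[w] <- m_within / (m_cross + 0.01)
  }

  s1 <- -rank_z(pi_w)
  s2 <- rank_z(f_tail)
  s3 <- rank_z(ld_ratio)
  low <- n_snps < 5
  comp <- ifelse(low, s1,
                 s1 + ifelse(is.na(s2), 0, s2) + ifelse(is.na(s3), 0, s3))
  window_stats(grid, comp, n_snps, "composite",
               flag = ifelse(low, "low_snps", ""))
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region iff the half-open intervals share at least
#' one base; a gene that merely abuts a region boundary is not assigned.
#'
#' @param regions a region data.frame (`chrom`, `start`, `end`, ...).
#' @param genes a gene table (`gene_id`, `chrom`, `start`, `end`).
#' @return `regions` with a `genes` column (comma-joined gene ids).
#' @export
annotate_regions <- function(regions, genes) {
  regions$genes <- ""
  if (nrow(regions) == 0 || is.null(genes) || nrow(genes) == 0) return(regions)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  hit <- GenomicRanges::findOverlaps(rg, gg)
  if (length(hit)) {
    ids <- tapply(genes$gene_id[S4Vectors::subjectHits(hit)],
                  S4Vectors::queryHits(hit),
                  function(g) paste(sort(unique(g)), collapse = ","))
    regions$genes[as.integer(names(ids))] <- unname(ids)
  }
  regions
}

#' Genome span and fraction covered by called regions
#'
#' @param regions non-overlapping region data.frame.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return `list(span_bp =, fraction =)`.
#' @export
genome_fraction <- function(regions, chrom_lengths) {
  if (nrow(regions) == 0) return(list(span_bp = 0, fraction = 0))
  for (cn in unique(regions$chrom)) {
    rr <- regions[regions$chrom == cn, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (nrow(rr) > 1 && any(rr$start[-1] < rr$end[-nrow(rr)]))
      stop("overlapping regions; merge before computing genome fraction")
  }
  span <- sum(regions$end - regions$start)
  list(span_bp = span, fraction = span / sum(as.numeric(chrom_lengths)))
}

#' Intersect region sets from different scans
#'
#' Utility to find spans called by every provided scan (e.g. ROD and the
#' composite scan, or the same scan across ecotypes).
#'
#' @param ... two or more region data.frames.
#' @return a data.frame of intersection intervals (`chrom`, `start`, `end`).
#' @export
intersect_regions <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 2)
  as_gr <- function(r) GenomicRanges::GRanges(r$chrom,
                                              IRanges::IRanges(r$start + 1, r$end))
  cur <- as_gr(sets[[1]])
  for (r in sets[-1]) cur <- GenomicRanges::intersect(cur, as_gr(r))
  data.frame(chrom = as.character(GenomicRanges::seqnames(cur)),
             start = GenomicRanges::start(cur) - 1,
             end = GenomicRanges::end(cur), stringsAsFactors = FALSE)
}
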