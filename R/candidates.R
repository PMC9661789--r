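#' Classify genes by the two-ratio RPKM rule
#'
#' Each gene carries four RPKM values: deepwater and non-deepwater accessions
#' under submergence, and the deepwater variety after and before submergence.
#' A gene is "up" when both ratios (deepwater/non-deepwater and after/before)
#' exceed `up_cut`, "down" when both fall below `down_cut` -- the direction
#' must be consistent across the two comparisons -- and "excluded" when all
#' four values are exactly zero (unexpressed, e.g. retrotransposon genes).
#' Everything else is "unclassified". A zero denominator with a positive
#' numerator counts as exceeding `up_cut` (flagged infinite ratio);
#' inequalities are strict.
#'
#' @param expr expression table (`gene_id`, `rpkm_dw_sub`, `rpkm_ndw_sub`,
#'   `rpkm_after`, `rpkm_before`).
#' @param up_cut,down_cut ratio cutoffs (defaults 1.5 and 0.67).
#' @return `expr` with columns `ratio_dw`, `ratio_ab`, `label`.
#' @export
classify_expression <- function(expr, up_cut = 1.5, down_cut = 0.67) {
  vals <- as.matrix(expr[, c("rpkm_dw_sub", "rpkm_ndw_sub",
                             "rpkm_after", "rpkm_before")])
  if (any(vals < 0, na.rm = TRUE)) stop("negative RPKM")
  ratio <- function(num, den) ifelse(den > 0, num / den,
                                     ifelse(num > 0, Inf, NA_real_))
  r_dw <- ratio(expr$rpkm_dw_sub, expr$rpkm_ndw_sub)
  r_ab <- ratio(expr$rpkm_after, expr$rpkm_before)
  all_zero <- rowSums(vals == 0) == 4L
  up <- !is.na(r_dw) & !is.na(r_ab) & r_dw > up_cut & r_ab > up_cut
  down <- !is.na(r_dw) & !is.na(r_ab) & r_dw < down_cut & r_ab < down_cut
  expr$ratio_dw <- r_dw
  expr$ratio_ab <- r_ab
  expr$label <- ifelse(all_zero, "excluded",
                       ifelse(up, "up", ifelse(down, "down", "unclassified")))
  expr
}

#' Screen regions for expression-supported candidate genes
#'
#' Reports every gene overlapping a QTL or sweep region together with its
#' expression label; candidates are the overlapping genes labelled up or
#' down. Region genes with no expression record are reported with label
#' `"no-data"`, never dropped.
#'
#' @param regions QTL or sweep-region data.frame (`chrom`, `start`, `end`).
#' @param genes gene table (0-based half-open).
#' @param expr expression table (classified or raw; raw tables are run
#'   through [classify_expression] first).
#' @param up_cut,down_cut passed to [classify_expression].
#' @return data.frame (`region`, `gene_id`, `label`, `ratio_dw`, `ratio_ab`,
#'   `candidate`).
#' @export
screen_candidates <- function(regions, genes, expr,
                              up_cut = 1.5, down_cut = 0.67) {
  empty <- data.frame(region = character(), gene_id = character(),
                      label = character(), ratio_dw = numeric(),
                      ratio_ab = numeric(), candidate = logical())
  if (nrow(regions) == 0) return(empty)
  if (is.null(expr$label)) expr <- classify_expression(expr, up_cut, down_cut)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  hit <- GenomicRanges::findOverlaps(rg, gg)
  if (length(hit) == 0) return(empty)
  ri <- S4Vectors::queryHits(hit); gi <- S4Vectors::subjectHits(hit)
  out <- data.frame(
    region = sprintf("%s:%d-%d", regions$chrom[ri],
                     as.integer(regions$start[ri]), as.integer(regions$end[ri])),
    gene_id = genes$gene_id[gi], stringsAsFactors = FALSE)
  mi <- match(out$gene_id, expr$gene_id)
  out$label <- ifelse(is.na(mi), "no-data", expr$label[mi])
  out$ratio_dw <- expr$ratio_dw[mi]
  out$ratio_ab <- expr$ratio_ab[mi]
  out$candidate <- out$label %in% c("up", "down")
  out
}

#' Pseudo-haplotype table over a genomic region
#'
#' Builds one allele string per accession over the region's SNPs from diploid
#' dosages (0 = ref, 2 = alt) -- justified by the near-complete homozygosity
#' of inbred rice lines. Heterozygous and missing calls are filled with the
#' region-wide major allele when the accession's het+missing fraction is at
#' most `max_missing_frac`; otherwise the accession is dropped. Identical
#' strings are pooled and counted per group.
#'
#' @param G a [genotype_matrix].
#' @param region `list(chrom =, start =, end =)`, 0-based half-open.
#' @param groups sample table (`sample_id`, `group`).
#' @param max_missing_frac accession-level tolerance (default 0.2).
#' @return list with `counts` (haplotype x group matrix), `assignments`
#'   (per-retained-sample haplotype and group), `dropped` (sample ids).
#' @export
haplotype_table <- function(G, region, groups, max_missing_frac = 0.2) {
  vi <- which(G$variants$chrom == region$chrom &
                G$variants$pos - 1 >= region$start &
                G$variants$pos - 1 < region$end)
  if (length(vi) == 0) stop("region contains no SNP")
  si <- match(groups$sample_id, G$samples)
  if (anyNA(si)) stop("samples missing from genotype matrix")
  cc <- G$calls[si, vi, drop = FALSE]
  badfrac <- rowMeans(is.na(cc) | cc == 1L)
  keep <- badfrac <= max_missing_frac
  if (!any(keep)) stop("all accessions exceed the het+missing tolerance of ",
                       max_missing_frac)
  cc <- cc[keep, , drop = FALSE]
  # region-wide major allele per site, from retained homozygous calls
  major <- vapply(seq_along(vi), function(j) {
    v <- cc[, j]; v <- v[!is.na(v) & v != 1L]
    if (!length(v)) 0L else if (sum(v == 2L) > sum(v == 0L)) 2L else 0L
  }, integer(1))
  strings <- vapply(seq_len(nrow(cc)), function(i) {
    v <- cc[i, ]
    fill <- is.na(v) | v == 1L
    v[fill] <- major[fill]
    paste(ifelse(v == 2L, "A", "R"), collapse = "")
  }, character(1))
  grp <- groups$group[keep]
  counts <- table(haplotype = strings, group = grp)
  counts <- unclass(counts)[, , drop = FALSE]
  list(counts = counts,
       assignments = data.frame(sample_id = groups$sample_id[keep],
                                group = grp, haplotype = strings,
                                stringsAsFactors = FALSE),
       dropped = groups$sample_id[!keep])
}

#' Haplotype-by-group differentiation test
#'
#' Pearson chi-square on the haplotype x group count table, with the p-value
#' from a group-label permutation null (`p = (1 + #{perm >= obs}) /
#' (n_perm + 1)`), since haplotype counts are far from chi-square asymptotics
#' in small ecotype panels. Deterministic for a fixed seed.
#'
#' @param tab output of [haplotype_table].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return `list(chi2 =, p_perm =)`.
#' @export
haplotype_differentiation <- function(tab, n_perm = 10000, seed = 1) {
  asg <- tab$assignments
  if (nrow(tab$counts) < 2 || length(unique(asg$group)) < 2) {
    warning("degenerate haplotype table; p = 1")
    return(list(chi2 = 0, p_perm = 1))
  }
  chi2_of <- function(hap, grp) {
    ct <- table(hap, grp)
    E <- outer(rowSums(ct), colSums(ct)) / sum(ct)
    sum((ct - E)^2 / E)
  }
  obs <- chi2_of(asg$haplotype, asg$group)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      chi2_of(asg$haplotype, sample(asg$group)) >= obs - 1e-12
    }, logical(1)))
  })
  list(chi2 = obs, p_perm = (1 + hits) / (n_perm + 1))
}
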