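#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.2, GT field) with Bioconductor's `VariantAnnotation` and
#' keeps biallelic SNPs only. Multi-allelic and non-SNP records are skipped and
#' counted (see `attr(, "n_skipped")`). Genotype separators `/` and `|` are
#' both accepted; half-calls and `./.` are treated as missing.
#'
#' @param path VCF file.
#' @param region optional `list(chrom =, start =, end =)`, 0-based half-open;
#'   variants outside it are dropped after parsing.
#' @return a [genotype_matrix] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  ref_chr <- as.character(VariantAnnotation::ref(vcf))
  alt_chr <- rep(NA_character_, length(vcf))
  one <- n_alt == 1L
  alt_chr[one] <- as.character(unlist(alt[one]))
  snp <- one & nchar(ref_chr) == 1L & !is.na(alt_chr) & nchar(alt_chr) == 1L
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[snp, , drop = FALSE]
  calls <- gt_to_dosage(gt)
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snp],
    pos = GenomicRanges::start(rr)[snp],
    ref = ref_chr[snp], alt = alt_chr[snp], stringsAsFactors = FALSE)
  if (!is.null(region)) {
    keep <- variants$chrom == region$chrom &
      variants$pos - 1L >= region$start & variants$pos - 1L < region$end
    variants <- variants[keep, , drop = FALSE]
    calls <- calls[, keep, drop = FALSE]
  }
  G <- genotype_matrix(calls, variants, colnames(gt))
  attr(G, "n_skipped") <- n_skipped
  G
}

# "0/0" -> 0, "0|1"/"1/0" -> 1, "1/1" -> 2, anything with '.' -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }, integer(1))
  t(matrix(map[match(gt, u)], nrow = nrow(gt), ncol = ncol(gt)))
}

#' Write a genotype matrix as VCF v4.2 (GT only)
#'
#' @param G a [genotype_matrix].
#' @param path output file.
#' @param chrom_lengths optional named vector; emitted as `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path, chrom_lengths = NULL) {
  gt <- c("0/0", "0/1", "1/1")[G$calls + 1L]
  gt[is.na(gt)] <- "./."
  gm <- matrix(gt, nrow = n_samples(G))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", G$samples), collapse = "\t"))
  v <- G$variants
  body <- data.table::data.table(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT")
  body <- cbind(body, data.table::as.data.table(t(gm)))
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply the missing-rate and MAF variant filters
#'
#' Keeps variants whose missing fraction is `<= max_missing_rate` and whose
#' minor-allele frequency over non-missing alleles is `>= min_maf`; both
#' boundaries are inclusive, matching the "missing rate of <=50% and minor
#' allele frequencies of >=5%" convention. Variants with no calls at all are
#' dropped (their MAF is undefined).
#'
#' @param G a [genotype_matrix].
#' @param max_missing_rate maximum tolerated fraction of missing genotypes.
#' @param min_maf minimum minor-allele frequency.
#' @return the filtered [genotype_matrix].
#' @export
filter_variants <- function(G, max_missing_rate = 0.5, min_maf = 0.05) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(G$calls))
  maf <- variant_maf(G)
  keep <- miss <= max_missing_rate & !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("all variants removed by filters")
  subset_genotypes(G, variants = keep)
}

#' Restrict a sample table to high-ancestry ("typical") accessions
#'
#' Keeps samples whose ADMIXTURE ancestry proportion is strictly greater than
#' `min_q` ("Q value greater than 0.8"). Samples with no `q_value` (wild
#' accessions) are kept only when `keep_no_q = TRUE`.
#'
#' @param tab sample table with columns `sample_id`, `group`, `q_value`.
#' @param min_q strict lower bound on the ancestry proportion.
#' @param keep_no_q pass through samples lacking a Q value?
#' @return the filtered sample table.
#' @export
select_core_samples <- function(tab, min_q = 0.8, keep_no_q = FALSE) {
  if (min_q < 0 || min_q > 1) stop("min_q must be in [0, 1]")
  has_q <- !is.na(tab$q_value)
  keep <- (has_q & tab$q_value > min_q) | (!has_q & keep_no_q)
  tab[keep, , drop = FALSE]
}

#' Read / write the plain-text side tables
#'
#' `read_sample_table` expects columns `sample_id`, `group`, `q_value`
#' (`q_value` may be `NA` for wild accessions); `read_expression` expects
#' `gene_id`, `rpkm_dw_sub`, `rpkm_ndw_sub`, `rpkm_after`, `rpkm_before`;
#' `read_genes` reads BED (0-based half-open, via `rtracklayer`) into a sorted
#' gene table; `write_bed` writes such a table back. `write_tsv`/`read_tsv`
#' are thin deterministic wrappers used for every other artifact.
#'
#' @param path file path.
#' @return a data.frame (readers) or `path` invisibly (writers).
#' @export
read_sample_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = c("NA", "")))
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$q_value)) tab$q_value <- NA_real_
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id")
  tab
}

#' @rdname read_sample_table
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  g <- data.frame(gene_id = gr$name %||% paste0("g", seq_along(gr)),
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,   # back to 0-based
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  stringsAsFactors = FALSE)
  g$strand[g$strand == "*"] <- "+"
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  rownames(g) <- NULL
  if (any(g$start >= g$end)) stop("gene with start >= end")
  g
}

#' @rdname read_sample_table
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   0-based half-open.
#' @export
write_bed <- function(genes, path) {
  g <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand %||% "+")
  gr$name <- g$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_sample_table
#' @export
read_expression <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("gene_id", "rpkm_dw_sub", "rpkm_ndw_sub", "rpkm_after", "rpkm_before")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_sample_table
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_sample_table
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = c("NA", "")))
}
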