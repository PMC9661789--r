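#' Genotype matrix of biallelic SNPs
#'
#' The substrate of every scan: an integer matrix of alternative-allele dosages
#' (samples x variants, codes 0/1/2, `NA` = missing) plus a variant table with
#' 1-based coordinates. Variants must be biallelic SNPs, unique on
#' `(chrom, pos)` and sorted by position within contiguous chromosome blocks;
#' chromosome names are pass-through strings, ordered by first appearance.
#'
#' @param calls integer matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples character vector of sample ids (defaults to rownames).
#' @return an object of class `genotype_matrix` with elements `calls`,
#'   `variants`, `samples`.
#' @export
genotype_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(nrow(calls) == length(samples), ncol(calls) == nrow(variants))
  variants <- data.frame(chrom = as.character(variants$chrom),
                         pos = as.integer(variants$pos),
                         ref = as.character(variants$ref),
                         alt = as.character(variants$alt),
                         stringsAsFactors = FALSE)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(paste(variants$chrom, variants$pos)))
    stop("duplicate (chrom, pos)")
  if (any(nchar(variants$ref) != 1L) || any(nchar(variants$alt) != 1L))
    stop("variants must be biallelic SNPs (single-base REF and ALT)")
  # chromosome blocks contiguous, positions increasing within block
  r <- rle(variants$chrom)
  if (anyDuplicated(r$values)) stop("variants of one chromosome must be contiguous")
  if (any(unlist(tapply(variants$pos, factor(variants$chrom, levels = r$values),
                        function(p) diff(p) <= 0))))
    stop("positions must be strictly increasing within chromosomes")
  rownames(calls) <- samples
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNPs on %d chromosome(s)\n",
              n_samples(x), n_variants(x), length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing: %.2f%%   het: %.2f%%\n", 100 * miss,
              100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param G a `genotype_matrix`.
#' @export
n_samples <- function(G) length(G$samples)

#' @rdname genotype_matrix
#' @export
n_variants <- function(G) nrow(G$variants)

#' Subset a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param samples sample ids (character) or indices to keep; `NULL` keeps all.
#' @param variants variant indices (integer/logical) to keep; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(G$samples)
        else if (is.character(samples)) match(samples, G$samples)
        else samples
  if (anyNA(si)) stop("unknown sample id(s): ",
                      paste(samples[is.na(si)], collapse = ", "))
  vi <- if (is.null(variants)) seq_len(n_variants(G)) else which2idx(variants, n_variants(G))
  genotype_matrix(G$calls[si, vi, drop = FALSE], G$variants[vi, , drop = FALSE],
                  G$samples[si])
}

which2idx <- function(v, n) {
  if (is.logical(v)) { stopifnot(length(v) == n); which(v) } else as.integer(v)
}

# per-variant allele bookkeeping over a sample subset:
# n_called (alleles), alt count, het count -- the SiteFreq primitives
site_counts <- function(G, samples = NULL) {
  cc <- if (is.null(samples)) G$calls else {
    si <- if (is.character(samples)) match(samples, G$samples) else samples
    if (anyNA(si)) stop("unknown sample id(s)")
    G$calls[si, , drop = FALSE]
  }
  called <- colSums(!is.na(cc))
  list(n_called = 2L * called,
       alt = colSums(cc, na.rm = TRUE),
       het = colSums(cc == 1L, na.rm = TRUE))
}

# minor allele frequency over non-missing alleles (NaN when no calls)
variant_maf <- function(G, samples = NULL) {
  sc <- site_counts(G, samples)
  p <- sc$alt / sc$n_called
  pmin(p, 1 - p)
}
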