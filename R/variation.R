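#' Per-variant alternative-allele frequency
#'
#' The default `"fraction"` convention is alt / (alt + ref) over non-missing
#' alleles, which lives in \[0, 1\]. The literal `"odds"` convention
#' (alt / ref) is kept for fidelity with how some reports phrase the ratio;
#' it is infinite when no reference allele is observed (flagged via attribute
#' `flag_infinite`). Sites with no calls return `NA`.
#'
#' @param G a [genotype_matrix].
#' @param samples sample ids/indices.
#' @param convention `"fraction"` (default) or `"odds"`.
#' @return numeric vector, one value per variant.
#' @export
alt_allele_frequency <- function(G, samples, convention = c("fraction", "odds")) {
  convention <- match.arg(convention)
  sc <- site_counts(G, samples)
  refc <- sc$n_called - sc$alt
  if (convention == "fraction") {
    out <- ifelse(sc$n_called > 0, sc$alt / sc$n_called, NA_real_)
  } else {
    out <- ifelse(sc$n_called > 0, sc$alt / refc, NA_real_)   # Inf when ref = 0
    attr(out, "flag_infinite") <- which(is.infinite(out))
  }
  out
}

#' Classify SNPs as standing / new / lost between an ecotype and its progenitor
#'
#' A variant is "present" in a population when its alternative-allele count
#' over non-missing calls reaches `min_carrier_count`. Present in both:
#' standing variation; ecotype only: new mutation; progenitor only: lost
#' variation; neither: absent (excluded from summaries). Variants with no
#' calls at all in one population cannot be scored for presence there; they
#' are classified from the other population alone and flagged.
#'
#' @param G a [genotype_matrix].
#' @param eco_samples,prog_samples disjoint sample sets, each >= 2 samples.
#' @param min_carrier_count minimum alt-allele count that counts as presence
#'   (default 1; raise it to damp sequencing-error-driven "new" calls).
#' @return data.frame (`chrom`, `pos`, `label`, `p_eco`, `p_prog`, `afd`,
#'   `flag`), one row per variant.
#' @export
classify_variants <- function(G, eco_samples, prog_samples,
                              min_carrier_count = 1L) {
  if (length(intersect(eco_samples, prog_samples)) > 0)
    stop("ecotype and progenitor sample sets must be disjoint")
  if (length(eco_samples) < 2 || length(prog_samples) < 2)
    stop("each population needs >= 2 samples")
  se <- site_counts(G, eco_samples)
  sp <- site_counts(G, prog_samples)
  p_eco <- ifelse(se$n_called > 0, se$alt / se$n_called, NA_real_)
  p_prog <- ifelse(sp$n_called > 0, sp$alt / sp$n_called, NA_real_)
  pres_e <- se$alt >= min_carrier_count & se$n_called > 0
  pres_p <- sp$alt >= min_carrier_count & sp$n_called > 0
  no_e <- se$n_called == 0
  no_p <- sp$n_called == 0
  label <- ifelse(pres_e & pres_p, "standing",
                  ifelse(pres_e, "new", ifelse(pres_p, "lost", "absent")))
  afd <- abs(ifelse(is.na(p_eco), 0, p_eco) - ifelse(is.na(p_prog), 0, p_prog))
  afd[no_e & no_p] <- NA_real_
  data.frame(chrom = G$variants$chrom, pos = G$variants$pos,
             label = label, p_eco = p_eco, p_prog = p_prog, afd = afd,
             flag = ifelse(no_e | no_p, "one_pop_uncalled", ""),
             stringsAsFactors = FALSE)
}

#' Summarize allele-frequency differentiation by variant class
#'
#' Per label (standing / new / lost): SNP count, fraction of classified SNPs,
#' mean AFD and mean ecotype alt frequency. Both means are reported because
#' per-class headline numbers in the literature are ambiguous between the
#' two; `absent` variants are excluded.
#'
#' @param classes output of [classify_variants].
#' @return data.frame with one row per label.
#' @export
afd_summary <- function(classes) {
  if (nrow(classes) == 0) stop("empty classification")
  keep <- classes$label %in% c("standing", "new", "lost")
  cl <- classes[keep, , drop = FALSE]
  tot <- nrow(cl)
  out <- do.call(rbind, lapply(c("standing", "new", "lost"), function(lb) {
    x <- cl[cl$label == lb, , drop = FALSE]
    data.frame(label = lb, n_snps = nrow(x),
               fraction = if (tot > 0) nrow(x) / tot else NA_real_,
               mean_afd = if (nrow(x)) mean(x$afd, na.rm = TRUE) else NA_real_,
               mean_p_eco = if (nrow(x)) mean(x$p_eco, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare windowed diversity between two populations
#'
#' Two-sided Mann-Whitney U test on per-window pi values (the published
#' comparisons report only a p-value; a rank test makes no normality
#' assumption about window diversity). Exact p for small window counts,
#' normal approximation with tie correction otherwise.
#'
#' @param pi_windows_A,pi_windows_B `window_stat` tables on the same grid.
#' @return `list(statistic =, p_value =)`.
#' @export
diversity_test <- function(pi_windows_A, pi_windows_B) {
  if (!same_grid(pi_windows_A, pi_windows_B)) stop("window grids differ")
  a <- pi_windows_A$value; b <- pi_windows_B$value
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  force_exact <- min(length(a), length(b)) < 5
  if (force_exact) warning("fewer than 5 windows per group; exact test forced")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = if (force_exact) TRUE else NULL))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
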