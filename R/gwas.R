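#' Encode the binary ecotype phenotype
#'
#' Case/control coding of ecotype membership: samples in `target_group` get 1,
#' all others 0 (the deepwater-versus-rest design). Order follows the sample
#' table.
#'
#' @param tab sample table (`sample_id`, `group`).
#' @param target_group ecotype label coded as 1.
#' @return named 0/1 numeric vector.
#' @export
encode_phenotype <- function(tab, target_group) {
  if (!target_group %in% tab$group)
    stop("target group not present: ", target_group)
  y <- as.numeric(tab$group == target_group)
  if (sum(y) < 5) warning("fewer than 5 case samples; association power is low")
  names(y) <- tab$sample_id
  y
}

#' LD pruning with PLINK --indep-pairwise semantics
#'
#' Slides a `window_snps`-SNP window along each chromosome in steps of
#' `step_snps` SNPs. Within a window, while any kept pair has genotype-code
#' r-squared above `r2_max`, one SNP of the worst pair is removed -- the one
#' with lower MAF, ties broken by removing the later position. r-squared is
#' the squared Pearson correlation of dosages over samples called at both
#' SNPs. The number of survivors is the "effective number of independent
#' SNPs" used for the suggestive threshold.
#'
#' @param G a [genotype_matrix].
#' @param window_snps,step_snps,r2_max the PLINK triple (defaults 50, 5, 0.3).
#' @return integer vector of kept variant indices (attribute `n_independent`).
#' @export
ld_prune <- function(G, window_snps = 50, step_snps = 5, r2_max = 0.3) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  m <- n_variants(G)
  keep <- rep(TRUE, m)
  maf <- variant_maf(G)
  cc <- G$calls
  prune_window <- function(win) {
    repeat {
      r2 <- suppressWarnings(cor(cc[, win, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      worst <- max(r2)
      if (worst <= r2_max) break
      hit <- which(r2 == worst, arr.ind = TRUE)[1, ]  # first = smallest indices
      i <- win[min(hit)]; j <- win[max(hit)]
      drop <- if (isTRUE(maf[i] < maf[j])) i
              else if (isTRUE(maf[j] < maf[i])) j
              else max(i, j)                           # tie: later position
      keep[drop] <<- FALSE
      win <- win[win != drop]
      if (length(win) < 2) break
    }
  }
  for (cn in unique(G$variants$chrom)) {
    cidx <- which(G$variants$chrom == cn)
    # windows slide over the surviving SNP list; removals shorten it, so
    # iterate to a fixed point (guarantees no surviving within-window pair
    # above r2_max under a post-hoc scan)
    repeat {
      before <- sum(keep[cidx])
      alive <- cidx[keep[cidx]]
      if (length(alive) < 2) break
      for (st in seq(1L, length(alive), by = step_snps)) {
        win <- alive[st:min(st + window_snps - 1L, length(alive))]
        win <- win[keep[win]]
        if (length(win) >= 2) prune_window(win)
      }
      if (sum(keep[cidx]) == before) break
    }
  }
  out <- which(keep)
  attr(out, "n_independent") <- length(out)
  out
}

# mean-imputed, optionally standardized dosage matrix (samples x variants);
# zero-variance columns are dropped
standardized_dosage <- function(G, scale = TRUE) {
  X <- G$calls
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  ok <- p > 0 & p < 1 & apply(X, 2, sd) > 0
  X <- X[, ok, drop = FALSE]
  p <- p[ok]
  Z <- sweep(X, 2, 2 * p, "-")
  if (scale) Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  attr(Z, "kept") <- which(ok)
  Z
}

#' Genomic relationship matrix
#'
#' Columns centred by twice the allele frequency and scaled to unit variance
#' (missing dosages mean-imputed first); `K = Z Z' / m`. A VanRaden-style
#' unscaled variant is available via `scale = FALSE`.
#'
#' @param G a [genotype_matrix].
#' @param scale per-variant unit-variance scaling (default) or VanRaden
#'   denominator `2 * sum(p(1-p))`.
#' @return symmetric sample x sample matrix.
#' @export
grm <- function(G, scale = TRUE) {
  if (n_samples(G) < 2 || n_variants(G) < 10)
    stop("need >= 2 samples and >= 10 variants")
  Z <- standardized_dosage(G, scale = scale)
  if (ncol(Z) == 0) stop("no polymorphic variants")
  K <- if (scale) tcrossprod(Z) / ncol(Z)
  else {
    p <- colMeans(G$calls, na.rm = TRUE)[attr(Z, "kept")] / 2
    tcrossprod(Z) / (2 * sum(p * (1 - p)))
  }
  dimnames(K) <- list(G$samples, G$samples)
  (K + t(K)) / 2
}

#' Principal-component covariates
#'
#' Top-k left singular vectors of the standardized dosage matrix, scaled by
#' their singular values. Deterministic sign convention: the
#' largest-magnitude variant loading of each component is made positive.
#'
#' @param G a [genotype_matrix].
#' @param k number of components (default 3).
#' @return sample x k score matrix.
#' @export
pca_covariates <- function(G, k = 3) {
  if (k == 0) {
    out <- matrix(0, n_samples(G), 0)
    rownames(out) <- G$samples
    return(out)
  }
  if (k >= min(n_samples(G), n_variants(G)))
    stop("k must be < min(n_samples, n_variants)")
  Z <- standardized_dosage(G)
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)] * flip, k)
  rownames(scores) <- G$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# negative REML log-likelihood of the rotated null model at a given delta
neg_reml <- function(log10_delta, lambda, ystar, Wstar) {
  delta <- 10^log10_delta
  w <- 1 / (lambda + delta)
  sw <- sqrt(w)
  A <- Wstar * sw
  yv <- ystar * sw
  fit <- qr(A)
  r <- yv - A %*% qr.coef(fit, yv)
  n <- length(ystar); q <- ncol(Wstar)
  sg2 <- sum(r^2) / (n - q)
  ldet_xwx <- sum(log(abs(diag(qr.R(fit))^2)))
  0.5 * ((n - q) * log(sg2) + sum(log(lambda + delta)) + ldet_xwx)
}

#' Mixed-model association scan (EMMAX-style)
#'
#' Fits `y = W a + g b + u + e`, `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)`: the
#' kinship is eigendecomposed once, the variance ratio
#' `delta = se2 / sg2` is estimated by REML on the covariate-only null (grid
#' over log10(delta) in \[-5, 5\] then Brent refinement to 1e-6), and each SNP
#' is tested by generalized least squares in the rotated coordinates with that
#' single delta -- the standard approximation to per-SNP REML. The binary
#' ecotype phenotype is treated as quantitative. Wald p-values use a t
#' distribution with `n - rank(W) - 1` df. Monomorphic SNPs are skipped
#' (`NA` rows).
#'
#' @param G a [genotype_matrix].
#' @param y numeric phenotype, aligned with `G$samples`.
#' @param covariates optional sample x q matrix (PCs etc.); an intercept is
#'   always added.
#' @param K kinship from [grm]; `NULL` fits plain OLS.
#' @return data.frame (`chrom`, `pos`, `beta`, `se`, `p_value`, `neglog10p`)
#'   with attribute `delta`.
#' @export
lmm_scan <- function(G, y, covariates = NULL, K = NULL) {
  n <- n_samples(G)
  stopifnot(length(y) == n)
  W <- cbind(intercept = rep(1, n), covariates)
  qw <- qr(W)
  if (qw$rank < ncol(W)) {
    bad <- colnames(W)[qw$pivot[(qw$rank + 1):ncol(W)]]
    stop("singular covariate block (collinear columns: ",
         paste(bad, collapse = ", "), ")")
  }
  if (is.null(K)) {
    U <- diag(n); lambda <- rep(0, n); delta <- 1
    w <- rep(1, n)
  } else {
    eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    U <- eig$vectors
    ystar <- drop(crossprod(U, y))
    Wstar <- crossprod(U, W)
    gridv <- seq(-5, 5, by = 0.25)
    nll <- vapply(gridv, neg_reml, numeric(1),
                  lambda = lambda, ystar = ystar, Wstar = Wstar)
    i0 <- which.min(nll)
    lo <- gridv[max(1, i0 - 1)]; hi <- gridv[min(length(gridv), i0 + 1)]
    opt <- optimize(neg_reml, c(lo, hi), lambda = lambda, ystar = ystar,
                    Wstar = Wstar, tol = 1e-6)
    delta <- 10^opt$minimum
    w <- 1 / (lambda + delta)
  }
  ystar <- drop(crossprod(U, y))
  Wstar <- crossprod(U, W)
  X <- G$calls
  storage.mode(X) <- "double"
  mono <- apply(X, 2, function(col) {
    v <- col[!is.na(col)]
    length(v) < 3 || length(unique(v)) < 2
  })
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  Xstar <- crossprod(U, X)
  sw <- sqrt(w)
  A <- Wstar * sw
  yv <- ystar * sw
  Xv <- Xstar * sw
  Q <- qr.Q(qr(A))
  Py <- yv - Q %*% crossprod(Q, yv)
  PX <- Xv - Q %*% crossprod(Q, Xv)
  xx <- colSums(PX^2)
  xy <- drop(crossprod(PX, Py))
  q <- ncol(W)
  df <- n - q - 1
  beta <- xy / xx
  rss <- drop(sum(Py^2)) - beta * xy
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / xx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  bad <- mono | xx < 1e-10
  beta[bad] <- NA; se[bad] <- NA; p[bad] <- NA
  out <- data.frame(chrom = G$variants$chrom, pos = G$variants$pos,
                    beta = beta, se = se, p_value = p,
                    neglog10p = -log10(p), stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  rownames(out) <- NULL
  out
}

#' Suggestive GWAS significance threshold
#'
#' `-log10(alpha / n_independent)`, the Bonferroni-style threshold over the
#' effective number of independent SNPs from LD pruning. `mode = "floor"`
#' truncates to an integer, reproducing the common practice of quoting a
#' round -log10(p) cutoff.
#'
#' @param n_independent effective number of independent SNPs (>= 1).
#' @param alpha genome-wide significance level (default 0.01).
#' @param mode `"exact"` or `"floor"`.
#' @return the threshold on the -log10(p) scale.
#' @export
suggestive_threshold <- function(n_independent, alpha = 0.01,
                                 mode = c("exact", "floor")) {
  mode <- match.arg(mode)
  stopifnot(n_independent >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  x <- -log10(alpha / n_independent)
  if (mode == "floor") floor(x) else x
}

#' Group significant SNPs into QTL regions
#'
#' Significant SNPs (`neglog10p >= threshold`) on the same chromosome within
#' `merge_distance_bp` of each other form one QTL (single-linkage clustering).
#' The lead variant has the smallest p (ties: smaller position); genes
#' overlapping the QTL span extended by `merge_distance_bp` on both sides are
#' reported.
#'
#' @param assoc output of [lmm_scan].
#' @param threshold -log10(p) cutoff, e.g. from [suggestive_threshold].
#' @param merge_distance_bp clumping distance (default 200 kb).
#' @param genes optional gene table for annotation.
#' @return data.frame of QTLs (`chrom`, `start`, `end`, `lead_chrom` omitted,
#'   `lead_pos`, `min_p`, `n_significant`, `genes`).
#' @export
call_qtls <- function(assoc, threshold, merge_distance_bp = 200000,
                      genes = NULL) {
  sig <- assoc[!is.na(assoc$neglog10p) & assoc$neglog10p >= threshold, ,
               drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      lead_pos = integer(), min_p = numeric(),
                      n_significant = integer(), genes = character()))
  out <- do.call(rbind, lapply(split(sig, sig$chrom), function(ss) {
    ss <- ss[order(ss$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(ss$pos) > merge_distance_bp))
    do.call(rbind, lapply(split(ss, grp), function(g) {
      lead <- g[order(g$p_value, g$pos), ][1, ]
      data.frame(chrom = g$chrom[1], start = min(g$pos) - 1, end = max(g$pos),
                 lead_pos = lead$pos, min_p = lead$p_value,
                 n_significant = nrow(g), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (!is.null(genes) && nrow(genes) > 0) {
    ext <- out
    ext$start <- pmax(0, ext$start - merge_distance_bp)
    ext$end <- ext$end + merge_distance_bp
    out$genes <- annotate_regions(ext, genes)$genes
  } else out$genes <- ""
  out
}
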