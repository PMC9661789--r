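#' Derive a stage-specific seed from a master seed
#'
#' One master seed drives every stochastic stage; each stage draws from its
#' own stream so that adding a stage never perturbs the randomness of the
#' others. The derived seed is a deterministic 31-bit hash of the master seed
#' and the stage name.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stable md5 of an R object via its deparsed, serialized form
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

# rank-based normal score (van der Waerden style), NA-preserving
rank_z <- function(x) {
  z <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0) z[ok] <- qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
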