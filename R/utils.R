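# Internal helpers shared across modules.

# Derive a stream-specific seed from a base seed. Keeps results reproducible
# while letting independent stages (landscape, pool, communities, bootstrap
# draws) consume independent streams. Result stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ch <- utf8ToInt(as.character(stream))
  offs <- sum(ch * seq_along(ch))
  as.integer((abs(seed) * 48271 + offs) %% 2147483647)
}

weighted_mean2 <- function(x, w) sum(w * x) / sum(w)

# Weighted sd with weights treated as relative frequencies (divisor sum(w)).
weighted_sd <- function(x, w) {
  m <- weighted_mean2(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# Centre and reduce columns of a matrix under observation weights w so each
# column has weighted mean 0 and weighted sd 1.
weighted_standardize <- function(X, w) {
  X <- as.matrix(X)
  wn <- w / sum(w)
  ctr <- colSums(wn * X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colSums(wn * Xc^2))
  if (any(scl <= .Machine$double.eps * 100)) {
    bad <- colnames(X)[scl <= .Machine$double.eps * 100]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  Xs <- sweep(Xc, 2L, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
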