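#' Moran's I within a distance class
#'
#' Spatial autocorrelation of `values` under binary neighbour weights:
#' `w_ij = 1` iff the pair's distance lies in `[class[1], class[2])`.
#' `I = (n / sum W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`;
#' its expectation under spatial independence is `-1/(n-1)`.
#'
#' @param values numeric vector (>= 8, non-constant).
#' @param x,y projected coordinates.
#' @param class length-2 numeric, distance-class bounds in metres.
#' @return Moran's I, with attribute `n_pairs` (ordered pairs in the class).
#'   `NA` (with `n_pairs = 0`) when the class holds no pair.
#' @export
morans_i <- function(values, x, y, class) {
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n, length(class) == 2L)
  if (n < 8) stop("need at least 8 values")
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("zero variance")
  dmat <- as.matrix(stats::dist(cbind(x, y)))
  w <- dmat >= class[1] & dmat < class[2]
  diag(w) <- FALSE
  sw <- sum(w)
  if (sw == 0) return(structure(NA_real_, n_pairs = 0L))
  i_val <- (n / sw) * sum(w * outer(z, z)) / s2
  structure(i_val, n_pairs = sum(w))
}

#' Spatial correlogram with bootstrap CIs and permutation tests
#'
#' Moran's I per distance class, computed over `n_draws` random subsamples of
#' the data (mean and percentile CI per class), with the conventional fixed
#' I = 0.05 flag and a permutation p-value per class computed on one
#' full-sample pass (values permuted over locations).
#'
#' @param values numeric vector (e.g. climatic debt, or model residuals).
#' @param x,y projected coordinates.
#' @param edges distance-class edges in metres (default 10-km steps to
#'   150 km).
#' @param n_draws subsample draws (default 100).
#' @param subsample size of each draw (default `min(n, 300)`).
#' @param n_perm permutations for the per-class test (default 199).
#' @param threshold fixed autocorrelation flag level (default 0.05).
#' @param seed integer seed.
#' @return A data.frame of class `debt_correlogram`: per class `lo`, `hi`,
#'   `mid`, `i_mean`, `ci_lo`, `ci_hi`, `n_pairs`, `exceeds` (fixed
#'   threshold), `p_perm`.
#' @export
correlogram <- function(values, x, y, edges = seq(0, 150000, by = 10000),
                        n_draws = 100, subsample = NULL, n_perm = 199,
                        threshold = 0.05, seed = 1L) {
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n, length(edges) >= 2)
  if (is.unsorted(edges, strictly = TRUE)) stop("class edges must increase")
  set.seed(derive_seed(seed, "correlogram"))
  subsample <- min(n, subsample %||% 300L)
  k <- length(edges) - 1L

  imat <- matrix(NA_real_, n_draws, k)
  for (d in seq_len(n_draws)) {
    idx <- sample.int(n, subsample)
    zs <- values[idx] - mean(values[idx])
    s2 <- sum(zs^2)
    dmat <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
    zz <- outer(zs, zs)
    for (c in seq_len(k)) {
      w <- dmat >= edges[c] & dmat < edges[c + 1]
      diag(w) <- FALSE
      sw <- sum(w)
      if (sw > 0 && s2 > 0)
        imat[d, c] <- (subsample / sw) * sum(w * zz) / s2
    }
  }

  # one full-sample pass for the permutation test (subsampled for big n)
  idx <- if (n > 1000) sample.int(n, 1000) else seq_len(n)
  m <- length(idx)
  dmat <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
  v0 <- values[idx]
  p_perm <- n_pairs <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    w <- dmat >= edges[c] & dmat < edges[c + 1]
    diag(w) <- FALSE
    sw <- sum(w)
    n_pairs[c] <- sw
    if (sw == 0) next
    obs_and_perm <- vapply(0:n_perm, function(r) {
      v <- if (r == 0) v0 else sample(v0)
      z <- v - mean(v)
      (m / sw) * sum(w * outer(z, z)) / sum(z^2)
    }, 0)
    p_perm[c] <- (1 + sum(abs(obs_and_perm[-1]) >= abs(obs_and_perm[1]))) /
      (n_perm + 1)
  }

  out <- data.frame(
    lo = edges[-length(edges)], hi = edges[-1],
    mid = (edges[-1] + edges[-length(edges)]) / 2,
    i_mean = colMeans(imat, na.rm = TRUE),
    ci_lo = apply(imat, 2, stats::quantile, 0.025, na.rm = TRUE),
    ci_hi = apply(imat, 2, stats::quantile, 0.975, na.rm = TRUE),
    n_pairs = n_pairs, p_perm = p_perm
  )
  out$exceeds <- !is.na(out$i_mean) & out$i_mean > threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("debt_correlogram", "data.frame")
  out
}

#' Plot a spatial correlogram
#'
#' Class-midpoint Moran's I with CI whiskers, the expectation under
#' independence, and the fixed autocorrelation threshold line.
#'
#' @param x a [correlogram()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.debt_correlogram <- function(x, ...) {
  graphics::plot(x$mid / 1000, x$i_mean, type = "b", pch = 19,
                 ylim = range(c(x$ci_lo, x$ci_hi, 0.06), na.rm = TRUE),
                 xlab = "distance class midpoint (km)", ylab = "Moran's I",
                 ...)
  graphics::segments(x$mid / 1000, x$ci_lo, x$mid / 1000, x$ci_hi)
  graphics::abline(h = attr(x, "threshold"), col = "red", lty = 3)
  graphics::abline(h = 0, lty = 1, col = "grey")
  invisible(x)
}
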