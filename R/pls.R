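#' Spatial thinning of survey locations
#'
#' Random-order greedy subsampling: surveys are visited in random order and
#' accepted iff they lie at least `min_dist` from every previously accepted
#' survey. The retained set therefore has all pairwise distances
#' `>= min_dist`, which suppresses spatial autocorrelation in downstream
#' regressions.
#'
#' @param x,y projected coordinates (metres).
#' @param min_dist minimum pairwise distance (default 10 km).
#' @param seed optional integer seed for the visiting order (`NULL` uses the
#'   current RNG state).
#' @return Integer indices of the retained surveys.
#' @export
spatial_thinning <- function(x, y, min_dist = 10000, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  acc <- integer(n); ax <- numeric(n); ay <- numeric(n)
  k <- 0L
  min2 <- min_dist^2
  for (i in ord) {
    if (k == 0L ||
        all((ax[seq_len(k)] - x[i])^2 + (ay[seq_len(k)] - y[i])^2 >= min2)) {
      k <- k + 1L
      acc[k] <- i; ax[k] <- x[i]; ay[k] <- y[i]
    }
  }
  acc[seq_len(k)]
}

#' Per-year observation weights
#'
#' `w_i = 1 / (number of surveys sharing survey i's year)`, so every year
#' contributes equal total weight and an unbalanced temporal distribution of
#' samples does not dominate the regression. Weights within each year sum
#' to 1.
#'
#' @param years integer vector of survey years.
#' @return Numeric weights.
#' @export
observation_weights <- function(years) {
  if (!length(years)) stop("no years supplied")
  cnt <- table(years)
  as.numeric(1 / cnt[as.character(years)])
}

#' Weighted partial least squares regression
#'
#' Observation-weighted NIPALS extraction for a single response: each
#' component's weight vector maximises the weighted covariance of the score
#' with the response; scores are mutually orthogonal under the weighted inner
#' product; the predictor matrix is deflated after each component. Inputs are
#' expected centred and reduced under the same weights ([debt_pls()] does
#' this per draw).
#'
#' @param X numeric matrix (n x p), weighted mean 0 / sd 1 per column.
#' @param y numeric response, weighted mean 0 / sd 1.
#' @param w observation weights.
#' @param max_components number of components to extract (<= p).
#' @return An object of class `wpls`: `weights` (p x H, unit-norm columns),
#'   `scores` (n x H), `loadings`, `q` (per-component response slopes),
#'   `rot` (rotation such that `scores = X %*% rot`), `rd` (per-component
#'   weighted squared correlation with y), plus the inputs' metadata.
#' @export
fit_weighted_pls <- function(X, y, w, max_components = ncol(X)) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(w) == n, max_components >= 1,
            max_components <= p)
  if (any(apply(X, 2, stats::sd) == 0)) stop("zero-variance predictor column")
  wn <- w / sum(w)
  H <- max_components
  W <- matrix(0, p, H); P <- matrix(0, p, H)
  Tm <- matrix(0, n, H); q <- numeric(H); tt <- numeric(H)
  Xh <- X; yh <- y
  sy2 <- sum(wn * y^2)
  for (h in seq_len(H)) {
    wh <- drop(crossprod(Xh, wn * yh))
    nw <- sqrt(sum(wh^2))
    if (nw < 1e-12) { H <- h - 1L; break }  # nothing left to extract
    wh <- wh / nw
    th <- drop(Xh %*% wh)
    tth <- sum(wn * th^2)
    if (tth < 1e-14) { H <- h - 1L; break }
    ph <- drop(crossprod(Xh, wn * th)) / tth
    qh <- sum(wn * y * th) / tth
    W[, h] <- wh; P[, h] <- ph; Tm[, h] <- th; q[h] <- qh; tt[h] <- tth
    Xh <- Xh - tcrossprod(th, ph)
    yh <- yh - qh * th
  }
  if (H == 0L) stop("response orthogonal to predictors: no component extracted")
  W <- W[, seq_len(H), drop = FALSE]; P <- P[, seq_len(H), drop = FALSE]
  Tm <- Tm[, seq_len(H), drop = FALSE]; q <- q[seq_len(H)]; tt <- tt[seq_len(H)]
  rot <- W %*% solve(crossprod(P, W))
  rd <- q^2 * tt / sy2
  structure(
    list(weights = W, scores = Tm, loadings = P, q = q, tt = tt, rot = rot,
         rd = rd, n_components = H, wn = wn, y = y,
         varnames = colnames(X) %||% paste0("x", seq_len(p))),
    class = "wpls")
}

#' @export
print.wpls <- function(x, ...) {
  cat(sprintf("weighted PLS: %d predictors, %d component(s), cumulative Rd = %.3f\n",
              nrow(x$weights), x$n_components, sum(x$rd)))
  invisible(x)
}

#' Bonferroni component selection
#'
#' Regresses the response on all extracted component scores (weighted linear
#' model) and retains the components whose slope passes a Student t-test at
#' `alpha` divided by the number of components tested. The retained set may
#' be non-contiguous.
#'
#' @param fit a [fit_weighted_pls()] object.
#' @param alpha familywise level before the Bonferroni division
#'   (default 0.05).
#' @return A list: `retained` (integer indices), `p_values`, `threshold`.
#' @export
select_components <- function(fit, alpha = 0.05) {
  H <- fit$n_components
  df <- as.data.frame(fit$scores)
  names(df) <- paste0("comp", seq_len(H))
  df$y <- fit$y
  lmfit <- stats::lm(y ~ ., data = df, weights = fit$wn)
  pv <- summary(lmfit)$coefficients[-1, 4]
  thr <- alpha / H
  list(retained = which(pv < thr), p_values = unname(pv), threshold = thr)
}

#' Coefficients and R-squared from retained components
#'
#' Back-transforms the retained-component regression into per-variable
#' standardized slopes (`beta = rot[, retained] %*% q[retained]`; exact for
#' any retained subset) and reports the weighted squared correlation of the
#' fitted values with the response.
#'
#' @param fit a [fit_weighted_pls()] object.
#' @param retained integer component indices (non-empty).
#' @return A list: `coefficients` (named), `r2`, `fitted`.
#' @export
pls_coefficients <- function(fit, retained) {
  if (!length(retained)) stop("empty retained set")
  beta <- drop(fit$rot[, retained, drop = FALSE] %*% fit$q[retained])
  names(beta) <- fit$varnames
  fitted <- drop(fit$scores[, retained, drop = FALSE] %*% fit$q[retained])
  wn <- fit$wn
  r2 <- sum(wn * fitted * fit$y)^2 /
    (sum(wn * fitted^2) * sum(wn * fit$y^2))
  list(coefficients = beta, r2 = r2, fitted = fitted)
}

#' Variance partitioning over predictors
#'
#' Attributes the explained variance to individual predictors:
#' `share_j = sum_h Rd(y, t_h) * w_jh^2` over the retained components, with
#' `w_h` the unit-norm component weight vectors. Because
#' `sum_j w_jh^2 = 1`, the shares sum exactly to the model's R-squared.
#'
#' @param fit a [fit_weighted_pls()] object.
#' @param retained integer component indices.
#' @return Named numeric vector of per-variable shares.
#' @export
variance_partition <- function(fit, retained) {
  if (!length(retained)) stop("empty retained set")
  sh <- drop(fit$weights[, retained, drop = FALSE]^2 %*% fit$rd[retained])
  stats::setNames(sh, fit$varnames)
}

#' Bootstrap sign test for coefficient significance
#'
#' A coefficient is significantly positive (negative) when at least
#' `1 - alpha` of its subsample draws lie above (below) zero.
#'
#' @param draws numeric vector or matrix (draws x variables) of coefficient
#'   values; at least 100 draws.
#' @param alpha level (default 0.01, i.e. the 99 percent rule).
#' @return Character vector `"positive"`/`"negative"`/`"ns"` per variable,
#'   with attribute `frac_positive`.
#' @export
coefficient_significance <- function(draws, alpha = 0.01) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 100) stop("need at least 100 draws for the sign test")
  fp <- colMeans(draws > 0, na.rm = TRUE)
  fn <- colMeans(draws < 0, na.rm = TRUE)
  out <- ifelse(fp >= 1 - alpha, "positive",
                ifelse(fn >= 1 - alpha, "negative", "ns"))
  attr(out, "frac_positive") <- fp
  out
}
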