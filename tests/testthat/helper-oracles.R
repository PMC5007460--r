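# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Classical weighted averaging with linear deshrinking: species optima as
# occurrence-weighted means, site scores as presence-weighted optimum means,
# then regress observed on inferred.
wa_oracle <- function(comm, x) {
  comm <- as.matrix(comm)
  opt <- colSums(comm * x) / colSums(comm)
  raw <- as.vector(comm %*% opt) / rowSums(comm)
  unname(fitted(lm(x ~ raw)))
}

# Weighted least squares through the normal equations.
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  drop(solve(t(X) %*% (w * X), t(X) %*% (w * y)))
}

# Textbook unweighted univariate NIPALS PLS, full algorithm rewritten from
# scratch; returns coefficients for centred/scaled inputs using all
# components.
nipals_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X)
  E <- X; f <- y
  W <- NULL; P <- NULL; q <- c()
  for (h in seq_len(ncomp)) {
    wv <- drop(t(E) %*% f); wv <- wv / sqrt(sum(wv^2))
    t_ <- drop(E %*% wv)
    p_ <- drop(t(E) %*% t_) / sum(t_^2)
    q_ <- sum(f * t_) / sum(t_^2)
    W <- cbind(W, wv); P <- cbind(P, p_); q <- c(q, q_)
    E <- E - outer(t_, p_)
    f <- f - q_ * t_
  }
  drop(W %*% solve(t(P) %*% W) %*% q)
}

# A small gradient calibration set: n surveys along a temperature gradient,
# m species with Gaussian responses. Returns the community matrix (filtered
# so no empty rows/columns) and the gradient values.
gradient_fixture <- function(n = 200, m = 40, seed = 42, t_range = c(5, 15)) {
  set.seed(seed)
  x <- sort(runif(n, t_range[1], t_range[2]))
  opt <- runif(m, t_range[1], t_range[2])
  br <- pmax(0.8, rnorm(m, 2, 0.5))
  comm <- matrix(0L, n, m,
                 dimnames = list(sprintf("s%03d", 1:n), sprintf("sp%02d", 1:m)))
  for (k in seq_len(m))
    comm[, k] <- as.integer(runif(n) < 0.85 * exp(-0.5 * ((x - opt[k]) / br[k])^2))
  keep_r <- rowSums(comm) >= 3
  comm <- comm[keep_r, colSums(comm[keep_r, ]) >= 3]
  list(comm = comm, x = x[keep_r])
}

# Random standardized design + response for PLS unit tests.
pls_fixture <- function(n = 120, p = 8, seed = 1, beta = NULL, noise = 0.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", seq_len(p)))))
  if (is.null(beta)) beta <- rnorm(p, 0, 0.3)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = as.numeric(scale(y)), beta = beta)
}
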