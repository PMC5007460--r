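test_that("spatial thinning enforces the minimum pairwise distance", {
  set.seed(8)
  # all surveys within 5 km of one point: only one survives a 10-km rule
  x <- rnorm(50, 0, 1500); y <- rnorm(50, 0, 1500)
  expect_length(spatial_thinning(x, y, 10000, seed = 1), 1)

  # 20-km lattice: everything survives
  g <- expand.grid(x = seq(0, 8e4, 2e4), y = seq(0, 8e4, 2e4))
  expect_length(spatial_thinning(g$x, g$y, 10000, seed = 1), nrow(g))

  # property: minimum pairwise distance >= 10 km for any seed
  xs <- runif(300, 0, 1e5); ys <- runif(300, 0, 1e5)
  for (s in 1:20) {
    idx <- spatial_thinning(xs, ys, 10000, seed = s)
    expect_gte(min(dist(cbind(xs[idx], ys[idx]))), 10000)
  }
})

test_that("observation weights invert the yearly counts", {
  expect_equal(observation_weights(c(1987, 1987, 1988)), c(0.5, 0.5, 1))
  expect_equal(observation_weights(1991:1995), rep(1, 5))
  yrs <- rep(2000:2003, c(7, 1, 4, 2))
  w <- observation_weights(yrs)
  expect_equal(as.numeric(tapply(w, yrs, sum)), rep(1, 4))
})

test_that("equal-weight weighted PLS reproduces an independent NIPALS", {
  fx <- pls_fixture(100, 6, seed = 2)
  w <- rep(1, 100)
  for (h in c(1, 3, 6)) {
    fit <- fit_weighted_pls(fx$X, fx$y, w, h)
    beta <- pls_coefficients(fit, seq_len(h))$coefficients
    expect_equal(unname(beta), unname(nipals_oracle(fx$X, fx$y, h)),
                 tolerance = 1e-8)
  }
})

test_that("full-component full-rank fits equal weighted least squares", {
  fx <- pls_fixture(150, 7, seed = 3)
  set.seed(3)
  w <- runif(150, 0.2, 2)
  fit <- fit_weighted_pls(fx$X, fx$y, w, 7)
  beta <- pls_coefficients(fit, 1:7)$coefficients
  expect_lt(max(abs(beta - wls_oracle(fx$X, fx$y, w))), 1e-8)
})

test_that("scores are pairwise orthogonal under the weighted inner product", {
  fx <- pls_fixture(120, 8, seed = 4)
  set.seed(4)
  w <- runif(120, 0.5, 1.5)
  fit <- fit_weighted_pls(fx$X, fx$y, w, 8)
  wn <- w / sum(w)
  G <- t(fit$scores) %*% (wn * fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("a response orthogonal to the predictors yields no signal", {
  set.seed(5)
  X <- scale(matrix(rnorm(200 * 4), 200, 4))
  y0 <- rnorm(200)
  y_exact <- as.numeric(scale(residuals(lm(y0 ~ X))))
  # exactly orthogonal: nothing extractable, reported as an error
  expect_error(fit_weighted_pls(X, y_exact, rep(1, 200), 4), "orthogonal")
  # nearly orthogonal: all component response correlations stay tiny
  y_near <- as.numeric(scale(y_exact + rnorm(200, 0, 1e-3)))
  fit <- fit_weighted_pls(X, y_near, rep(1, 200), 4)
  expect_lt(max(fit$rd), 0.05)
})

# Build a wpls-shaped object with fixed orthonormal scores so the selection
# step can be tested in isolation from the extraction step.
score_fixture <- function(n, h, y, seed = 1) {
  set.seed(seed)
  Tm <- qr.Q(qr(matrix(rnorm(n * h), n, h)))
  structure(list(scores = Tm, y = y, wn = rep(1 / n, n),
                 n_components = h),
            class = "wpls")
}

test_that("component selection retains dominant components under Bonferroni", {
  set.seed(6)
  n <- 300
  # deterministic fixture: only score 1 carries signal
  fx <- score_fixture(n, 20, y = NULL)
  y <- as.numeric(scale(5 * fx$scores[, 1] + rnorm(n, 0, 0.08)))
  fx$y <- y
  sel <- select_components(fx)
  expect_equal(unname(sel$retained), 1L)
  # the Bonferroni divisor is the number of components tested: 20 -> 0.0025
  expect_equal(sel$threshold, 0.0025)

  # organic fit: the component carrying the planted signal is always kept
  X <- scale(matrix(rnorm(400 * 6), 400, 6))
  yv <- as.numeric(scale(drop(X %*% c(1, 1, 0, 0, 0, 0)) + rnorm(400, 0, 0.4)))
  fit <- fit_weighted_pls(X, yv, rep(1, 400), 6)
  expect_true(1L %in% select_components(fit)$retained)
})

test_that("pure-noise responses retain few components", {
  # The first extracted score is chosen to maximise covariance with y, so the
  # score-on-response t-test is optimistic for it; retention of pure noise is
  # limited but not at the nominal alpha (see the methods vignette).
  cnt <- vapply(1:40, function(s) {
    set.seed(100 + s)
    Xn <- scale(matrix(rnorm(150 * 5), 150, 5))
    yn <- as.numeric(scale(rnorm(150)))
    fn <- fit_weighted_pls(Xn, yn, rep(1, 150), 5)
    length(select_components(fn)$retained)
  }, 0L)
  expect_lt(mean(cnt), 1)
  # components beyond the first are almost never retained on noise
  beyond <- vapply(1:40, function(s) {
    set.seed(100 + s)
    Xn <- scale(matrix(rnorm(150 * 5), 150, 5))
    yn <- as.numeric(scale(rnorm(150)))
    sum(select_components(fit_weighted_pls(Xn, yn, rep(1, 150), 5))$retained > 1)
  }, 0L)
  expect_lte(mean(beyond), 0.2)
})

test_that("coefficients back-transform exactly for any retained subset", {
  fx <- pls_fixture(150, 6, seed = 7)
  w <- rep(1, 150)
  fit <- fit_weighted_pls(fx$X, fx$y, w, 6)
  # single retained component: coefficients proportional to its weight vector
  b1 <- pls_coefficients(fit, 1)$coefficients
  expect_equal(unname(b1 / fit$weights[, 1]),
               rep(fit$q[1], 6), tolerance = 1e-10)
  # non-contiguous subsets: fitted values equal the score-space regression
  cr <- pls_coefficients(fit, c(1, 3))
  expect_equal(drop(fx$X %*% cr$coefficients),
               drop(fit$scores[, c(1, 3)] %*% fit$q[c(1, 3)]),
               tolerance = 1e-10)
  # perfect linear response: R2 = 1 with all components
  y_perf <- as.numeric(scale(drop(fx$X %*% fx$beta)))
  fitp <- fit_weighted_pls(fx$X, y_perf, w, 6)
  expect_equal(pls_coefficients(fitp, 1:fitp$n_components)$r2, 1,
               tolerance = 1e-8)
})

test_that("variance shares sum to the fit's R-squared", {
  for (s in 1:100) {
    fx <- pls_fixture(60, 5, seed = 200 + s, noise = runif(1, 0.2, 1.5))
    w <- runif(60, 0.3, 2)
    wn <- w / sum(w)
    ys <- (fx$y - sum(wn * fx$y)) / sqrt(sum(wn * (fx$y - sum(wn * fx$y))^2))
    Xs <- climdebt:::weighted_standardize(fx$X, w)
    fit <- fit_weighted_pls(Xs, ys, w, 5)
    keep <- seq_len(fit$n_components)
    if (s %% 3 == 0 && fit$n_components > 1) keep <- keep[-2]
    cr <- pls_coefficients(fit, keep)
    expect_equal(sum(variance_partition(fit, keep)), cr$r2,
                 tolerance = 1e-8)
  }
})

test_that("a variable with zero weight on retained components gets no share", {
  fit <- structure(list(
    weights = cbind(c(0.8, 0.6, 0), c(0, 0, 1)),
    rd = c(0.5, 0.2), varnames = c("a", "b", "c"), n_components = 2L),
    class = "wpls")
  sh <- variance_partition(fit, 1L)
  expect_equal(unname(sh["c"]), 0)
  expect_equal(sum(sh), 0.5)
})

test_that("the bootstrap sign test applies the 99 percent rule", {
  expect_equal(unname(coefficient_significance(rep(1, 200))[1]), "positive")
  d98 <- c(rep(1, 98), rep(-1, 2))
  expect_equal(unname(coefficient_significance(rep(d98, 2))[1]), "ns")
  d99 <- c(rep(1, 99), -1)
  expect_equal(unname(coefficient_significance(rep(d99, 2))[1]), "positive")
  expect_equal(unname(coefficient_significance(rep(-d99, 2))[1]), "negative")
  expect_error(coefficient_significance(rep(1, 50)), "at least 100")
})

test_that("bootstrap draws are recorded and planted effects recovered", {
  tab <- simulate_predictor_table(n = 1500, extent = 2e5, seed = 9)
  fit <- debt_pls(tab, "PLS0", n_draws = 150, seed = 2)
  expect_equal(fit$n_draws, 150)
  expect_equal(nrow(fit$draws$coefficients), 150)
  expect_equal(length(fit$draws$r2), 150)

  s <- fit$summary
  expect_gt(s$mean[s$variable == "T"], 0.2)
  expect_gt(s$ci_lo[s$variable == "T"], 0)      # CI excludes zero
  expect_lt(s$ci_hi[s$variable == "NC"], 0)
  ci_road <- c(s$ci_lo[s$variable == "road_prox"],
               s$ci_hi[s$variable == "road_prox"])
  expect_true(ci_road[1] < 0 && ci_road[2] > 0) # zero-effect covariate
  expect_equal(s$significance[s$variable == "road_prox"], "ns")

  # year always enters the model
  expect_true("year" %in% s$variable)
  expect_s3_class(fit, "debt_pls")
  expect_silent(coef(fit))
  expect_equal(dim(confint(fit, "T")), c(1, 2))
})

test_that("error propagation reduces to the plain bootstrap at zero noise and attenuates under noise", {
  tab <- simulate_predictor_table(n = 1200, extent = 2e5, seed = 10)
  base <- debt_pls(tab, "PLS0", n_draws = 60, seed = 3)
  zero <- error_propagation(tab, c(T = 0, P = 0), variant = "PLS0",
                            n_draws = 60, seed = 3)
  expect_equal(base$summary$mean, zero$summary$mean, tolerance = 1e-12)

  noisy <- error_propagation(tab, c(T = 3), variant = "PLS0",
                             n_draws = 60, seed = 3)
  t_base <- base$summary$mean[base$summary$variable == "T"]
  t_noisy <- noisy$summary$mean[noisy$summary$variable == "T"]
  expect_lt(abs(t_noisy), abs(t_base))
  expect_error(error_propagation(tab, c(T = -1), n_draws = 60), "negative")
})

test_that("model variants partition the survey sets as documented", {
  tab <- simulate_predictor_table(n = 800, extras = TRUE, seed = 11)
  late <- variant_surveys(tab, "PLS1")
  d3 <- variant_surveys(tab, "PLS3")
  d4 <- variant_surveys(tab, "PLS4")
  expect_setequal(c(d3$id, d4$id), late$id)
  expect_length(intersect(d3$id, d4$id), 0)

  f0 <- debt_pls(tab, "PLS0", n_draws = 30, min_dist = 5000, seed = 4)
  f2 <- debt_pls(tab, "PLS2", n_draws = 30, min_dist = 5000, seed = 4)
  expect_equal(nrow(f2$summary), nrow(f0$summary) + 4)
  expect_error(debt_pls(tab, "PLS9"), "unknown variant")
  expect_error(debt_pls(tab[setdiff(names(tab), "NC")], "PLS0",
                        n_draws = 10), "missing column")
})
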