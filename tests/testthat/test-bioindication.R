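test_that("calibration filter iterates to a fixed point", {
  # 3 surveys sharing 6 species occurring 3x each: everything cascades away
  m <- matrix(1L, 3, 6)
  expect_error(filter_calibration(m, min_richness = 5, min_occurrences = 5),
               "empty")

  # already-valid matrix returned unchanged
  set.seed(1)
  ok <- matrix(rbinom(20 * 10, 1, 0.8), 20, 10)
  ok[rowSums(ok) < 5, 1:5] <- 1L
  flt <- filter_calibration(ok)
  expect_identical(flt$comm, ok)
  expect_equal(flt$removed_surveys + flt$removed_species, 0)

  # hand-traced cascade: survey 1 has 4 species and is dropped; species h
  # occurred 5x but 2 of those in survey 1... build it explicitly
  m2 <- matrix(0L, 10, 8, dimnames = list(paste0("s", 1:10), letters[1:8]))
  m2[1, 1:4] <- 1L                      # survey 1: richness 4 -> dropped
  m2[2:10, 1:7] <- 1L                   # surveys 2-10: richness 7
  m2[2:5, 8] <- 1L                      # species h: 4 occurrences -> dropped
  flt2 <- filter_calibration(m2)
  expect_equal(rownames(flt2$comm), paste0("s", 2:10))
  expect_equal(colnames(flt2$comm), letters[1:7])
  expect_equal(flt2$removed_surveys, 1)
  expect_equal(flt2$removed_species, 1)
})

test_that("component-1 optima are occurrence-weighted response means", {
  fx <- gradient_fixture(80, 20, seed = 7)
  x <- fx$x
  # pin one species to sites at exactly 9 degrees
  comm <- fx$comm
  x[c(3, 9, 17)] <- 9
  comm[, 1] <- 0L
  comm[c(3, 9, 17), 1] <- 1L
  fit <- fit_wapls(comm, x, 1)
  expect_equal(unname(fit$u[1, 1]), 9)
})

test_that("one-component WA-PLS matches the classical WA oracle", {
  fx <- gradient_fixture(200, 40)
  fit <- fit_wapls(fx$comm, fx$x, 1)
  expect_lt(max(abs(fit$fitted_by_comp[, 1] - wa_oracle(fx$comm, fx$x))),
            1e-8)
})

test_that("training RMSD is non-increasing in the number of components", {
  fx <- gradient_fixture(150, 30, seed = 11)
  fit <- fit_wapls(fx$comm, fx$x, 3)
  expect_true(all(diff(fit$rmsd) <= 1e-10))
})

test_that("degenerate calibration inputs are rejected", {
  fx <- gradient_fixture(60, 15, seed = 2)
  bad <- cbind(fx$comm, empty = 0L)
  expect_error(fit_wapls(bad, fx$x, 1), "zero total occurrence")
  expect_error(fit_wapls(fx$comm, rep(10, nrow(fx$comm)), 1), "constant")
})

test_that("the residual forest never worsens training error and vanishes on a perfect fit", {
  fx <- gradient_fixture(150, 30, seed = 3)
  tf <- transfer_function(fx$comm, fx$x, n_components = 2, seed = 1)
  wrmsd <- tf$wapls$rmsd[2]
  expect_lte(tf$rmsd, wrmsd + 1e-12)

  # a response the WA-PLS stage fits perfectly leaves nothing to learn
  fit0 <- fit_wapls(fx$comm, fx$x, 1)
  expect_null(fit_residual_learner(fit0, fx$comm,
                                   fit0$fitted_by_comp[, 1], 1))
})

test_that("the forest stage captures a planted species interaction", {
  set.seed(21)
  n <- 400; m <- 20
  comm <- matrix(rbinom(n * m, 1, 0.45), n, m,
                 dimnames = list(NULL, sprintf("sp%02d", 1:m)))
  base <- 8 + 2 * rowMeans(comm[, 1:6])       # linear part
  x <- base + 1.0 * (comm[, 7] & comm[, 8]) + rnorm(n, 0, 0.15)
  tr <- seq_len(300); te <- 301:400
  tf_lin <- transfer_function(comm[tr, ], x[tr], n_components = 2,
                              learner = FALSE, min_occurrences = 1)
  tf_hyb <- transfer_function(comm[tr, ], x[tr], n_components = 2,
                              min_occurrences = 1, seed = 2)
  rmsd_lin <- validate_transfer(tf_lin, comm[te, ], x[te])$rmsd
  rmsd_hyb <- validate_transfer(tf_hyb, comm[te, ], x[te])$rmsd
  expect_lt(rmsd_hyb, rmsd_lin)
})

test_that("prediction handles known, unknown and degenerate surveys", {
  fx <- gradient_fixture(150, 30, seed = 5)
  tf <- transfer_function(fx$comm, fx$x, n_components = 2, seed = 1)
  # calibration surveys predict their fitted values
  expect_equal(as.numeric(predict(tf, tf$comm[1:5, , drop = FALSE])),
               unname(tf$fitted[1:5]), tolerance = 1e-10)
  # unknown species are dropped and counted
  aug <- cbind(tf$comm[1:3, , drop = FALSE],
               ghost1 = c(1L, 0L, 1L), ghost2 = 1L)
  pa <- predict(tf, aug)
  expect_equal(as.numeric(pa), unname(tf$fitted[1:3]), tolerance = 1e-10)
  expect_equal(attr(pa, "n_unknown"), c(2L, 1L, 2L))
  # surveys of only unknown species fail
  only_ghost <- matrix(1L, 1, 2, dimnames = list(NULL, c("gh1", "gh2")))
  expect_error(predict(tf, only_ghost), "no species|share no species")
})

test_that("a single-species survey scores at that species' optimum before deshrinking", {
  fx <- gradient_fixture(120, 25, seed = 6)
  fit <- fit_wapls(fx$comm, fx$x, 2)
  solo <- matrix(0L, 1, ncol(fx$comm), dimnames = list(NULL, colnames(fx$comm)))
  solo[1, 4] <- 1L
  sc <- climdebt:::wapls_scores(fit, solo)
  expect_equal(sc[1, 1] + fit$orth[[1]]$center, unname(fit$u[4, 1]))
})

test_that("validation statistics follow their closed forms", {
  fx <- gradient_fixture(150, 30, seed = 8)
  tr <- seq_len(100); te <- 101:nrow(fx$comm)
  tf <- transfer_function(fx$comm[tr, ], fx$x[tr], n_components = 2, seed = 1,
                          min_occurrences = 3)
  v <- validate_transfer(tf, fx$comm[te, ], fx$x[te])
  expect_true(v$r2 >= 0 && v$r2 <= 1 && v$rmsd >= 0)
  # shifted predictions: RMSD = |c|, R2 = 1
  obs <- c(9, 10, 11, 12)
  prd <- obs + 0.7
  expect_equal(sqrt(mean((prd - obs)^2)), 0.7)
  expect_equal(cor(prd, obs)^2, 1)
  # uncorrelated predictions give R2 near 0
  set.seed(1)
  expect_lt(cor(rnorm(2000), rnorm(2000))^2, 0.01)
  expect_error(validate_transfer(tf, fx$comm[1, , drop = FALSE], fx$x[1]),
               "holdout")
})

test_that("the debt is the CrT-FrT difference and is antisymmetric", {
  expect_equal(compute_debt(12, 11), 1)
  expect_equal(compute_debt(8.3, 8.3), 0)
  expect_equal(compute_debt(c(10, 11), c(9, 12)), c(1, -1))
  for (i in 1:10) {
    a <- rnorm(1, 10); b <- rnorm(1, 10)
    expect_equal(compute_debt(a, b), -compute_debt(b, a))
  }
  expect_error(compute_debt(NA, 3), "non-finite")
  expect_error(compute_debt(Inf, 3), "non-finite")
})

test_that("independent gradients bioindicated from one matrix stay uncorrelated", {
  set.seed(31)
  n <- 300; m <- 60
  grad1 <- runif(n, 5, 15)    # temperature-like
  grad2 <- runif(n, 4, 8)     # pH-like, independent
  grad3 <- runif(n, 0.02, 0.1)  # inverse C:N-like, independent
  opt1 <- runif(m, 5, 15); opt2 <- runif(m, 4, 8); opt3 <- runif(m, 0.02, 0.1)
  comm <- matrix(0L, n, m, dimnames = list(NULL, sprintf("sp%02d", 1:m)))
  for (k in seq_len(m)) {
    suit <- 0.9 * exp(-0.5 * ((grad1 - opt1[k]) / 2.5)^2 -
                        0.5 * ((grad2 - opt2[k]) / 1.0)^2 -
                        0.5 * ((grad3 - opt3[k]) / 0.02)^2)
    comm[, k] <- as.integer(runif(n) < suit)
  }
  keep <- rowSums(comm) >= 5
  comm <- comm[keep, ]
  tr <- seq_len(floor(sum(keep) * 0.7)); te <- setdiff(seq_len(sum(keep)), tr)
  fits <- lapply(list(grad1[keep], grad2[keep], grad3[keep]), function(g)
    transfer_function(comm[tr, ], g[tr], n_components = 2, seed = 1,
                      min_occurrences = 3))
  preds <- lapply(fits, function(f) as.numeric(predict(f, comm[te, ])))
  expect_lt(cor(preds[[1]], preds[[2]])^2, 0.2)
  expect_lt(cor(preds[[1]], preds[[3]])^2, 0.2)
  expect_lt(cor(preds[[2]], preds[[3]])^2, 0.2)
})

test_that("baseline-period surveys show no systematic debt", {
  cfg <- sim_config(grid_nx = 16, grid_ny = 16, n_species = 120,
                    baseline_years = 1975:1980, study_years = 2000:2005,
                    n_surveys_per_year = stats::setNames(
                      c(rep(40, 6), rep(20, 6)), c(1975:1980, 2000:2005)),
                    warming_total = 1, lag_lambda = 0.5, seed = 12)
  st <- simulate_debt_study(cfg)
  surv <- st$communities$surveys
  isb <- surv$period == "baseline"
  crt <- grid_extract(st$landscape$temperature, surv$x[isb], surv$y[isb],
                      surv$year[isb])
  tf <- transfer_function(surv$species[isb], crt, seed = 4)
  # within-calibration equilibrium: mean debt indistinguishable from zero
  d <- tf$observed - tf$fitted
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))
})
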