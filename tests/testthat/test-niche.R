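test_that("occupancy distributions are proper relative-frequency histograms", {
  d <- occupancy_distribution(c(8.1, 8.4, 9.9, 10.2, 10.3), binwidth = 0.5)
  expect_equal(sum(d$freq), 1, tolerance = 1e-12)
  expect_true(all(d$freq >= 0))
  expect_equal(d$n, 5)
  expect_error(occupancy_distribution(numeric(0)), "empty")
})

test_that("Schoener's D matches its identities and stays bounded", {
  e <- seq(0, 10, 1)
  p <- occupancy_distribution(c(1.5, 2.5, 3.5), e)
  expect_equal(schoener_d(p, p), 1)
  q <- occupancy_distribution(c(7.5, 8.5), e)
  expect_equal(schoener_d(p, q), 0)

  # the (0.5, 0.5) vs (0.8, 0.2) pair: D = 1 - 0.5 * (0.3 + 0.3) = 0.7
  e2 <- c(0, 1, 2)
  a <- occupancy_distribution(c(rep(0.5, 5), rep(1.5, 5)), e2)
  b <- occupancy_distribution(c(rep(0.5, 8), rep(1.5, 2)), e2)
  expect_equal(schoener_d(a, b), 0.7)
  expect_equal(schoener_d(b, a), 0.7)  # symmetry

  set.seed(4)
  for (i in 1:20) {
    u <- occupancy_distribution(runif(30, 0, 10), e)
    v <- occupancy_distribution(runif(30, 0, 10), e)
    d <- schoener_d(u, v)
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, schoener_d(v, u))
    # D = 1 iff bin-wise identical
    if (any(abs(u$freq - v$freq) > 1e-12)) expect_lt(d, 1)
  }
  expect_error(schoener_d(p, occupancy_distribution(1:3, seq(0, 12, 1))),
               "mismatched")
})

test_that("climatic tolerance is the occupied range", {
  expect_equal(climatic_tolerance(c(8, 10, 12)), 4)
  expect_equal(climatic_tolerance(5.5), 0)
  expect_equal(climatic_tolerance(c(500, 1300)), 800)
})

test_that("an unmoved species in an unchanged climate is perfectly conserved", {
  set.seed(10)
  clim <- rnorm(300, 10, 1.5)
  res <- distribution_conservatism(clim, clim, clim, n_replicates = 30)
  expect_equal(res$index, 1, tolerance = 1e-9)
  expect_equal(res$d_ref, 1)
})

test_that("distribution conservatism is 1 for in-place persistence under warming", {
  set.seed(11)
  base <- rnorm(400, 10, 1.5)
  warmed <- base + 1          # same localities, climate uniformly +1
  res <- distribution_conservatism(base, warmed, warmed, n_replicates = 50)
  expect_gt(res$index, 0.9)   # N_obs reproduces N_exp up to binning noise
})

test_that("displacement to climatically alien cells collapses DC", {
  set.seed(12)
  base <- rnorm(400, 10, 1.0)
  warmed_same <- base + 1.5
  # species moved to cells whose current climate is far from the expected
  # (stay-in-place) niche: the matched sample cannot reproduce N_exp
  moved_current <- rnorm(400, 16, 1.0)
  res <- distribution_conservatism(base, warmed_same, moved_current,
                                   n_replicates = 50)
  expect_lt(res$index, 0.3)
  # partial displacement sits in between
  half <- c(rnorm(200, 16, 1.0), base[1:200] + 1.5)
  res_half <- distribution_conservatism(base, warmed_same, half,
                                        n_replicates = 50)
  expect_lt(res_half$index, 1)
  expect_gt(res_half$index, res$index)
})

test_that("niche conservatism rewards tracking and punishes standing still", {
  set.seed(13)
  base <- rnorm(500, 10, 1.2)
  background <- rnorm(3000, 10.7, 2.5)   # rich background covering N_0
  tracking <- rnorm(500, 10, 1.2)        # occupied climate reproduces N_0
  res_track <- niche_conservatism(base, tracking, background,
                                  n_replicates = 50)
  expect_gt(res_track$index, 0.9)
  expect_lte(res_track$index, 1)         # bound holds by construction

  stayed <- base + 8                     # all occupied temps shifted, disjoint
  res_stay <- niche_conservatism(base, stayed, c(background, stayed),
                                 n_replicates = 50)
  expect_lt(res_stay$index, 0.1)
})

test_that("uncovered past-niche bins make NC undefined", {
  base <- c(rep(5, 30), rep(12, 30))
  background <- rep(12, 500)   # cannot reconstruct the cold half of N_0
  expect_error(niche_conservatism(base, rep(12, 50), background),
               "does not cover")
})

test_that("conservatism indices survive relabelling and duplication", {
  set.seed(14)
  base <- rnorm(200, 10, 1)
  now <- base + 0.8
  study <- c(base + 0.8, rnorm(200, 11, 1))
  r1 <- distribution_conservatism(base, now, study, n_replicates = 40)
  # duplicating every occurrence leaves all histograms unchanged
  r2 <- distribution_conservatism(rep(base, 2), rep(now, 2), rep(study, 2),
                                  n_replicates = 40)
  expect_equal(r1$d_ref, r2$d_ref, tolerance = 1e-12)
  expect_equal(r1$index, r2$index, tolerance = 0.05)  # matched-sampling noise
})

test_that("community means average the present species and count the missing", {
  vals <- c(a = 2, b = 4, c = NA)
  expect_equal(as.numeric(community_mean(vals, "a")), 2)
  m <- community_mean(vals, c("a", "b"))
  expect_equal(as.numeric(m), 3)
  expect_equal(attr(m, "n_missing"), 0)
  m2 <- community_mean(vals, c("a", "b", "c"))
  expect_equal(as.numeric(m2), 3)
  expect_equal(attr(m2, "n_missing"), 1)
  expect_error(community_mean(vals, "c"), "no species")
})
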