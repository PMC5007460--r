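test_that("temperature heterogeneity follows the fine-cell dispersion", {
  # 2x2 coarse cells, each split 2x2: fill one unit with {9, 9, 11, 11}
  fm <- matrix(10, 4, 4)
  fm[1:2, 1:2] <- c(9, 11, 9, 11)
  fine <- climate_grid(fm, 2000, cell_size = 500)
  expect_equal(temperature_heterogeneity(fine, 500, 500, 1000),
               sd(c(9, 9, 11, 11)), tolerance = 1e-9)
  expect_equal(sd(c(9, 9, 11, 11)), 2 / sqrt(3), tolerance = 1e-9)
  # uniform unit
  expect_equal(temperature_heterogeneity(fine, 1500, 1500, 1000), 0)
  # doubling the spread doubles the statistic
  fm2 <- matrix(10, 4, 4); fm2[1:2, 1:2] <- c(8, 12, 8, 12)
  fine2 <- climate_grid(fm2, 2000, cell_size = 500)
  expect_equal(temperature_heterogeneity(fine2, 500, 500, 1000),
               2 * temperature_heterogeneity(fine, 500, 500, 1000))
  # range statistic available
  expect_equal(temperature_heterogeneity(fine, 500, 500, 1000, stat = "range"),
               2)
})

test_that("potential habitat needs both forest and a suitable temperature", {
  tm <- matrix(c(7, 7, 12, 7), 2, 2)
  forest <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  hab <- potential_habitat(c(5, 10), tm, forest)
  expect_true(hab[1, 1])        # forest at 7
  expect_false(hab[2, 1])       # non-forest at 7
  expect_false(hab[1, 2])       # forest at 12
  # monotone in the tolerance interval
  hab_wide <- potential_habitat(c(4, 13), tm, forest)
  expect_true(all(hab_wide[hab]))
  expect_error(potential_habitat(c(5, 10), tm, matrix(FALSE, 2, 2)), "empty")
})

test_that("habitat proximity is inverse offset distance and monotone", {
  hab <- matrix(FALSE, 20, 20)
  hab[1, 1] <- TRUE             # habitat cell centred at (500, 500)
  # point inside habitat: maximum HP = 1/cell_size
  expect_equal(habitat_proximity(600, 600, hab, 1000), 1 / 1000)
  # point 9 km from the habitat cell centre
  expect_equal(habitat_proximity(9500, 500, hab, 1000), 1 / 10000)
  # doubling the distance strictly decreases HP
  expect_lt(habitat_proximity(18500, 500, hab, 1000),
            habitat_proximity(9500, 500, hab, 1000))
  expect_error(habitat_proximity(1, 1, matrix(FALSE, 3, 3), 1000),
               "empty past habitat")
})

test_that("aggregation index matches hand-counted patterns", {
  solid <- matrix(TRUE, 3, 3)             # e = 12, e_max = 12
  expect_equal(aggregation_index(solid), 1)
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_equal(aggregation_index(checker), 0)
  single <- matrix(c(TRUE, rep(FALSE, 8)), 3, 3)
  expect_equal(aggregation_index(single), 0)   # e_max = 0 convention
  expect_error(aggregation_index(matrix(FALSE, 2, 2)), "undefined")

  # translation and 90-degree rotation invariance
  set.seed(3)
  pat <- matrix(runif(64) < 0.4, 8, 8)
  if (!any(pat)) pat[3, 3] <- TRUE
  big <- matrix(FALSE, 12, 12); big[3:10, 2:9] <- pat
  expect_equal(aggregation_index(pat), aggregation_index(big))
  expect_equal(aggregation_index(pat), aggregation_index(t(pat[nrow(pat):1, ])))

  # identical periods give zero aggregation change
  expect_equal(habitat_aggregation_change(pat, pat), 0)
})

test_that("network distance is the point-to-polyline minimum", {
  seg <- cbind(c(-1, 1), c(0, 0))
  expect_equal(distance_to_network(0, 0, seg), 0)
  expect_equal(distance_to_network(0, 3, seg), 3)
  # beyond the endpoint the distance is to the vertex
  expect_equal(distance_to_network(2, 0, seg), 1)
  near <- cbind(c(0, 10), c(1, 1)); far <- cbind(c(0, 10), c(50, 50))
  expect_equal(distance_to_network(5, 0, list(near, far)), 1)
  expect_error(distance_to_network(0, 0, list()), "empty")
})

test_that("population sums count cell centres inside the disc", {
  dens <- matrix(1, 30, 30)    # 1 person per 1-km cell
  # survey at a cell centre: integer offsets, Gauss circle count for r = 10
  hpd <- population_within_radius(dens, 14500, 14500, radius = 10000)
  expect_equal(hpd, 317)
  expect_equal(population_within_radius(matrix(0, 30, 30), 14500, 14500), 0)
  expect_equal(population_within_radius(2 * dens, 14500, 14500), 2 * hpd)
  expect_error(population_within_radius(dens, 14999, 14999, radius = 100),
               "no raster cell")
})

test_that("radius clipping keeps only nearby habitat cells", {
  hab <- matrix(TRUE, 40, 40)
  clip <- clip_radius(hab, 20500, 20500, radius = 5000)
  centres_kept <- sum(clip)
  expect_lt(centres_kept, sum(hab))
  expect_gt(centres_kept, 0)
  # every kept cell centre is within the radius
  idx <- which(clip, arr.ind = TRUE)
  d <- sqrt(((idx[, 2] - 0.5) * 1000 - 20500)^2 +
              ((idx[, 1] - 0.5) * 1000 - 20500)^2)
  expect_true(all(d <= 5000))
})
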