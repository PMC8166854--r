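test_that("labeling matches a flood-fill oracle for both connectivities", {
  expect_equal(label_particles(matrix(0, 6, 6))$n, 0L)

  diag2 <- matrix(0, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- 1
  expect_equal(label_particles(diag2, 8)$n, 1L)
  expect_equal(label_particles(diag2, 4)$n, 2L)

  set.seed(61)
  for (conn in c(4, 8)) {
    m <- matrix(rbinom(300, 1, 0.4), 15, 20)
    got <- label_particles(m, conn)
    want <- oracle_label(m, conn)
    expect_equal(max(want), got$n)
    # identical partition up to label permutation
    pairs <- table(got$labels[m == 1], want[m == 1])
    expect_true(all(rowSums(pairs > 0) == 1))
    expect_true(all(colSums(pairs > 0) == 1))
  }
})

test_that("area and radius conversions reproduce the published values", {
  s4 <- scale_for("4x")
  s10 <- scale_for("10x")
  expect_equal(particle_area(20, s4), 142, tolerance = 0.005)
  expect_equal(particle_area(20, s10), 21.7, tolerance = 0.005)
  expect_equal(equivalent_radius(particle_area(20, s4)), 6.72,
    tolerance = 0.005
  )
  expect_equal(equivalent_radius(particle_area(20, s10)), 2.62,
    tolerance = 0.005
  )
  expect_equal(particle_area(1, scale_for("1x", um_per_pixel = 1)), 1)

  expect_equal(equivalent_radius(184.94), 7.67, tolerance = 0.001)
  expect_equal(equivalent_radius(41482.36), 114.91, tolerance = 0.001)
  expect_equal(equivalent_radius(177.82), 7.52, tolerance = 0.001)
  expect_equal(equivalent_radius(9389.01), 54.67, tolerance = 0.001)
  expect_equal(equivalent_radius(pi), 1)
  expect_equal(equivalent_diameter(pi), 2)
})

test_that("circularity is exact for analytic shapes", {
  r <- 3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  a <- 5
  expect_equal(circularity(a^2, 4 * a), pi / 4)
  expect_error(circularity(10, 0), "> 0")
})

test_that("perimeter estimator is accurate and scale-linear", {
  s1 <- scale_for("1x", um_per_pixel = 1)
  sq <- matrix(0, 14, 14)
  sq[3:12, 3:12] <- 1
  p <- perimeter_um(sq, s1)
  expect_equal(p, 36, tolerance = 0.05)

  # doubling a smooth shape roughly doubles the perimeter
  d16 <- disk_mask(44, 44, 22, 22, 16)
  d32 <- disk_mask(80, 80, 40, 40, 32)
  expect_equal(
    perimeter_um(d32, s1) / perimeter_um(d16, s1), 2,
    tolerance = 0.05
  )

  # two physical scales: exact linearity
  s2 <- scale_for("2x", um_per_pixel = 2.5)
  expect_equal(perimeter_um(sq, s2), 2.5 * p)

  # rasterized disk: circularity within the estimator's tolerance band
  d <- disk_mask(70, 70, 35, 35, 30)
  a_um <- particle_area(sum(d), s1)
  circ <- circularity(a_um, perimeter_um(d, s1))
  expect_gt(circ, 0.85)
  expect_lt(circ, 1.15)

  # single pixel: unit-square boundary
  one <- matrix(0, 3, 3)
  one[2, 2] <- 1
  expect_equal(perimeter_um(one, s1), 4)
})

test_that("per-particle table is consistent with the mask", {
  set.seed(62)
  m <- matrix(0, 40, 50)
  m <- pmax(m, disk_mask(40, 50, 10, 12, 5))
  m <- pmax(m, disk_mask(40, 50, 28, 35, 8))
  s <- scale_for("4x")
  tab <- particle_features(m, s)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$n_pixels), sum(m))
  expect_equal(tab$area_um2, tab$n_pixels * s$um_per_pixel^2)
  # area / um_per_pixel^2 is an integer pixel count
  expect_equal(tab$area_um2 / s$um_per_pixel^2, round(tab$area_um2 / s$um_per_pixel^2))
  expect_equal(tab$eq_radius_um, sqrt(tab$area_um2 / pi))
  expect_true(all(tab$circularity > 0))
  # centroids sit at the disk centres
  expect_equal(tab$centroid_row, c(10, 28), tolerance = 0.05)
  expect_equal(tab$centroid_col, c(12, 35), tolerance = 0.05)

  empty <- particle_features(matrix(0, 5, 5), s)
  expect_equal(nrow(empty), 0L)
})

test_that("recovered disk radii are within rasterization tolerance", {
  s1 <- scale_for("1x", um_per_pixel = 1)
  for (r in c(5, 9, 15, 24)) {
    d <- disk_mask(2 * r + 8, 2 * r + 8, r + 4, r + 4, r)
    tab <- particle_features(d, s1)
    expect_equal(tab$eq_radius_um, r, tolerance = 0.1)
  }
})

test_that("size distribution bins radii into 10-um classes", {
  rec <- tibble::tibble(eq_radius_um = c(7.52, 54.67))
  d <- size_distribution(rec)
  expect_equal(d$count[d$bin_lo == 0], 1L)
  expect_equal(d$count[d$bin_lo == 50], 1L)
  expect_equal(sum(d$count), 2L)
  expect_equal(attr(d, "total"), 2L)

  d0 <- size_distribution(tibble::tibble(eq_radius_um = numeric()))
  expect_true(all(d0$count == 0))

  set.seed(63)
  radii <- runif(100, 0, 130)
  dd <- size_distribution(tibble::tibble(eq_radius_um = radii))
  for (i in seq_len(nrow(dd))) {
    expect_equal(
      dd$count[i],
      sum(radii >= dd$bin_lo[i] & radii < dd$bin_hi[i])
    )
  }
  expect_equal(sum(dd$count), 100L)
  # overflow bin aggregates radii >= 100
  expect_equal(dd$count[is.infinite(dd$bin_hi)], sum(radii >= 100))
})

test_that("distribution comparison reports per-bin deltas", {
  rec <- tibble::tibble(eq_radius_um = c(3, 14, 14, 95))
  d <- size_distribution(rec)
  self <- compare_distributions(d, d)
  expect_true(all(self$delta == 0))

  rec2 <- tibble::tibble(eq_radius_um = c(3, 14, 44, 44, 101))
  d2 <- size_distribution(rec2)
  cmp <- compare_distributions(d, d2)
  expect_equal(cmp$delta[cmp$bin_lo == 10], -1L)
  expect_equal(cmp$delta[cmp$bin_lo == 40], 2L)
  expect_equal(cmp$delta[is.infinite(cmp$bin_hi)], 1L)

  d3 <- size_distribution(rec, bin_width_um = 25)
  expect_error(compare_distributions(d, d3), "different bin edges")
})
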