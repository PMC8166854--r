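test_that("single-threshold binarization is inclusive at the boundary", {
  img <- matrix(c(3, 9, 200), 1, 3)
  expect_equal(as.vector(apply_threshold(img, 9)), c(0, 1, 1))
  expect_true(all(apply_threshold(img, 0) == 1))
  expect_true(all(apply_threshold(img, 256) == 0))
})

test_that("two-threshold binarization matches a per-pixel loop oracle", {
  set.seed(41)
  g <- random_uint8(12, 9)
  h <- random_uint8(12, 9)
  S <- 80
  T <- 120
  want <- matrix(0, 12, 9)
  for (r in 1:12) {
    for (c in 1:9) {
      if (g[r, c] >= S && h[r, c] >= T) want[r, c] <- 1
    }
  }
  expect_equal(apply_threshold_2d(g, h, S, T), want)
  expect_true(all(apply_threshold_2d(g, h, 0, 0) == 1))
  expect_true(all(
    apply_threshold_2d(matrix(200, 3, 3), matrix(10, 3, 3), 100, 50) == 0
  ))
  # raising T never adds foreground
  counts <- vapply(
    seq(0, 255, by = 15),
    function(T) sum(apply_threshold_2d(g, h, S, T)),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("weighted median threshold follows the deviation-median rule", {
  img <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10, 100), 3, 3)
  res <- weighted_median_threshold(img, weight = 4.5)
  expect_equal(res$S, 45) # median 10, MAD 10, 4.5 * 10
  expect_equal(
    weighted_median_threshold(img, 4.5, variant = "median_plus_mad")$S,
    10 + 45
  )
  expect_warning(
    res0 <- weighted_median_threshold(matrix(7, 4, 4)),
    "constant"
  )
  expect_equal(res0$S, 0)
  expect_true(all(apply_threshold(matrix(7, 4, 4), res0$S) == 1))
})

test_that("1D Otsu equals the exhaustive two-class variance scan", {
  two <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  s <- otsu_1d(two)$S
  expect_gte(s, 51)
  expect_lte(s, 200)
  expect_equal(s, oracle_otsu_1d(two))

  expect_warning(otsu_1d(matrix(5, 3, 3)), "constant")

  set.seed(42)
  for (i in 1:25) {
    img <- random_uint8(16, 16)
    expect_equal(otsu_1d(img)$S, oracle_otsu_1d(img))
  }
  # normalized threshold reported on the unit scale
  expect_equal(otsu_1d(two)$diagnostics$S_normalized, s / 255)
})

test_that("average grayscale equals the loop mean oracle", {
  expect_equal(average_grayscale(matrix(9, 5, 5), 3), matrix(9, 5, 5))
  img <- random_uint8(5, 5)
  expect_equal(average_grayscale(img, 1), img)
  set.seed(43)
  img <- random_uint8(5, 5)
  expect_equal(average_grayscale(img, 3), oracle_mean_filter(img, 3))
  expect_error(average_grayscale(img, 4), "odd")
})

test_that("joint histogram counts pairs and marginalizes correctly", {
  cst <- matrix(7, 4, 5)
  jh <- joint_histogram(cst, cst)
  expect_equal(jh$r[8, 8], 20)
  expect_equal(sum(jh$p), 1)

  g <- matrix(c(0, 255), 2, 1)
  jh2 <- joint_histogram(g, g)
  expect_equal(jh2$p[1, 1], 0.5)
  expect_equal(jh2$p[256, 256], 0.5)

  set.seed(44)
  ga <- random_uint8(10, 10)
  ha <- random_uint8(10, 10)
  jh3 <- joint_histogram(ga, ha)
  expect_equal(sum(jh3$p), 1)
  expect_equal(
    unname(rowSums(jh3$r)),
    tabulate(as.vector(ga) + 1L, nbins = jh3$L + 1L)
  )
  expect_equal(
    unname(colSums(jh3$r)),
    tabulate(as.vector(ha) + 1L, nbins = jh3$L + 1L)
  )
  expect_error(joint_histogram(ga, random_uint8(9, 10)), "shapes")
})

test_that("2D Otsu separates two blocks and handles degeneracy", {
  g <- matrix(c(rep(40, 32), rep(200, 32)), 8, 8)
  res <- otsu_2d(g, g)
  expect_gte(res$S, 40)
  expect_lt(res$S, 200)
  st <- oracle_otsu_2d(g, g)
  expect_equal(c(res$S, res$T), st)

  expect_error(otsu_2d(matrix(3, 4, 4), matrix(3, 4, 4)), "degenerate")

  # empty edge/noise quadrants: class probabilities are complementary
  jh <- joint_histogram(g, g)
  w0 <- sum(jh$p[1:res$S, 1:res$T])
  w1 <- sum(jh$p[(res$S + 1):(jh$L + 1), (res$T + 1):(jh$L + 1)])
  expect_equal(w0 + w1, 1)
})

test_that("cubic log-frequency fit recovers a generating cubic exactly", {
  # counts at 4 bins: the LS cubic interpolates, so the recovered
  # coefficients must match the Vandermonde solution of the same points
  ns <- c(10, 30, 60, 90)
  ks <- c(1000, 400, 120, 30)
  vals <- rep(ns, times = ks)
  h <- matrix(c(vals, rep(ns[1], 50 * 31 - length(vals))), 50, 31)
  fit <- fit_log_frequency(h, slope_set_value = -0.05)
  counts <- tabulate(as.vector(h) + 1L, 256L)
  stopifnot(sum(counts > 0) == 4)
  expected <- solve(
    outer(ns, 0:3, `^`),
    log10(counts[ns + 1])
  )
  expect_equal(fit$coefficients, unname(expected), tolerance = 1e-6)
  expect_lt(fit$T_min, fit$T_max)

  # steep pure-exponential decay: slope never exceeds the set value
  ns2 <- c(0, 10, 20, 30)
  ks2 <- c(10000, 1000, 100, 10) # log10 slope -0.1 everywhere
  vals2 <- rep(ns2, times = ks2)
  h2 <- matrix(c(vals2, rep(0, 11200 - length(vals2))), 112, 100)
  expect_error(fit_log_frequency(h2, -0.05), "never exceeds")

  expect_error(fit_log_frequency(matrix(3, 4, 4)), ">= 4 populated bins")
})

test_that("guess threshold reproduces the published worked examples", {
  expect_equal(guess_threshold(20.11, 49.48, 38), 29.562)
  expect_equal(round(guess_threshold(17.4, 45.76, 48), 1), 29.2)
  expect_equal(guess_threshold(12, 12, 12), 12)
  # convexity: result within the range of its inputs
  set.seed(45)
  for (i in 1:20) {
    x <- runif(3, 0, 255)
    gt <- guess_threshold(x[1], x[2], x[3])
    expect_gte(gt, min(x))
    expect_lte(gt, max(x))
  }
  expect_error(guess_threshold(1, 2, 3, weights = c(-1, 1, 1)), "non-negative")
})

test_that("particle-count estimate counts clean disks and ignores blanks", {
  expect_equal(estimate_particle_count(matrix(0, 40, 40)), 0L)

  img <- matrix(5, 96, 96)
  centers <- expand.grid(r = c(16, 48, 80), c = c(16, 48, 80))
  for (i in seq_len(9)) {
    img <- pmax(img, 220 * disk_mask(96, 96, centers$r[i], centers$c[i], 5))
  }
  set.seed(46)
  img <- pmin(pmax(round(img + matrix(rnorm(96 * 96, sd = 2), 96, 96)), 0), 255)
  expect_equal(estimate_particle_count(img), 9L)
})

test_that("modified 2D Otsu converges inside the feasible threshold band", {
  # scene with well-separated bright disks over low noise
  set.seed(47)
  img <- matrix(sample(0:14, 120 * 120, replace = TRUE), 120, 120)
  centers <- expand.grid(r = c(20, 60, 100), c = c(20, 60, 100))
  for (i in seq_len(9)) {
    img <- pmax(img, 210 * disk_mask(120, 120, centers$r[i], centers$c[i], 6))
  }
  h <- average_grayscale(img, 3)
  res <- modified_otsu_2d(img, h, fallback = "otsu_t")
  d <- res$diagnostics
  expect_true(d$converged)
  expect_equal(d$N_g, d$N_e)
  expect_equal(d$N_e, 9L)

  # oracle: exhaustive scan of the feasible T interval at the returned S
  feasible <- vapply(1:d$L, function(T) {
    m <- postprocess_mask(apply_threshold_2d(img, h, res$S, T))
    label_particles(m)$n == d$N_e
  }, logical(1))
  expect_true(feasible[round(res$T)])

  # never worse than the initial guess
  traj <- d$trajectory
  expect_lte(
    min(abs(d$N_e - traj$N_g[traj$T == res$T])),
    abs(d$N_e - traj$N_g[1])
  )
})

test_that("modified 2D Otsu stops immediately when the guess already matches", {
  set.seed(48)
  img <- matrix(sample(0:14, 120 * 120, replace = TRUE), 120, 120)
  centers <- expand.grid(r = c(20, 60, 100), c = c(20, 60, 100))
  for (i in seq_len(9)) {
    img <- pmax(img, 210 * disk_mask(120, 120, centers$r[i], centers$c[i], 6))
  }
  h <- average_grayscale(img, 3)
  res <- modified_otsu_2d(img, h, fallback = "otsu_t")
  if (res$diagnostics$trajectory$error[1] == 0) {
    expect_equal(res$diagnostics$iterations, 1L)
    expect_equal(res$T, res$diagnostics$T_guess)
  } else {
    expect_gt(res$diagnostics$iterations, 1L)
  }
})
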