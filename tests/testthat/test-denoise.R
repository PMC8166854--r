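test_that("median filter matches a brute-force neighborhood oracle", {
  expect_equal(median_filter(matrix(9, 5, 5), 3), matrix(9, 5, 5))

  imp <- matrix(0, 3, 3)
  imp[2, 2] <- 255
  expect_true(all(median_filter(imp, 3) == 0))

  set.seed(21)
  for (n in c(3, 5)) {
    img <- random_uint8(7, 7)
    expect_equal(median_filter(img, n), oracle_median_filter(img, n))
  }
  expect_error(median_filter(matrix(0, 4, 4), 2), "odd")
})

test_that("median filter never invents values outside the neighborhood", {
  set.seed(22)
  img <- random_uint8(12, 10)
  out <- median_filter(img, 3)
  expect_true(all(out %in% img))
})

test_that("total variation matches analytic and loop-oracle values", {
  expect_equal(total_variation(matrix(4, 6, 6)), 0)
  # ramp along columns, both rows identical: (N-1) unit x-steps per row
  ramp <- rbind(1:8, 1:8)
  expect_equal(total_variation(ramp), 2 * 7)
  set.seed(23)
  img <- matrix(runif(25, 0, 100), 5, 5)
  expect_equal(total_variation(img), oracle_total_variation(img))
})

test_that("TV denoising reduces TV monotonically and converges", {
  flat <- matrix(5, 16, 16)
  out <- tv_denoise(flat)
  expect_equal(out$image, flat)
  expect_equal(nrow(out$trace), 0L)

  zero <- matrix(0, 8, 8)
  expect_equal(tv_denoise(zero)$image, zero)

  set.seed(24)
  blob <- 20 + 200 * disk_mask(48, 48, 24, 24, 9) +
    matrix(rnorm(48 * 48, sd = 10), 48, 48)
  res <- tv_denoise(blob)
  expect_lt(total_variation(res$image), total_variation(blob))
  tr <- res$trace
  expect_gt(nrow(tr), 0)
  # line search: TV non-increasing across accepted steps
  expect_true(all(diff(tr$tv) <= 0))
  expect_true(
    tr$rel_change[nrow(tr)] < 0.005 || nrow(tr) == tv_params()$max_iters
  )
})

test_that("background estimation passes low frequencies and rejects high", {
  const <- matrix(42, 32, 32)
  expect_equal(
    estimate_background(const, 0.1)$background, const,
    tolerance = 1e-9
  )

  # DCT-basis cosine (even-symmetric), one half-cycle over 64 px:
  # frequency 1/128 cycles/px, far below cutoff 0.1 * Nyquist = 0.05
  j <- 64
  low <- 100 + 30 * outer(
    cos(pi * (seq_len(j) - 0.5) / j),
    cos(pi * (seq_len(j) - 0.5) / j)
  )
  bg <- estimate_background(low, 0.1)$background
  expect_lt(max(abs(bg - low)), 1e-6 * 30)

  # fast even-symmetric oscillation on a DC offset: only DC survives
  hi <- 100 + 40 * outer(
    cos(pi * 16 * (seq_len(j) - 0.5) / j),
    rep(1, j)
  )
  bg2 <- estimate_background(hi, 0.05)$background
  expect_lt(max(abs(bg2 - 100)), 1e-6 * 40)
})

test_that("background estimation is linear without object clipping", {
  set.seed(25)
  i1 <- matrix(runif(32 * 32, 0, 100), 32, 32)
  i2 <- matrix(runif(32 * 32, 0, 100), 32, 32)
  b <- function(x) estimate_background(x, 0.07, "subtract")$background
  expect_equal(b(2 * i1 + 3 * i2), 2 * b(i1) + 3 * b(i2), tolerance = 1e-8)
})

test_that("background normalization flattens a blank field and ramps", {
  img <- matrix(50, 24, 24)
  bg_d <- estimate_background(img, 0.1, "divide")
  expect_true(all(normalize_background(img, bg_d) == 0))
  bg_s <- estimate_background(img, 0.1, "subtract")
  expect_true(all(normalize_background(img, bg_s) == 0))
  expect_error(
    normalize_background(matrix(1, 2, 2), bg_d),
    "shapes differ"
  )
})

test_that("divide-mode normalization strongly reduces background CV", {
  sc <- generate_scene(
    scene_config(
      dim = c(128, 128), n_particles = 3, radius_range = c(4, 7),
      illumination_amplitude = 0, gaussian_sigma = 0, poisson = FALSE,
      n_distractors = 0
    ),
    seed = 31
  )
  sc <- apply_illumination(sc, amplitude = 0.4, spatial_period = 120)
  g <- sc$green
  bg <- estimate_background(g, 0.05, "divide", clip_objects = TRUE)
  out <- normalize_background(g, bg)
  bg_px <- sc$truth_mask == 0
  # background dispersion relative to the image's dynamic range: the raw
  # frame carries the full illumination gradient, the normalized frame a
  # flat background
  disp <- function(x, ref) sd(x[bg_px]) / diff(range(ref))
  expect_gt(disp(g, g) / disp(out, out), 5)
})
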