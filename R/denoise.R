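#' Median filter
#'
#' Replaces each pixel with the median of its `n x n` neighborhood.
#' Effective against salt-type impulse noise and the long-tailed intensity
#' histograms typical of fluorescence backgrounds. Borders are handled by
#' replicate padding, so output values are always members of the input
#' neighborhood multiset.
#'
#' @param img Grayscale matrix.
#' @param n Odd window size (default 3).
#' @return Filtered matrix, same shape and scale.
#' @export
median_filter <- function(img, n = 3) {
  stopifnot_gray(img)
  n <- check_odd_window(n)
  if (n == 1L) {
    return(img)
  }
  off <- window_offsets(n)
  cols <- purrr::map2(
    off$dr, off$dc,
    function(dr, dc) as.vector(shift_mat(img, dr, dc, pad = "replicate"))
  )
  matrix(elementwise_median(cols), nrow(img), ncol(img))
}

# Forward-difference gradients with replicate edge: the last row/column
# difference is 0. Returns list(gx, gy) (column and row direction).
#' @keywords internal
#' @noRd
forward_gradient <- function(img) {
  j <- nrow(img)
  k <- ncol(img)
  gx <- img[, c(seq_len(k - 1L) + 1L, k), drop = FALSE] - img
  gy <- img[c(seq_len(j - 1L) + 1L, j), , drop = FALSE] - img
  list(gx = gx, gy = gy)
}

#' Total variation of an image
#'
#' The L1 norm of the discrete gradient: the sum over pixels of
#' `sqrt(|grad_x g|^2 + |grad_y g|^2)` with forward differences and
#' replicate edges. Captures local fluctuations (noise); edges of real
#' particles also contribute, but noise dominates in raw images.
#'
#' @param img Grayscale matrix with at least 2 rows and columns.
#' @return A scalar.
#' @export
total_variation <- function(img) {
  stopifnot_gray(img)
  if (nrow(img) < 2 || ncol(img) < 2) {
    stop("`img` must be at least 2 x 2", call. = FALSE)
  }
  gr <- forward_gradient(img)
  sum(sqrt(gr$gx^2 + gr$gy^2))
}

#' Total-variation denoising parameters
#'
#' @param tolerance Convergence bound on the relative change
#'   `||g_new - g|| / ||g||` (Frobenius norms) between iterations.
#' @param epsilon_scale The gradient regularizer epsilon is
#'   `epsilon_scale * (max - min)` of the input; it only prevents division
#'   by zero in flat regions.
#' @param max_iters Iteration cap.
#' @param step_rule `"line_search"` (backtracking, TV non-increasing) or
#'   `"fixed"`.
#' @param tau0 Initial step as a fraction of the dynamic range.
#' @return A `tv_params` list.
#' @export
tv_params <- function(tolerance = 0.005, epsilon_scale = 1e-6,
                      max_iters = 200, step_rule = c("line_search", "fixed"),
                      tau0 = 0.25) {
  stopifnot(tolerance > 0, epsilon_scale > 0, max_iters >= 1, tau0 > 0)
  structure(
    list(
      tolerance = tolerance, epsilon_scale = epsilon_scale,
      max_iters = as.integer(max_iters),
      step_rule = match.arg(step_rule), tau0 = tau0
    ),
    class = "tv_params"
  )
}

# Gradient of TV(g): minus the divergence of the epsilon-normalized
# gradient field. Divergence uses the adjoint backward difference (zero
# padding), the standard pairing for forward-difference TV.
#' @keywords internal
#' @noRd
tv_gradient <- function(img, epsilon) {
  gr <- forward_gradient(img)
  mag <- sqrt(gr$gx^2 + gr$gy^2 + epsilon^2)
  nx <- gr$gx / mag
  ny <- gr$gy / mag
  divx <- nx - shift_mat(nx, 0L, 1L, pad = 0)
  divy <- ny - shift_mat(ny, 1L, 0L, pad = 0)
  -(divx + divy)
}

#' Total-variation denoising by gradient descent
#'
#' Iterates `g <- g - tau * grad TV(g)` until the relative change between
#' iterates falls below `params$tolerance` or `params$max_iters` is
#' reached. The step `tau` is found by backtracking line search (halving
#' from `tau0 * dynamic range` until TV decreases), so TV is
#' non-increasing across accepted steps; a fixed-step mode is available.
#' Runs on the float representation; quantize afterwards with
#' [to_uint8()].
#'
#' @param img Grayscale matrix (any numeric scale).
#' @param params A [tv_params()] list.
#' @return A list with `image` (denoised matrix) and `trace` (a
#'   `tv_trace` tibble: iteration, tv, rel_change, tau).
#' @export
tv_denoise <- function(img, params = tv_params()) {
  stopifnot_gray(img)
  if (!all(is.finite(img))) {
    stop("`img` contains non-finite values", call. = FALSE)
  }
  rng <- max(img) - min(img)
  empty_trace <- function() {
    structure(
      tibble::tibble(
        iteration = integer(), tv = numeric(),
        rel_change = numeric(), tau = numeric()
      ),
      class = c("tv_trace", "tbl_df", "tbl", "data.frame")
    )
  }
  norm_g <- sqrt(sum(img^2))
  if (rng == 0 || norm_g == 0) {
    # flat or all-zero image: TV already 0 / relative change undefined;
    # treated as converged at iteration 0
    return(list(image = img, trace = empty_trace()))
  }
  eps <- params$epsilon_scale * rng
  tau_init <- params$tau0 * rng
  g <- img
  tv_cur <- total_variation(g)
  rows <- vector("list", params$max_iters)
  n_used <- 0L
  for (it in seq_len(params$max_iters)) {
    grad <- tv_gradient(g, eps)
    if (params$step_rule == "fixed") {
      tau <- tau_init
      g_new <- g - tau * grad
      tv_new <- total_variation(g_new)
    } else {
      tau <- tau_init
      accepted <- FALSE
      for (half in 1:40) {
        g_new <- g - tau * grad
        tv_new <- total_variation(g_new)
        if (tv_new < tv_cur) {
          accepted <- TRUE
          break
        }
        tau <- tau / 2
      }
      if (!accepted) break # no decreasing step exists: converged
    }
    rel <- sqrt(sum((g_new - g)^2)) / sqrt(sum(g^2))
    n_used <- it
    rows[[it]] <- tibble::tibble(
      iteration = it, tv = tv_new, rel_change = rel, tau = tau
    )
    g <- g_new
    tv_cur <- tv_new
    if (rel < params$tolerance) break
  }
  trace <- if (n_used == 0L) {
    empty_trace()
  } else {
    structure(
      dplyr::bind_rows(rows[seq_len(n_used)]),
      class = c("tv_trace", "tbl_df", "tbl", "data.frame")
    )
  }
  list(image = g, trace = trace)
}

#' Estimate the illumination background by FFT low-pass filtering
#'
#' Takes the 2-D FFT, zeroes every frequency whose radial distance exceeds
#' `cutoff_fraction` of the Nyquist frequency (ideal low-pass, DC always
#' kept), and inverts. The surviving low-frequency field is the smooth
#' illumination background; particle-scale detail lies far above the
#' cutoff.
#'
#' @param img Grayscale matrix.
#' @param cutoff_fraction Radial cutoff as a fraction of Nyquist, in
#'   `(0, 1]`. The default 0.02 keeps only illumination-scale (tens of
#'   pixels and larger) variation.
#' @param mode `"divide"` or `"subtract"`; with `"divide"` the background
#'   is floored to a small positive value.
#' @param clip_objects If `TRUE`, pixel values are clipped at a robust
#'   ceiling (median + 3 MAD) before the FFT, so that bright particles do
#'   not leak ringing artifacts into the illumination estimate. `FALSE`
#'   (default) keeps the operator linear.
#' @return A `background_model` list: `background` matrix,
#'   `cutoff_fraction`, `mode`.
#' @export
estimate_background <- function(img, cutoff_fraction = 0.02,
                                mode = c("divide", "subtract"),
                                clip_objects = FALSE) {
  stopifnot_gray(img)
  mode <- match.arg(mode)
  if (isTRUE(clip_objects)) {
    med <- stats::median(img)
    ceil <- med + 3 * stats::median(abs(img - med))
    if (ceil > min(img)) img <- pmin(img, ceil)
  }
  if (cutoff_fraction <= 0 || cutoff_fraction > 1) {
    stop("`cutoff_fraction` must be in (0, 1]", call. = FALSE)
  }
  j <- nrow(img)
  k <- ncol(img)
  # even (mirror) extension to 2J x 2K before the FFT: the image is not
  # periodic, and an ideal low-pass on the raw frame rings at the borders
  ext <- rbind(
    cbind(img, img[, rev(seq_len(k)), drop = FALSE]),
    cbind(
      img[rev(seq_len(j)), , drop = FALSE],
      img[rev(seq_len(j)), rev(seq_len(k)), drop = FALSE]
    )
  )
  j2 <- 2L * j
  k2 <- 2L * k
  # signed frequencies in cycles/pixel; Nyquist = 0.5
  fr <- (seq_len(j2) - 1L) / j2
  fr <- ifelse(fr > 0.5, fr - 1, fr)
  fc <- (seq_len(k2) - 1L) / k2
  fc <- ifelse(fc > 0.5, fc - 1, fc)
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- rad <= cutoff_fraction * 0.5
  ft <- stats::fft(ext)
  ft[!keep] <- 0
  bg <- Re(stats::fft(ft, inverse = TRUE))[seq_len(j), seq_len(k)] / (j2 * k2)
  if (mode == "divide") {
    floor_val <- 1e-6 * max(abs(bg), 1)
    n_bad <- sum(bg < floor_val)
    if (n_bad > 0) {
      warning(n_bad, " non-positive background pixel(s) floored for division")
      bg <- pmax(bg, floor_val)
    }
  }
  structure(
    list(background = bg, cutoff_fraction = cutoff_fraction, mode = mode),
    class = "background_model"
  )
}

#' Normalize uneven illumination with a background model
#'
#' `divide` mode divides pixel-by-pixel by the low-pass background;
#' `subtract` subtracts it and clips at zero. Either way the result is
#' quantized to the 0--255 working scale with [to_uint8()], ready for
#' thresholding.
#'
#' @param img Grayscale matrix (same shape as the background).
#' @param bg A `background_model` from [estimate_background()].
#' @return Integer-valued uint8 matrix.
#' @export
normalize_background <- function(img, bg) {
  stopifnot_gray(img)
  if (!inherits(bg, "background_model")) {
    stop("`bg` must come from estimate_background()", call. = FALSE)
  }
  if (!all(dim(img) == dim(bg$background))) {
    stop("image and background shapes differ", call. = FALSE)
  }
  out <- if (bg$mode == "divide") {
    b <- bg$background
    floor_val <- 1e-6 * max(abs(b), 1)
    if (any(b < floor_val)) {
      warning("non-positive background pixels floored for division")
      b <- pmax(b, floor_val)
    }
    img / b
  } else {
    pmax(img - bg$background, 0)
  }
  to_uint8(out)
}
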