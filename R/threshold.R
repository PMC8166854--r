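# Thresholding: weighted median, 1D Otsu, 2D Otsu on the joint
# grayscale/average-grayscale histogram, and the modified 2D Otsu that
# iteratively tunes the average-grayscale threshold T against a particle
# count estimated by weighted-median thresholding.

#' @keywords internal
#' @noRd
new_threshold_result <- function(method, S, T = NA_real_,
                                 diagnostics = list()) {
  structure(
    list(method = method, S = S, T = T, diagnostics = diagnostics),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> method:", x$method, "\n")
  cat("  S =", format(x$S), if (!is.na(x$T)) paste(" T =", format(x$T)), "\n")
  dg <- x$diagnostics
  keys <- intersect(
    c("T_otsu", "T_min", "T_max", "T_guess", "N_e", "iterations", "converged"),
    names(dg)
  )
  for (k in keys) cat("  ", k, "=", format(dg[[k]]), "\n")
  invisible(x)
}

#' Binarize an image with a single grayscale threshold
#'
#' Pixels with `g >= T` become 1 (foreground, white), all others 0. The
#' boundary is inclusive: a pixel exactly at the threshold is foreground.
#'
#' @param img Grayscale matrix.
#' @param T Threshold on the pixel-value scale.
#' @return Binary \{0,1\} matrix of the same shape.
#' @export
apply_threshold <- function(img, T) {
  stopifnot_gray(img)
  (img >= T) * 1
}

#' Binarize with grayscale and average-grayscale thresholds
#'
#' The two-threshold rule of the 2D Otsu family: foreground iff
#' `g >= S` and `h >= T` simultaneously; everything else (including the
#' edge/noise quadrants of the joint histogram) is background.
#'
#' @param g Grayscale matrix.
#' @param h Average-grayscale matrix (same shape, see
#'   [average_grayscale()]).
#' @param S Grayscale threshold.
#' @param T Average-grayscale threshold.
#' @return Binary \{0,1\} matrix.
#' @export
apply_threshold_2d <- function(g, h, S, T) {
  stopifnot_gray(g)
  stopifnot_gray(h)
  if (!all(dim(g) == dim(h))) {
    stop("`g` and `h` shapes differ", call. = FALSE)
  }
  ((g >= S) & (h >= T)) * 1
}

#' Weighted median threshold
#'
#' Computes the median `m` of all pixels, the absolute deviation matrix
#' `D = |img - m|`, and sets the threshold to `weight * median(D)` --
#' a robust scale estimate of the background fluctuation. A signed
#' deviation would have median ~0 and make the method vacuous, so the
#' absolute deviation is used; the variant `"median_plus_mad"`
#' (`T = m + weight * median(D)`) is available but off by default.
#'
#' @param img uint8 grayscale matrix.
#' @param weight Multiplier on the median absolute deviation (default 4.5,
#'   the setting used for FITC aggregate images).
#' @param variant `"mad"` (default) or `"median_plus_mad"`.
#' @return A `threshold_result` with `S` set to the threshold.
#' @export
weighted_median_threshold <- function(img, weight = 4.5,
                                      variant = c("mad", "median_plus_mad")) {
  stopifnot_uint8(img)
  variant <- match.arg(variant)
  m <- stats::median(img)
  mad_val <- stats::median(abs(img - m))
  thr <- if (variant == "mad") weight * mad_val else m + weight * mad_val
  if (mad_val == 0 && variant == "mad") {
    if (stats::var(as.vector(img)) == 0) {
      warning("constant image: weighted-median threshold is 0 (all-ones mask)")
    }
  }
  new_threshold_result(
    "weighted_median",
    S = thr,
    diagnostics = list(median = m, mad = mad_val, weight = weight,
                       variant = variant)
  )
}

#' 1D Otsu threshold
#'
#' Builds the 256-bin histogram of pixel values, computes zeroth and first
#' cumulative moments, and returns the integer threshold maximizing the
#' between-class variance. Ties are broken by the smallest threshold. The
#' normalized value `S / 255` is reported in the diagnostics.
#'
#' @param img uint8 grayscale matrix.
#' @return A `threshold_result` with integer `S`.
#' @export
otsu_1d <- function(img) {
  stopifnot_uint8(img)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L) {
    warning("constant image: 1D Otsu threshold degenerate")
    s <- as.numeric(img[1])
    return(new_threshold_result(
      "otsu1d",
      S = s,
      diagnostics = list(S_normalized = s / 255, degenerate = TRUE)
    ))
  }
  v <- 0:255
  # class 0 holds values < s (the threshold itself is foreground per the
  # g >= S binarization rule); candidate s = 1..255
  omega <- cumsum(p)[1:255] # P(value < s) for s = 1..255
  mu <- cumsum(v * p)[1:255]
  mu_t <- sum(v * p)
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  s <- (1:255)[which.max(sigma_b)]
  new_threshold_result(
    "otsu1d",
    S = as.numeric(s),
    diagnostics = list(
      S_normalized = s / 255,
      sigma_B = max(sigma_b, na.rm = TRUE)
    )
  )
}

#' Average-grayscale image
#'
#' The local `n x n` neighborhood mean of the grayscale image, rounded to
#' the nearest integer (replicate-padded borders). This is the second axis
#' of the 2D Otsu joint histogram: genuine particles are bright in both
#' `g` and `h`, whereas isolated noise is bright in `g` only.
#'
#' @param img uint8 grayscale matrix.
#' @param n Odd neighborhood size (default 3).
#' @return Integer-valued matrix.
#' @export
average_grayscale <- function(img, n = 3) {
  stopifnot_uint8(img)
  n <- check_odd_window(n)
  if (n > min(dim(img))) {
    stop("`n` must not exceed the smallest image dimension", call. = FALSE)
  }
  if (n == 1L) {
    return(img)
  }
  off <- window_offsets(n)
  acc <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(off))) {
    acc <- acc + shift_mat(img, off$dr[i], off$dc[i], pad = "replicate")
  }
  round_half_away(acc / n^2)
}

#' Joint grayscale/average-grayscale histogram
#'
#' Counts the pairs `(g(x,y) = i, h(x,y) = j)` over all pixels into the
#' joint frequency matrix `r` and probability matrix `p = r / (J K)`,
#' with bins `0..L` on each axis where `L` is the maximum pixel value
#' over `g` and `h`.
#'
#' @param g uint8 grayscale matrix.
#' @param h uint8 average-grayscale matrix, same shape.
#' @return A `joint_histogram` list: `r`, `p` (both `(L+1) x (L+1)`),
#'   `L`, `J`, `K`.
#' @export
joint_histogram <- function(g, h) {
  stopifnot_uint8(g, "g")
  stopifnot_uint8(h, "h")
  if (!all(dim(g) == dim(h))) {
    stop("`g` and `h` shapes differ", call. = FALSE)
  }
  L <- max(g, h)
  nb <- L + 1L
  idx <- as.vector(g) * nb + as.vector(h) + 1L
  r <- matrix(tabulate(idx, nbins = nb * nb), nb, nb, byrow = TRUE)
  dimnames(r) <- list(g = 0:L, h = 0:L)
  structure(
    list(r = r, p = r / length(g), L = L, J = nrow(g), K = ncol(g)),
    class = "joint_histogram"
  )
}

# Trace of the between-class variance over every candidate (s,t), via 2-D
# cumulative sums of p, i*p, j*p. Class 0 is {g < s, h < t} so that the
# binarization rule g >= S & h >= T recovers class 1 exactly; cells with
# omega0 in {0,1} have an undefined denominator and are skipped.
#' @keywords internal
#' @noRd
trace_sigma_b_grid <- function(jh) {
  p <- jh$p
  L <- jh$L
  vals <- 0:L
  cum2 <- function(m) t(apply(apply(m, 2, cumsum), 1, cumsum))
  P0 <- cum2(p)
  Mi <- cum2(p * vals) # rows indexed by i = g value
  Mj <- cum2(t(t(p) * vals))
  mu_ti <- Mi[L + 1L, L + 1L]
  mu_tj <- Mj[L + 1L, L + 1L]
  num <- (mu_ti * P0 - Mi)^2 + (mu_tj * P0 - Mj)^2
  den <- P0 * (1 - P0)
  tr <- num / den
  tr[den <= 0] <- -Inf
  tr[!is.finite(tr)] <- -Inf
  # row/col u of tr holds the class-0 sums over values 0..u-1, i.e. the
  # candidate thresholds s = u, t = u (class 0 strictly below)
  tr[seq_len(L), seq_len(L), drop = FALSE] # s, t = 1..L
}

#' 2D Otsu threshold
#'
#' Maximizes the trace of the between-class variance of the joint
#' grayscale/average-grayscale distribution over all candidate threshold
#' pairs `(s, t)`. Class 0 (background) is the quadrant `g <= s, h <= t`;
#' class 1 (objects) is `g > s, h > t`; the remaining quadrants hold edge
#' and noise pixels whose probability mass is negligible after denoising.
#' Ties are broken by the smallest `s`, then the smallest `t`.
#'
#' @param g uint8 grayscale matrix.
#' @param h uint8 average-grayscale matrix (see [average_grayscale()]).
#' @return A `threshold_result` with `S` and `T`.
#' @export
otsu_2d <- function(g, h) {
  jh <- joint_histogram(g, h)
  tr <- trace_sigma_b_grid(jh)
  if (all(tr == -Inf)) {
    stop(
      "degenerate joint histogram: no threshold pair separates two ",
      "non-empty classes (constant image?)",
      call. = FALSE
    )
  }
  # ties broken by the smallest s, then the smallest t: scan s-major
  best <- -Inf
  s_best <- t_best <- NA_integer_
  for (si in seq_len(nrow(tr))) {
    row <- tr[si, ]
    m <- max(row)
    if (m > best) {
      best <- m
      s_best <- si
      t_best <- which.max(row)
    }
  }
  new_threshold_result(
    "otsu2d",
    S = as.numeric(s_best), T = as.numeric(t_best),
    diagnostics = list(trace_sigma_B = best, L = jh$L)
  )
}

#' Cubic fit to the log-frequency curve of the average-grayscale image
#'
#' The common logarithm of the pixel-value frequency of `h` decays with
#' pixel value; the steep drop at low values marks the background. A cubic
#' polynomial `P(n)` is least-squares fitted to `log10 k(n)` over the
#' populated bins. `T_min` and `T_max` bracket the pixel-value interval
#' on which the fitted slope `fP(n)` exceeds `slope_set_value`: the
#' interval ends are the roots of `fP(n) = slope_set_value`, clamped to
#' the populated range when a root falls outside it. The fit errors when
#' the slope never exceeds the set value (e.g. a steep pure-exponential
#' decay), or with fewer than 4 populated bins.
#'
#' @param h uint8 average-grayscale matrix.
#' @param slope_set_value Target slope (default -0.05).
#' @return A `cubic_log_fit` list: `coefficients` (cubic, ascending
#'   powers), `fp_coefficients` (quadratic derivative), `T_min`, `T_max`,
#'   `domain`, `slope_set_value`.
#' @export
fit_log_frequency <- function(h, slope_set_value = -0.05) {
  stopifnot_uint8(h)
  counts <- tabulate(as.vector(h) + 1L, nbins = 256L)
  n_val <- (0:255)[counts > 0]
  k <- counts[counts > 0]
  if (length(n_val) < 4L) {
    stop(
      "cubic log-frequency fit needs >= 4 populated bins, got ",
      length(n_val),
      call. = FALSE
    )
  }
  fit <- stats::lm(y ~ n + I(n^2) + I(n^3),
    data = data.frame(n = n_val, y = log10(k))
  )
  cf <- unname(stats::coef(fit)) # c0, c1, c2, c3
  fp <- c(cf[2], 2 * cf[3], 3 * cf[4]) # derivative coefficients
  # interval where fp(n) > slope_set_value, intersected with the
  # populated range; its ends are T_min and T_max
  dom <- range(n_val)
  fp_at <- function(n) fp[1] + fp[2] * n + fp[3] * n^2
  a <- fp[3]
  b <- fp[2]
  cc <- fp[1] - slope_set_value
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  grid <- sort(unique(c(dom, pmin(pmax(roots, dom[1]), dom[2]))))
  above <- vapply(grid, function(x) fp_at(x) > slope_set_value, logical(1))
  mids <- (grid[-length(grid)] + grid[-1]) / 2
  seg_above <- vapply(mids, function(x) fp_at(x) > slope_set_value, logical(1))
  if (!any(seg_above)) {
    stop(
      "log-frequency fit: the fitted slope never exceeds ",
      slope_set_value, " inside the populated range [", dom[1], ", ",
      dom[2], "]; consider relaxing `slope_set_value`",
      call. = FALSE
    )
  }
  lo <- grid[min(which(seg_above))]
  hi <- grid[max(which(seg_above)) + 1L]
  roots <- c(lo, hi)
  if (roots[1] >= roots[2]) {
    stop("log-frequency fit: degenerate slope interval", call. = FALSE)
  }
  structure(
    list(
      coefficients = cf, fp_coefficients = fp,
      T_min = roots[1], T_max = roots[2],
      domain = dom, slope_set_value = slope_set_value
    ),
    class = "cubic_log_fit"
  )
}

#' Guess threshold from the log-frequency roots and the 2D Otsu value
#'
#' The weighted average `w1*T_min + w2*T_max + w3*T_otsu`. The 2D Otsu
#' method is known to overestimate the average-grayscale threshold, so the
#' default weights (0.6, 0.2, 0.2) favor the smaller estimate `T_min`,
#' placing the starting guess between `T_min` and `T_max`.
#'
#' @param T_min,T_max Roots of the cubic log-frequency fit.
#' @param T_otsu Average-grayscale threshold from [otsu_2d()].
#' @param weights Non-negative weights `(w1, w2, w3)`.
#' @return The guess threshold (scalar).
#' @examples
#' guess_threshold(20.11, 49.48, 38) # 29.562
#' @export
guess_threshold <- function(T_min, T_max, T_otsu,
                            weights = c(0.6, 0.2, 0.2)) {
  if (length(weights) != 3L || any(weights < 0)) {
    stop("`weights` must be three non-negative numbers", call. = FALSE)
  }
  weights[1] * T_min + weights[2] * T_max + weights[3] * T_otsu
}

#' Estimate the particle count by weighted-median thresholding
#'
#' The convergence anchor of the modified 2D Otsu: binarizes with the
#' weighted-median threshold, applies the same morphological
#' post-processing as the main pipeline (so the comparison is
#' like-for-like), and counts connected components.
#'
#' @param img uint8 grayscale matrix.
#' @param weight Weighted-median weight (default 4.5).
#' @param morphology A [morphology_settings()] list.
#' @param variant Weighted-median variant; the default
#'   `"median_plus_mad"` centers the threshold at the image median, which
#'   the anchor needs on images whose background plateau sits above
#'   `weight * MAD` (on background-subtracted images with median ~ 0 the
#'   two variants coincide).
#' @return Integer particle count.
#' @export
estimate_particle_count <- function(img, weight = 4.5,
                                    morphology = morphology_settings(),
                                    variant = "median_plus_mad") {
  stopifnot_uint8(img)
  if (min(img) == max(img)) {
    # a featureless field holds no particles; the literal threshold rule
    # (T = 0, all-ones mask) would count the frame itself as one
    return(0L)
  }
  wm <- weighted_median_threshold(img, weight = weight, variant = variant)
  mask <- apply_threshold(img, wm$S)
  mask <- postprocess_mask(mask, morphology)
  label_particles(mask, connectivity = morphology$connectivity)$n
}

#' Modified 2D Otsu threshold
#'
#' The grayscale threshold `S` is taken from [otsu_2d()] unchanged; the
#' average-grayscale threshold `T` is optimized iteratively. Starting from
#' the guess threshold (weighted average of `T_min`, `T_max`, `T_otsu`),
#' each iteration binarizes with `g >= S & h >= T`, post-processes,
#' counts particles `N_g`, and moves `T` by subtracting a tuning step
#' `alpha` proportional to the error `N_e - N_g` (clamped, minimum unit
#' magnitude), where `N_e` is the weighted-median count estimate. The
#' iteration stops when `N_g == N_e`, when `N_g` is unchanged for
#' `stall_limit` consecutive iterations, or at `max_iters`; without
#' convergence the best `T` seen (minimum `|N_e - N_g|`) is returned,
#' flagged non-converged. This correction counters the overestimation of
#' `T` by plain 2D Otsu, which deletes genuine aggregates.
#'
#' @param g uint8 grayscale matrix.
#' @param h uint8 average-grayscale matrix.
#' @param weight Weighted-median weight for the `N_e` estimate.
#' @param wm_variant Weighted-median variant for the `N_e` estimate (see
#'   [estimate_particle_count()]).
#' @param weights Guess-threshold weights `(w1, w2, w3)`.
#' @param slope_set_value Target slope for [fit_log_frequency()].
#' @param morphology [morphology_settings()] applied identically to the
#'   `N_e` estimate and to each iteration's mask.
#' @param eta Proportional gain of the alpha rule (default 0.5).
#' @param alpha_max Clamp on `|alpha|` (default 8 gray levels).
#' @param stall_limit Consecutive unchanged `N_g` before stopping.
#' @param max_iters Iteration cap.
#' @param fallback `"error"` (default): propagate a log-frequency fit
#'   failure; `"otsu_t"`: start the iteration at `T_otsu` instead.
#' @return A `threshold_result` with `S`, `T`, and diagnostics including
#'   `T_otsu`, `T_min`, `T_max`, `T_guess`, `N_e`, `iterations`,
#'   `converged`, and the full `trajectory` tibble
#'   (iteration, T, N_g, error, alpha).
#' @export
modified_otsu_2d <- function(g, h, weight = 4.5,
                             wm_variant = "median_plus_mad",
                             weights = c(0.6, 0.2, 0.2),
                             slope_set_value = -0.05,
                             morphology = morphology_settings(),
                             eta = 0.5, alpha_max = 8,
                             stall_limit = 3, max_iters = 50,
                             fallback = c("error", "otsu_t")) {
  fallback <- match.arg(fallback)
  base <- otsu_2d(g, h)
  S <- base$S
  T_otsu <- base$T
  L <- base$diagnostics$L
  fit <- tryCatch(fit_log_frequency(h, slope_set_value), error = identity)
  if (inherits(fit, "error")) {
    if (fallback == "error") stop(fit)
    T_min <- T_max <- NA_real_
    T_guess <- T_otsu
  } else {
    T_min <- fit$T_min
    T_max <- fit$T_max
    T_guess <- guess_threshold(T_min, T_max, T_otsu, weights)
  }
  N_e <- estimate_particle_count(
    g,
    weight = weight, morphology = morphology, variant = wm_variant
  )

  count_at <- function(T) {
    mask <- apply_threshold_2d(g, h, S, T)
    mask <- postprocess_mask(mask, morphology)
    label_particles(mask, connectivity = morphology$connectivity)$n
  }

  T_cur <- T_guess
  traj <- vector("list", max_iters)
  best_T <- NA_real_
  best_err <- Inf
  stall <- 0L
  prev_ng <- NA_integer_
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    N_g <- count_at(T_cur)
    e <- N_e - N_g
    # ties in |error| resolve to the smallest T: the method exists to
    # counter T overestimation, so among equally count-consistent
    # thresholds the most size-retentive one is returned
    if (abs(e) < best_err || (abs(e) == best_err && T_cur < best_T)) {
      best_err <- abs(e)
      best_T <- T_cur
    }
    alpha <- if (e == 0) 0 else sign(e) * max(min(abs(eta * e), alpha_max), 1)
    traj[[it]] <- tibble::tibble(
      iteration = it, T = T_cur, N_g = N_g, error = e, alpha = alpha
    )
    if (e == 0) {
      converged <- TRUE
      break
    }
    if (!is.na(prev_ng) && N_g == prev_ng) stall <- stall + 1L else stall <- 0L
    prev_ng <- N_g
    if (stall >= stall_limit) break
    T_cur <- min(max(round_half_away(T_cur - alpha), 1), L)
  }
  trajectory <- dplyr::bind_rows(traj[seq_len(it)])
  new_threshold_result(
    "modified_otsu2d",
    S = S, T = best_T,
    diagnostics = list(
      T_otsu = T_otsu, T_min = T_min, T_max = T_max, T_guess = T_guess,
      N_e = N_e, N_g = trajectory$N_g[which.min(abs(trajectory$error))],
      iterations = it, converged = converged, trajectory = trajectory, L = L
    )
  )
}
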