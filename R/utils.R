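# Internal pixel-grid helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_away <- function(x) {
  # round-half-away-from-zero: bit-stable across platforms, unlike round()
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
#' @noRd
stopifnot_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`", arg, "` must be a numeric matrix (grayscale image)", call. = FALSE)
  }
  invisible(img)
}

#' @keywords internal
#' @noRd
stopifnot_uint8 <- function(img, arg = "img") {
  stopifnot_gray(img, arg)
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != floor(img))) {
    stop("`", arg, "` must contain integer values in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

#' @keywords internal
#' @noRd
stopifnot_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("`", arg, "` must be a binary {0,1} matrix", call. = FALSE)
  }
  invisible(mask)
}

# Shift a matrix by (dr, dc); vacated cells filled per `pad`:
# "replicate" repeats the edge row/column, otherwise a constant.
#' @keywords internal
#' @noRd
shift_mat <- function(m, dr, dc, pad = "replicate") {
  j <- nrow(m)
  k <- ncol(m)
  ri <- seq_len(j) - dr
  ci <- seq_len(k) - dc
  if (identical(pad, "replicate")) {
    ri <- pmin(pmax(ri, 1L), j)
    ci <- pmin(pmax(ci, 1L), k)
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(as.numeric(pad), j, k)
    rok <- ri >= 1L & ri <= j
    cok <- ci >= 1L & ci <= k
    out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
    out
  }
}

# Offsets of the n x n neighborhood centred on a pixel.
#' @keywords internal
#' @noRd
window_offsets <- function(n) {
  h <- (n - 1L) / 2L
  expand.grid(dr = -h:h, dc = -h:h)
}

#' @keywords internal
#' @noRd
check_odd_window <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n %% 2 == 0) {
    stop("window size `n` must be an odd integer >= 1", call. = FALSE)
  }
  as.integer(n)
}

# Elementwise k-th order statistic across the columns of `cols` (a list of
# equal-length vectors), by an exchange network: O(m^2) pmin/pmax passes,
# fully vectorized over pixels.
#' @keywords internal
#' @noRd
elementwise_median <- function(cols) {
  m <- length(cols)
  for (i in seq_len(m - 1L)) {
    for (jj in seq_len(m - i)) {
      a <- cols[[jj]]
      b <- cols[[jj + 1L]]
      cols[[jj]] <- pmin(a, b)
      cols[[jj + 1L]] <- pmax(a, b)
    }
  }
  cols[[(m + 1L) / 2L]]
}
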