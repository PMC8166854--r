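# Post-threshold binary cleanup: clean (remove isolated pixels), fill
# (interior holes), close (dilate-then-erode with a 3x3 square), and a
# pixel-count size filter. Order is pinned: clean -> fill -> close ->
# size_filter.

#' Morphology settings
#'
#' @param clean,fill,close Logical flags for the three operations.
#' @param min_pixels Size threshold: components with fewer pixels are
#'   removed (default 20; at 4x this corresponds to ~142 um^2, at 10x to
#'   ~21.7 um^2). Components with exactly `min_pixels` are kept.
#' @param connectivity 4 or 8 (default) for component labeling.
#' @return A `morphology_settings` list.
#' @export
morphology_settings <- function(clean = TRUE, fill = TRUE, close = TRUE,
                                min_pixels = 20, connectivity = 8) {
  stopifnot(min_pixels >= 0, connectivity %in% c(4, 8))
  structure(
    list(
      clean = isTRUE(clean), fill = isTRUE(fill), close = isTRUE(close),
      min_pixels = as.integer(min_pixels),
      connectivity = as.integer(connectivity)
    ),
    class = "morphology_settings"
  )
}

#' Remove isolated foreground pixels
#'
#' Any 1-pixel whose eight neighbors are all 0 becomes 0; everything else
#' is unchanged. Never adds foreground.
#'
#' @param mask Binary \{0,1\} matrix.
#' @return Binary matrix.
#' @export
mask_clean <- function(mask) {
  stopifnot_mask(mask)
  off <- window_offsets(3)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  nb <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    nb <- nb + shift_mat(mask, off$dr[i], off$dc[i], pad = 0)
  }
  mask * ((mask == 0) | (nb > 0))
}

#' Fill interior holes
#'
#' Background regions not 4-connected to the image border (topological
#' holes) become foreground. Never removes foreground.
#'
#' @param mask Binary \{0,1\} matrix.
#' @return Binary matrix.
#' @export
mask_fill <- function(mask) {
  stopifnot_mask(mask)
  bg <- 1 - mask
  lab <- label_particles(bg, connectivity = 4)
  if (lab$n == 0L) {
    return(mask)
  }
  j <- nrow(mask)
  k <- ncol(mask)
  border_labels <- unique(c(
    lab$labels[1, ], lab$labels[j, ], lab$labels[, 1], lab$labels[, k]
  ))
  border_labels <- border_labels[border_labels > 0]
  hole <- lab$labels > 0 & !(lab$labels %in% border_labels)
  out <- mask
  out[hole] <- 1
  out
}

#' @keywords internal
#' @noRd
dilate3 <- function(mask) {
  off <- window_offsets(3)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- pmax(out, shift_mat(mask, off$dr[i], off$dc[i], pad = 0))
  }
  out
}

#' @keywords internal
#' @noRd
erode3 <- function(mask) {
  off <- window_offsets(3)
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- pmin(out, shift_mat(mask, off$dr[i], off$dc[i], pad = 0))
  }
  out
}

#' Morphological closing
#'
#' Dilation followed by erosion with a 3x3 square structuring element:
#' bridges 1-pixel gaps and smooths ragged particle outlines without
#' shrinking them. Computed on a zero-padded canvas so the result equals
#' the closing of the mask embedded in an infinite zero plane (no border
#' growth artifacts). Idempotent; never removes foreground.
#'
#' @param mask Binary \{0,1\} matrix.
#' @return Binary matrix.
#' @export
mask_close <- function(mask) {
  stopifnot_mask(mask)
  j <- nrow(mask)
  k <- ncol(mask)
  canvas <- matrix(0, j + 4L, k + 4L)
  canvas[2L + seq_len(j), 2L + seq_len(k)] <- mask
  closed <- erode3(dilate3(canvas))
  closed[2L + seq_len(j), 2L + seq_len(k), drop = FALSE]
}

#' Remove small connected components
#'
#' Components with fewer than `min_pixels` pixels are deleted; components
#' with `min_pixels` or more are kept intact. This is the "size threshold"
#' that discards residual noise specks after thresholding.
#'
#' @param mask Binary \{0,1\} matrix.
#' @param min_pixels Minimum surviving component size (default 20).
#' @param connectivity 4 or 8 (default).
#' @return Binary matrix.
#' @export
size_filter <- function(mask, min_pixels = 20, connectivity = 8) {
  stopifnot_mask(mask)
  if (min_pixels <= 1) {
    return(mask)
  }
  lab <- label_particles(mask, connectivity = connectivity)
  if (lab$n == 0L) {
    return(mask)
  }
  sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
  keep <- which(sizes >= min_pixels)
  out <- mask
  out[lab$labels > 0 & !(lab$labels %in% keep)] <- 0
  out
}

#' Apply the full morphology chain
#'
#' Runs the enabled operations in the fixed order clean -> fill -> close
#' -> size filter.
#'
#' @param mask Binary \{0,1\} matrix.
#' @param settings A [morphology_settings()] list.
#' @return Binary matrix.
#' @export
postprocess_mask <- function(mask, settings = morphology_settings()) {
  stopifnot_mask(mask)
  if (settings$clean) mask <- mask_clean(mask)
  if (settings$fill) mask <- mask_fill(mask)
  if (settings$close) mask <- mask_close(mask)
  size_filter(mask,
    min_pixels = settings$min_pixels,
    connectivity = settings$connectivity
  )
}
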