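#' Load a microscope image as an RGB array
#'
#' Reads a TIFF, PNG or JPEG file and returns a `J x K x 3` numeric array of
#' channel intensities on the 0--255 scale (R, G, B along the third
#' dimension). Grayscale files are replicated across the three channels with
#' a warning, so that downstream green-channel extraction still works.
#'
#' @param path Path to a TIFF, PNG or JPEG file.
#' @return A `J x K x 3` array with values in `[0, 255]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(0, 2, 2), f)
#' dim(load_image(f))
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '.", ext, "' (use TIFF, PNG or JPEG)",
      call. = FALSE
    )
  )
  # readers return intensities on [0,1]; rescale to the 0-255 working scale
  px <- px * 255
  if (length(dim(px)) == 2L) {
    warning("grayscale input replicated across R, G, B channels: ", path)
    px <- array(px, dim = c(dim(px), 3L))
  } else if (dim(px)[3] > 3L) {
    px <- px[, , 1:3, drop = FALSE] # drop alpha
  } else if (dim(px)[3] == 2L) {
    stop("cannot interpret 2-channel image: ", path, call. = FALSE)
  }
  px
}

#' Extract the green channel
#'
#' FITC-tagged aggregates emit green, so only the green channel (the second
#' of R, G, B) carries signal; red and blue are discarded.
#'
#' @param img A `J x K x 3` RGB array on the 0--255 scale.
#' @return An integer-valued grayscale matrix (uint8 scale).
#' @export
extract_green <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 2L) {
    stop("`img` must be a J x K x 3 RGB array", call. = FALSE)
  }
  g <- array(img[, , 2L], dim = dim(img)[1:2]) # keep 1-row/col matrices 2-D
  round_half_away(pmin(pmax(g, 0), 255))
}

#' Quantize a grayscale image to the 0--255 working scale
#'
#' Linearly rescales `[min, max]` to `[0, 255]` and rounds half away from
#' zero. A constant image maps to all zeros (degenerate range). Thresholding
#' histograms operate on integer pixel values, so this is applied once after
#' the float-valued denoising stages.
#'
#' @param img A finite-valued grayscale matrix.
#' @return An integer-valued matrix with values in `[0, 255]`.
#' @export
to_uint8 <- function(img) {
  stopifnot_gray(img)
  if (!all(is.finite(img))) {
    stop("`img` contains non-finite values", call. = FALSE)
  }
  lo <- min(img)
  hi <- max(img)
  if (hi == lo) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  round_half_away((img - lo) / (hi - lo) * 255)
}

#' Magnification scale registry
#'
#' Maps a magnification label to the physical pixel size. The built-in
#' registry carries the widefield settings used for aggregate imaging:
#' 4x -> 2.667 um/pixel and 10x -> 1.0416 um/pixel. Pixels are square.
#'
#' @param name Magnification label, e.g. `"4x"`.
#' @param um_per_pixel Optional explicit pixel size in micrometres,
#'   required for labels not in the registry.
#' @return A `magnification_scale` object (list with `name`,
#'   `um_per_pixel`).
#' @examples
#' scale_for("4x")$um_per_pixel
#' @export
scale_for <- function(name, um_per_pixel = NULL) {
  registry <- c("4x" = 2.667, "10x" = 1.0416)
  if (is.null(um_per_pixel)) {
    if (!name %in% names(registry)) {
      stop(
        "unknown magnification '", name,
        "'; supply `um_per_pixel` explicitly", call. = FALSE
      )
    }
    um_per_pixel <- unname(registry[[name]])
  }
  if (!is.numeric(um_per_pixel) || um_per_pixel <= 0) {
    stop("`um_per_pixel` must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, um_per_pixel = um_per_pixel),
    class = "magnification_scale"
  )
}

#' @export
print.magnification_scale <- function(x, ...) {
  cat(
    "<magnification_scale> ", x$name, ": ",
    x$um_per_pixel, " um/pixel\n",
    sep = ""
  )
  invisible(x)
}

#' Write a grayscale image or binary mask to PNG/TIFF
#'
#' @param img Numeric matrix; values are rescaled from `[0, max]` of the
#'   declared `scale` to `[0, 1]` for the writer.
#' @param path Output path ending in .png, .tif or .tiff.
#' @param scale Maximum of the value scale (255 for uint8 images, 1 for
#'   binary masks).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, scale = 255) {
  stopifnot_gray(img)
  px <- pmin(pmax(img / scale, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}
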