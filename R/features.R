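# Particle labeling and morphometrics: area, perimeter, circularity,
# equivalent diameter/radius, and 10-um size-distribution binning.

#' Label connected components
#'
#' Assigns each connected set of foreground pixels a distinct positive
#' integer; background stays 0. Labels are ordered by the first
#' (column-major) pixel of each component, so the labeling is
#' deterministic.
#'
#' @param mask Binary \{0,1\} matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   default, matching the usual `bwlabel` semantics).
#' @return A list with `labels` (integer matrix) and `n` (component
#'   count).
#' @export
label_particles <- function(mask, connectivity = 8) {
  stopifnot_mask(mask)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  j <- nrow(mask)
  k <- ncol(mask)
  fg <- which(mask == 1)
  labels <- matrix(0L, j, k)
  if (length(fg) == 0L) {
    return(list(labels = labels, n = 0L))
  }
  # vertex id for every pixel (NA off the foreground)
  vid <- rep(NA_integer_, j * k)
  vid[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  }
  edges <- integer(0)
  for (o in offs) {
    dr <- o[1]
    dc <- o[2]
    rows <- seq_len(j)
    cols <- seq_len(k)
    r1 <- rows[rows + dr >= 1L & rows + dr <= j]
    c1 <- cols[cols + dc >= 1L & cols + dc <= k]
    if (length(r1) == 0 || length(c1) == 0) next
    # as.vector: a 2-column index matrix would trigger coordinate indexing
    a <- as.vector(outer(r1, (c1 - 1L) * j, `+`)) # linear index of (r, c)
    b <- as.vector(outer(r1 + dr, (c1 + dc - 1L) * j, `+`))
    both <- mask[a] == 1 & mask[b] == 1
    if (any(both)) {
      edges <- c(edges, rbind(vid[a[both]], vid[b[both]]))
    }
  }
  gph <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(gph)$membership
  # relabel in order of first appearance along column-major pixel order
  first_seen <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first_seen]] <- seq_len(sum(first_seen))
  labels[fg] <- remap[memb]
  list(labels = labels, n = max(remap))
}

#' Particle area in square micrometres
#'
#' Pixel count times the physical pixel area (`l * b`, square pixels).
#'
#' @param n_pixels Number of pixels in the particle.
#' @param scale A [scale_for()] magnification scale.
#' @return Area in um^2.
#' @examples
#' particle_area(20, scale_for("4x")) # ~142 um^2
#' @export
particle_area <- function(n_pixels, scale) {
  stopifnot(inherits(scale, "magnification_scale"))
  n_pixels * scale$um_per_pixel^2
}

#' Circularity
#'
#' `4 * pi * A / P^2`: 1 for a perfect circle, smaller for irregular
#' shapes.
#'
#' @param area_um2 Particle area.
#' @param perimeter_um Particle perimeter (same length unit).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(perimeter_um <= 0)) {
    stop("perimeter must be > 0", call. = FALSE)
  }
  4 * pi * area_um2 / perimeter_um^2
}

#' Equivalent circle radius and diameter
#'
#' The circle with the particle's area has diameter `sqrt(4 A / pi)`;
#' the radius `sqrt(A / pi)` is what size distributions are binned on.
#'
#' @param area_um2 Particle area in um^2 (vectorized).
#' @return Radius in um; see also [equivalent_diameter()].
#' @examples
#' equivalent_radius(184.94) # 7.67 um
#' @export
equivalent_radius <- function(area_um2) {
  stopifnot(all(area_um2 >= 0))
  sqrt(area_um2 / pi)
}

#' @rdname equivalent_radius
#' @export
equivalent_diameter <- function(area_um2) {
  2 * equivalent_radius(area_um2)
}

# Border-pixel perimeter estimator: border = mask minus its 4-neighbor
# erosion; each border pixel is classified by its border neighborhood via
# the kernel [10 2 10; 2 1 2; 10 2 10] and weighted 1 (straight edge),
# sqrt(2) (diagonal step) or (1+sqrt(2))/2 (corner). Returns pixels.
#' @keywords internal
#' @noRd
perimeter_pixels <- function(mask) {
  n_px <- sum(mask)
  if (n_px == 0) {
    return(0)
  }
  er <- matrix(1, nrow(mask), ncol(mask))
  for (o in list(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    er <- pmin(er, shift_mat(mask, o[1], o[2], pad = 0))
  }
  border <- mask - er
  if (sum(border) == 0) border <- mask # tiny component: all border
  kernel <- rbind(c(10, 2, 10), c(2, 1, 2), c(10, 2, 10))
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1) {
    for (dc in -1:1) {
      w <- kernel[dr + 2, dc + 2]
      acc <- acc + w * shift_mat(border, dr, dc, pad = 0)
    }
  }
  codes <- acc[border == 1]
  weights <- numeric(50)
  weights[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  weights[c(21, 33) + 1] <- sqrt(2)
  weights[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  p <- sum(weights[pmin(codes, 49) + 1])
  if (p == 0) {
    # isolated single pixel (or degenerate dot cluster): unit-square
    # boundary per pixel
    p <- 4 * sum(border)
  }
  p
}

#' Perimeter of one labeled component in micrometres
#'
#' Uses a weighted boundary-step estimator (straight steps weight 1,
#' diagonal steps `sqrt(2)`, corners `(1+sqrt(2))/2`), which approximates
#' the perimeter of the underlying smooth object far better than raw edge
#' counting, then multiplies by the pixel size. An isolated single pixel
#' is assigned the unit-square boundary (4 pixels).
#'
#' @param component_mask Binary matrix containing a single particle.
#' @param scale A [scale_for()] magnification scale.
#' @return Perimeter in um.
#' @export
perimeter_um <- function(component_mask, scale) {
  stopifnot_mask(component_mask)
  stopifnot(inherits(scale, "magnification_scale"))
  if (sum(component_mask) == 0) {
    stop("component is empty", call. = FALSE)
  }
  perimeter_pixels(component_mask) * scale$um_per_pixel
}

#' Per-particle morphometrics table
#'
#' Labels the mask and computes, for every particle: pixel count, area
#' (um^2), perimeter (um), circularity, equivalent diameter and radius
#' (um), and the centroid in pixel coordinates (1-based row/col).
#'
#' @param mask Binary \{0,1\} matrix (post-morphology).
#' @param scale A [scale_for()] magnification scale.
#' @param connectivity 4 or 8 (default).
#' @return A tibble with one row per particle.
#' @export
particle_features <- function(mask, scale, connectivity = 8) {
  stopifnot_mask(mask)
  stopifnot(inherits(scale, "magnification_scale"))
  lab <- label_particles(mask, connectivity = connectivity)
  empty <- tibble::tibble(
    label = integer(), n_pixels = integer(), area_um2 = numeric(),
    perimeter_um = numeric(), circularity = numeric(),
    eq_diameter_um = numeric(), eq_radius_um = numeric(),
    centroid_row = numeric(), centroid_col = numeric()
  )
  if (lab$n == 0L) {
    return(empty)
  }
  j <- nrow(mask)
  purrr::map_dfr(seq_len(lab$n), function(id) {
    idx <- which(lab$labels == id)
    rows <- (idx - 1L) %% j + 1L
    cols <- (idx - 1L) %/% j + 1L
    comp <- matrix(0, j, ncol(mask))
    comp[idx] <- 1
    n_px <- length(idx)
    a <- particle_area(n_px, scale)
    p <- perimeter_um(comp, scale)
    tibble::tibble(
      label = id, n_pixels = n_px, area_um2 = a, perimeter_um = p,
      circularity = circularity(a, p),
      eq_diameter_um = equivalent_diameter(a),
      eq_radius_um = equivalent_radius(a),
      centroid_row = mean(rows), centroid_col = mean(cols)
    )
  })
}

#' Bin particle radii into a size distribution
#'
#' Equivalent radii are sorted ascending and counted into left-closed
#' right-open bins of `bin_width_um` starting at 0; radii of 100 um and
#' above go into a single overflow bin.
#'
#' @param records Per-particle tibble from [particle_features()] (or any
#'   data frame with an `eq_radius_um` column). May be empty.
#' @param bin_width_um Bin width in um (default 10).
#' @param overflow_um Lower edge of the open overflow bin (default 100).
#' @return A `size_distribution` tibble: `bin_lo`, `bin_hi` (`Inf` for
#'   the overflow bin), `count`; total particles in
#'   `attr(, "total")`.
#' @export
size_distribution <- function(records, bin_width_um = 10,
                              overflow_um = 100) {
  stopifnot(bin_width_um > 0, overflow_um > 0)
  radii <- sort(records$eq_radius_um %||% numeric(0))
  edges_lo <- seq(0, overflow_um - bin_width_um, by = bin_width_um)
  bin_lo <- c(edges_lo, overflow_um)
  bin_hi <- c(edges_lo + bin_width_um, Inf)
  counts <- vapply(
    seq_along(bin_lo),
    function(i) sum(radii >= bin_lo[i] & radii < bin_hi[i]),
    integer(1)
  )
  out <- tibble::tibble(bin_lo = bin_lo, bin_hi = bin_hi, count = counts)
  attr(out, "total") <- length(radii)
  attr(out, "bin_width_um") <- bin_width_um
  class(out) <- c("size_distribution", class(out))
  out
}

#' Compare two size distributions
#'
#' Side-by-side counts per bin with deltas (`b - a`), e.g. to contrast
#' aggregate growth between two incubation time points.
#'
#' @param dist_a,dist_b `size_distribution` tibbles with identical bin
#'   edges.
#' @return A tibble: `bin_lo`, `bin_hi`, `count_a`, `count_b`, `delta`.
#' @export
compare_distributions <- function(dist_a, dist_b) {
  if (!identical(dist_a$bin_lo, dist_b$bin_lo) ||
    !identical(dist_a$bin_hi, dist_b$bin_hi)) {
    stop("distributions have different bin edges", call. = FALSE)
  }
  tibble::tibble(
    bin_lo = dist_a$bin_lo, bin_hi = dist_a$bin_hi,
    count_a = dist_a$count, count_b = dist_b$count,
    delta = dist_b$count - dist_a$count
  )
}
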