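# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold result
#'
#' One row per threshold parameter or diagnostic scalar (`S`, `T`,
#' `T_otsu`, `T_min`, `T_max`, `T_guess`, `N_e`, ...).
#'
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `value`.
#' @export
tidy.threshold_result <- function(x, ...) {
  dg <- x$diagnostics
  scalars <- dg[vapply(
    dg, function(v) is.numeric(v) && length(v) == 1, logical(1)
  )]
  tibble::tibble(
    term = c("S", if (!is.na(x$T)) "T", names(scalars)),
    value = c(x$S, if (!is.na(x$T)) x$T, unlist(scalars, use.names = FALSE))
  )
}

#' Glance at a threshold result
#'
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `S`, `T`, `iterations`,
#'   `converged`.
#' @export
glance.threshold_result <- function(x, ...) {
  dg <- x$diagnostics
  tibble::tibble(
    method = x$method, S = x$S, T = x$T,
    iterations = dg$iterations %||% NA_integer_,
    converged = dg$converged %||% NA
  )
}

#' Tidy an image result
#'
#' Returns the per-particle morphometrics table.
#'
#' @param x An `image_result` from [analyze_image()].
#' @param ... Unused.
#' @return The particle tibble.
#' @export
tidy.image_result <- function(x, ...) {
  x$particles
}

#' Glance at an image result
#'
#' @param x An `image_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `S`, `T`, `n_particles`,
#'   `total_area_um2`, `median_radius_um`.
#' @export
glance.image_result <- function(x, ...) {
  tibble::tibble(
    method = x$threshold$method, S = x$threshold$S, T = x$threshold$T,
    n_particles = x$n_particles,
    total_area_um2 = sum(x$particles$area_um2),
    median_radius_um = if (x$n_particles) {
      stats::median(x$particles$eq_radius_um)
    } else {
      NA_real_
    }
  )
}

#' Tidy a run report
#'
#' Pooled per-particle records with their image of origin.
#'
#' @param x A `run_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The pooled particle tibble.
#' @export
tidy.run_report <- function(x, ...) {
  x$particles
}

#' Glance at a run report
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return A one-row tibble: image count, failures, pooled particle
#'   total, radius range.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$images),
    n_failed = nrow(x$failures),
    n_particles = attr(x$distribution, "total"),
    min_radius_um = if (nrow(x$particles)) min(x$particles$eq_radius_um) else NA_real_,
    max_radius_um = if (nrow(x$particles)) max(x$particles$eq_radius_um) else NA_real_
  )
}
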