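# End-to-end orchestration: green channel -> median filter -> TV
# denoising -> FFT background normalization -> uint8 -> thresholding ->
# morphology -> labeling -> morphometrics -> size distribution, per image
# and pooled over a batch.

#' Pipeline configuration
#'
#' All stage settings in one validated list. Every stage can be disabled
#' for ablation runs.
#'
#' @param magnification Label passed to [scale_for()] (default `"4x"`).
#' @param um_per_pixel Optional explicit pixel size for custom
#'   magnifications.
#' @param median_window Median filter window (odd; 0 or 1 disables).
#' @param tv A [tv_params()] list, or `NULL` to skip TV denoising.
#' @param background_cutoff FFT low-pass cutoff fraction of Nyquist;
#'   `NULL` skips background normalization.
#' @param background_mode `"divide"` or `"subtract"`.
#' @param threshold_method One of `"modified_otsu2d"` (default,
#'   recommended), `"otsu2d"`, `"otsu1d"`, `"weighted_median"`.
#' @param weight Weighted-median weight (default 4.5).
#' @param wm_variant Weighted-median variant used for the particle-count
#'   anchor and the `weighted_median` method: `"median_plus_mad"`
#'   (default, centered at the image median) or `"mad"` (the raw
#'   `weight * MAD` form, appropriate when the background median is ~0).
#' @param n_avg Average-grayscale neighborhood (odd, default 3).
#' @param slope_set_value Cubic-fit slope target (default -0.05).
#' @param guess_weights Guess-threshold weights (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param alpha_eta,alpha_max,stall_limit,threshold_max_iters Tuning-rule
#'   settings of [modified_otsu_2d()].
#' @param morphology A [morphology_settings()] list.
#' @param bin_width_um Size-distribution bin width (default 10).
#' @param min_signal_ratio Blank-field guard: after background
#'   estimation, the ratio image `g / background` has background pixels
#'   near 1 and genuine fluorescent particles several-fold higher. If its
#'   maximum divided by its median falls below this factor (default 3),
#'   the field is declared blank and an empty mask is returned instead of
#'   contrast-stretching pure noise. Set to 0 to disable.
#' @param min_images Warn when a batch has fewer images than this
#'   (single fields of view under-sample the aggregate population).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(magnification = "4x", um_per_pixel = NULL,
                            median_window = 3,
                            tv = tv_params(),
                            background_cutoff = 0.02,
                            background_mode = c("divide", "subtract"),
                            threshold_method = c(
                              "modified_otsu2d", "otsu2d", "otsu1d",
                              "weighted_median"
                            ),
                            weight = 4.5,
                            wm_variant = c("median_plus_mad", "mad"),
                            n_avg = 3,
                            slope_set_value = -0.05,
                            guess_weights = c(0.6, 0.2, 0.2),
                            alpha_eta = 0.5, alpha_max = 8,
                            stall_limit = 3, threshold_max_iters = 50,
                            morphology = morphology_settings(),
                            bin_width_um = 10,
                            min_signal_ratio = 3,
                            min_images = 20) {
  structure(
    list(
      scale = scale_for(magnification, um_per_pixel),
      median_window = median_window,
      tv = tv,
      background_cutoff = background_cutoff,
      background_mode = match.arg(background_mode),
      threshold_method = match.arg(threshold_method),
      weight = weight, wm_variant = match.arg(wm_variant),
      n_avg = n_avg,
      slope_set_value = slope_set_value,
      guess_weights = guess_weights,
      alpha_eta = alpha_eta, alpha_max = alpha_max,
      stall_limit = stall_limit,
      threshold_max_iters = threshold_max_iters,
      morphology = morphology,
      bin_width_um = bin_width_um,
      min_signal_ratio = min_signal_ratio,
      min_images = min_images
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments, with nested
#' blocks `tv:` (tolerance, max_iters, step_rule), `background:`
#' (cutoff_fraction, mode), `threshold:` (method, weight, n_avg,
#' slope_set_value, weights, alpha: eta/max/stall_limit/max_iters) and
#' `morphology:` (clean, fill, close, min_pixels, connectivity).
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- y$threshold %||% list()
  al <- thr$alpha %||% list()
  bg <- y$background %||% list()
  mo <- y$morphology %||% list()
  tvb <- y$tv %||% list()
  pipeline_config(
    magnification = y$magnification %||% "4x",
    um_per_pixel = y$um_per_pixel,
    median_window = y$median_window %||% 3,
    tv = tv_params(
      tolerance = tvb$tolerance %||% 0.005,
      max_iters = tvb$max_iters %||% 200,
      step_rule = tvb$step_rule %||% "line_search"
    ),
    background_cutoff = bg$cutoff_fraction %||% 0.02,
    background_mode = bg$mode %||% "divide",
    threshold_method = thr$method %||% "modified_otsu2d",
    weight = thr$weight %||% 4.5,
    wm_variant = thr$wm_variant %||% "median_plus_mad",
    n_avg = thr$n_avg %||% 3,
    slope_set_value = thr$slope_set_value %||% -0.05,
    guess_weights = unlist(thr$weights %||% c(0.6, 0.2, 0.2)),
    alpha_eta = al$eta %||% 0.5,
    alpha_max = al$max %||% 8,
    stall_limit = al$stall_limit %||% 3,
    threshold_max_iters = al$max_iters %||% 50,
    morphology = morphology_settings(
      clean = mo$clean %||% TRUE, fill = mo$fill %||% TRUE,
      close = mo$close %||% TRUE, min_pixels = mo$min_pixels %||% 20,
      connectivity = mo$connectivity %||% 8
    ),
    bin_width_um = y$bin_width_um %||% 10,
    min_signal_ratio = y$min_signal_ratio %||% 3,
    min_images = y$min_images %||% 20
  )
}

#' Analyze one image through the full pipeline
#'
#' Accepts a file path, an RGB array, a grayscale matrix, or a
#' `synthetic_scene`, and runs green-channel extraction, the denoising
#' chain, the configured thresholding method, morphology and
#' morphometrics.
#'
#' @param img Input image (see Details above).
#' @param config A [pipeline_config()] list.
#' @return An `image_result` list: `mask` (final binary mask),
#'   `threshold` (`threshold_result`), `particles` (tibble),
#'   `distribution` (`size_distribution`), `n_particles`, `denoised`
#'   (uint8 matrix entering thresholding), `tv_trace`.
#' @export
analyze_image <- function(img, config = pipeline_config()) {
  if (is.character(img)) img <- load_image(img)
  if (inherits(img, "synthetic_scene")) img <- img$image
  g <- if (is.matrix(img)) {
    stopifnot_gray(img)
    round_half_away(pmin(pmax(img, 0), 255))
  } else {
    extract_green(img)
  }
  if (!is.null(config$median_window) && config$median_window >= 3) {
    g <- median_filter(g, config$median_window)
  }
  tv_trace <- NULL
  if (!is.null(config$tv)) {
    dn <- tv_denoise(g, config$tv)
    g <- dn$image
    tv_trace <- dn$trace
  }
  blank_field <- FALSE
  signal_ratio <- NA_real_
  if (!is.null(config$background_cutoff)) {
    bg <- estimate_background(
      g, config$background_cutoff, config$background_mode,
      clip_objects = TRUE
    )
    # blank-field guard: to_uint8 is a pure contrast stretch, so a field
    # with no absolute signal above its own background must be rejected
    # before stretching, on the ratio scale where background ~ 1
    b <- pmax(bg$background, 1e-6 * max(abs(bg$background), 1))
    ratio <- g / b
    signal_ratio <- max(ratio) / stats::median(ratio)
    blank_field <- is.finite(signal_ratio) &&
      signal_ratio < config$min_signal_ratio
    g <- normalize_background(g, bg)
  } else {
    g <- to_uint8(g)
  }
  if (blank_field) {
    mask <- matrix(0, nrow(g), ncol(g))
    thr <- new_threshold_result(
      config$threshold_method,
      S = Inf,
      diagnostics = list(blank_field = TRUE, signal_ratio = signal_ratio)
    )
    particles <- particle_features(
      mask, config$scale,
      connectivity = config$morphology$connectivity
    )
    return(structure(
      list(
        mask = mask, threshold = thr, particles = particles,
        distribution = size_distribution(particles, config$bin_width_um),
        n_particles = 0L, denoised = g, tv_trace = tv_trace
      ),
      class = "image_result"
    ))
  }
  thr <- switch(config$threshold_method,
    weighted_median = weighted_median_threshold(
      g, config$weight,
      variant = config$wm_variant
    ),
    otsu1d = otsu_1d(g),
    otsu2d = otsu_2d(g, average_grayscale(g, config$n_avg)),
    modified_otsu2d = modified_otsu_2d(
      g, average_grayscale(g, config$n_avg),
      weight = config$weight, wm_variant = config$wm_variant,
      weights = config$guess_weights,
      slope_set_value = config$slope_set_value,
      morphology = config$morphology,
      eta = config$alpha_eta, alpha_max = config$alpha_max,
      stall_limit = config$stall_limit,
      max_iters = config$threshold_max_iters,
      fallback = "otsu_t"
    )
  )
  mask <- if (is.na(thr$T)) {
    apply_threshold(g, thr$S)
  } else {
    apply_threshold_2d(g, average_grayscale(g, config$n_avg), thr$S, thr$T)
  }
  thr$diagnostics$signal_ratio <- signal_ratio
  mask <- postprocess_mask(mask, config$morphology)
  particles <- particle_features(
    mask, config$scale,
    connectivity = config$morphology$connectivity
  )
  structure(
    list(
      mask = mask, threshold = thr, particles = particles,
      distribution = size_distribution(particles, config$bin_width_um),
      n_particles = nrow(particles),
      denoised = g, tv_trace = tv_trace
    ),
    class = "image_result"
  )
}

#' @export
print.image_result <- function(x, ...) {
  cat(
    "<image_result> ", x$n_particles, " particle(s); threshold method ",
    x$threshold$method, " (S=", format(x$threshold$S),
    if (!is.na(x$threshold$T)) paste0(", T=", format(x$threshold$T)),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' Run the pipeline over a batch of images
#'
#' Processes each input independently, pools the per-particle records
#' into one column of sizes (sorted ascending), and bins the pooled
#' equivalent radii into the shared size distribution. A failing image is
#' recorded and skipped; the run errors only if every image fails.
#'
#' @param inputs A character vector of image paths, or a list of images /
#'   `synthetic_scene`s.
#' @param config A [pipeline_config()] list.
#' @param output_dir Optional directory; when given, per-image masks
#'   (PNG), a pooled per-particle CSV, and distribution +
#'   threshold-diagnostics JSON are written there.
#' @return A `run_report` list: `images` (per-image summary tibble),
#'   `particles` (pooled tibble with an `image` column),
#'   `distribution` (pooled `size_distribution`), `results` (list of
#'   `image_result`), `failures` (tibble), `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         output_dir = NULL) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (!is.list(inputs) || length(inputs) == 0) {
    stop("`inputs` must name at least one image", call. = FALSE)
  }
  if (length(inputs) < config$min_images) {
    warning(
      "only ", length(inputs), " image(s); >= ", config$min_images,
      " fields of view are recommended for a representative ",
      "size distribution"
    )
  }
  names_in <- names(inputs) %||% rep("", length(inputs))
  ids <- ifelse(
    nzchar(names_in), names_in,
    vapply(seq_along(inputs), function(i) {
      x <- inputs[[i]]
      if (is.character(x)) basename(x) else sprintf("image_%03d", i)
    }, character(1))
  )
  results <- vector("list", length(inputs))
  fail <- list()
  for (i in seq_along(inputs)) {
    res <- tryCatch(
      analyze_image(inputs[[i]], config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fail[[length(fail) + 1]] <- tibble::tibble(
        image = ids[i], message = conditionMessage(res)
      )
      results[i] <- list(NULL)
    } else {
      results[[i]] <- res
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    stop("all images failed; first error: ", fail[[1]]$message,
      call. = FALSE
    )
  }
  pooled <- purrr::map_dfr(which(ok), function(i) {
    dplyr::mutate(results[[i]]$particles, image = ids[i], .before = 1)
  })
  pooled <- dplyr::arrange(pooled, .data$area_um2)
  dist <- size_distribution(pooled, config$bin_width_um)
  images <- purrr::map_dfr(which(ok), function(i) {
    r <- results[[i]]
    tibble::tibble(
      image = ids[i], method = r$threshold$method,
      S = r$threshold$S, T = r$threshold$T,
      n_particles = r$n_particles
    )
  })
  report <- structure(
    list(
      images = images, particles = pooled, distribution = dist,
      results = results[ok],
      failures = if (length(fail)) {
        dplyr::bind_rows(fail)
      } else {
        tibble::tibble(image = character(), message = character())
      },
      config = config
    ),
    class = "run_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir, ids[ok])
  report
}

#' @keywords internal
#' @noRd
write_report <- function(report, output_dir, ids) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(report$results)) {
    write_image(
      report$results[[i]]$mask,
      file.path(output_dir, paste0(ids[i], "_mask.png")),
      scale = 1
    )
  }
  utils::write.csv(
    report$particles, file.path(output_dir, "particles.csv"),
    row.names = FALSE
  )
  thr <- purrr::map(report$results, function(r) {
    d <- r$threshold$diagnostics
    d$trajectory <- NULL
    c(list(method = r$threshold$method, S = r$threshold$S, T = r$threshold$T), d)
  })
  jsonlite::write_json(
    list(
      distribution = as.data.frame(dplyr::mutate(
        report$distribution,
        bin_hi = ifelse(is.infinite(.data$bin_hi), "Inf", .data$bin_hi)
      )),
      total = attr(report$distribution, "total"),
      thresholds = thr
    ),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(output_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(
    "<run_report> ", nrow(x$images), " image(s), ",
    attr(x$distribution, "total"), " particle(s) pooled\n",
    sep = ""
  )
  print(x$images)
  invisible(x)
}

#' Compare the pooled size distributions of two runs
#'
#' Delegates to [compare_distributions()] on the pooled distributions,
#' e.g. to contrast aggregate growth between incubation time points.
#'
#' @param report_a,report_b `run_report` objects with compatible bins.
#' @return A comparison tibble (see [compare_distributions()]).
#' @export
compare_timepoints <- function(report_a, report_b) {
  compare_distributions(report_a$distribution, report_b$distribution)
}
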