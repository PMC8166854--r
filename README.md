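# fluoragg

Detecting and sizing therapeutic-antibody aggregates in fluorescence
microscope images.

Therapeutic monoclonal antibodies form sub-visible (0.1–50 µm) and larger
aggregates under stress, and aggregate size distributions are a direct
immunogenicity concern. When the antibody is FITC-tagged, a widefield
fluorescence microscope shows aggregates as bright green blobs on a
noisy, unevenly illuminated background. `fluoragg` converts such frames
into per-particle morphometrics and pooled size distributions:

1. **Denoising** — green-channel extraction, median filtering, total-variation
   (TV) denoising by gradient descent with line search
   (`g ← g − τ ∇ TV(g)`, stop when ‖Δg‖/‖g‖ < 0.005), and illumination
   correction by FFT low-pass background estimation (divide or subtract).
2. **Thresholding** — weighted median (`T = w · median|g − median(g)|`,
   w = 4.5), 1D Otsu, 2D Otsu on the joint histogram of gray value *g*
   and 3×3 neighborhood mean *h* (maximizing tr σ_B(s, t)), and a
   **modified 2D Otsu** that keeps the 2D-Otsu grayscale threshold *S*
   but iteratively lowers the average-grayscale threshold *T* from
   `T_guess = 0.6·T_min + 0.2·T_max + 0.2·T_otsu` until the particle
   count matches a weighted-median estimate — countering the systematic
   overestimation of *T* that deletes genuine aggregates.
3. **Morphology** — clean → fill → close → 20-pixel size filter.
4. **Morphometrics** — per particle: area `A = N̂·l·b` (µm²), perimeter
   *P* (weighted boundary steps), circularity `4πA/P²`, equivalent
   diameter `√(4A/π)` and radius `√(A/π)`; size distributions binned in
   10-µm radius classes.

A seeded synthetic-scene generator (irregular blobs with exact truth
masks, illumination fields, Poisson + Gaussian noise, defocused
distractors) makes every stage testable without microscope data.

## Worked example

```r
library(fluoragg)

sc  <- generate_scene(
  scene_config(preset = "high_snr", dim = c(256, 256), n_particles = 6),
  seed = 42
)
res <- analyze_image(sc, pipeline_config(min_images = 1))
glance(res)
#> # A tibble: 1 × 6
#>   method              S     T n_particles total_area_um2 median_radius_um
#>   <chr>           <dbl> <dbl>       <int>          <dbl>            <dbl>
#> 1 modified_otsu2d    27  74.9           6         11153.             23.6
```

All six seeded particles are recovered. `S = 27` is the grayscale
threshold from 2D Otsu; the average-grayscale threshold converged at
`T = 74.9` (down from the plain 2D-Otsu value `T_otsu = 115`, which would
have eroded particle boundaries). Per particle:

```r
tidy(res)[, c("label", "n_pixels", "area_um2", "circularity", "eq_radius_um")]
#> # A tibble: 6 × 5
#>   label n_pixels area_um2 circularity eq_radius_um
#>   <int>    <int>    <dbl>       <dbl>        <dbl>
#> 1     1      177    1259.       0.998         20.0
#> 2     2      354    2518.       0.988         28.3
#> 3     3      469    3336.       0.942         32.6
#> 4     4       73     519.       1.09          12.9
#> 5     5      291    2070.       0.935         25.7
#> 6     6      204    1451.       0.968         21.5
```

Areas are in µm² at the 4× scale (2.667 µm/pixel); circularity ≈ 1 means
near-circular blobs; `autoplot(res$distribution)` plots the 10-µm-binned
radius histogram. Batches run through `run_pipeline()` (pooled
distributions, per-particle CSV, mask and JSON outputs) and two time
points are contrasted with `compare_timepoints()`. A thin command-line
front end with `process`, `fixtures` and `compare` subcommands lives at
`inst/cli/fluoragg.R`.

See `vignette("aggregate-imaging")` for the full methods account:
discretization and convergence of the TV descent, the background
estimator, the joint-histogram thresholds and the tuning rule, the
morphology conventions, the perimeter estimator, and what the synthetic
generator does and does not emulate.

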