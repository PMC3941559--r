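#' Render a synthetic video frame
#'
#' Draws the five markers of one respiratory phase as filled dark circles
#' of physical diameter 13 mm on a light background, at the subject's
#' ground-truth scale, with optional additive Gaussian pixel noise. Circle
#' edges are anti-aliased by analytic pixel coverage so measured diameters
#' match the nominal diameter to sub-pixel accuracy.
#'
#' Image rows grow downward (raster convention); the support-surface
#' baseline is a known row near the bottom of the raster, and marker
#' heights above it map to rows above it.
#'
#' @param truth A [kinematic_truth][make_kinematics].
#' @param phase `"expiration"` or `"inspiration"`.
#' @param subject The `subject_spec` the truth was built for (supplies
#'   `mm_per_px`).
#' @param noise_sd SD of additive Gaussian noise, in 8-bit gray levels
#'   (0-255 scale); 0 for a noiseless render.
#' @param rng_seed Integer seed for the noise; deterministic per seed.
#' @param margin_px Blank margin around the marker bounding box, pixels.
#' @return Object of class `rendered_frame`: list with `pixels` (numeric
#'   matrix in \[0, 1\], rows = image rows), `marker_px_diameter`
#'   (13 / mm_per_px), `phase`, `mm_per_px`, `baseline_y_px` (image row of
#'   the support surface) and `truth_px` (data frame of true marker pixel
#'   centers, for oracle checks).
#' @export
render_frame <- function(truth, phase = c("expiration", "inspiration"), subject,
                         noise_sd = 0, rng_seed = NULL, margin_px = 20) {
  phase <- match.arg(phase)
  if (!inherits(truth, "kinematic_truth")) stop_data("truth must be a kinematic_truth")
  ms <- if (phase == "expiration") truth$marker_exp else truth$marker_insp
  mmpx <- subject$mm_per_px
  r <- 13 / mmpx / 2                      # marker radius, px
  px_per_cm <- 10 / mmpx

  # disjointness of the drawn circles (1 px guard band)
  cx_cm <- ms$x_cm; cy_cm <- ms$y_cm
  d2 <- as.matrix(dist(cbind(cx_cm, cy_cm))) * px_per_cm
  if (any(d2[upper.tri(d2)] <= 2 * r + 2))
    stop_geometry("invalid configuration: markers too close to render disjoint circles")

  x0 <- margin_px + r + 1
  col_c <- x0 + (cx_cm - min(cx_cm)) * px_per_cm
  width <- ceiling(max(col_c) + r + margin_px)
  baseline_row <- ceiling(max(cy_cm) * px_per_cm + r + margin_px + 1)
  height <- baseline_row + 4              # a few rows of bed below the baseline
  row_c <- baseline_row - cy_cm * px_per_cm

  bg <- 0.90; fg <- 0.15
  img <- matrix(bg, nrow = height, ncol = width)
  for (k in 1:5) {
    rows <- max(1, floor(row_c[k] - r - 1)):min(height, ceiling(row_c[k] + r + 1))
    cols <- max(1, floor(col_c[k] - r - 1)):min(width, ceiling(col_c[k] + r + 1))
    dr <- outer(rows - row_c[k], cols - col_c[k], function(a, b) sqrt(a^2 + b^2))
    cov <- pmin(pmax(r + 0.5 - dr, 0), 1)  # analytic edge coverage
    img[rows, cols] <- pmin(img[rows, cols], bg - (bg - fg) * cov)
  }
  if (noise_sd > 0) {
    img <- with_rng(rng_seed, img + matrix(rnorm(length(img), 0, noise_sd / 255),
                                           nrow = height))
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(pixels = img, marker_px_diameter = 13 / mmpx, phase = phase,
                 mm_per_px = mmpx, baseline_y_px = baseline_row,
                 truth_px = data.frame(landmark = ms$landmark,
                                       x_px = col_c, y_px = row_c)),
            class = "rendered_frame")
}

#' @export
print.rendered_frame <- function(x, ...) {
  cat(sprintf("Rendered %s frame: %d x %d px, marker diameter %.1f px, baseline row %d\n",
              x$phase, nrow(x$pixels), ncol(x$pixels), x$marker_px_diameter,
              x$baseline_y_px))
  invisible(x)
}

#' Write a rendered frame as an 8-bit grayscale PNG
#'
#' @param frame A `rendered_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$pixels, target = path)
  invisible(path)
}
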