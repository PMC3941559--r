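#' Read an image frame as a grayscale matrix
#'
#' Reads PNG and TIFF through the png/tiff packages and other formats
#' (e.g. JPEG) through EBImage. Multi-channel images are reduced to their
#' first channel. Values are rescaled to \[0, 1\].
#'
#' @param path Image file path.
#' @return Numeric matrix, rows = image rows (y grows downward), values in
#'   \[0, 1\].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("frame not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    {
      e <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x (columns) first; transpose to row-major raster
      if (length(dim(e)) == 3) e <- e[, , 1]
      t(e)
    })
  if (length(dim(img)) == 3) img <- img[, , 1]
  img <- as.matrix(img)
  rng <- range(img)
  if (rng[2] > 1) img <- img / rng[2]
  img
}

as_pixel_matrix <- function(frame) {
  if (inherits(frame, "rendered_frame")) return(frame$pixels)
  if (is.character(frame) && length(frame) == 1) return(read_frame(frame))
  if (is.matrix(frame) && is.numeric(frame)) return(frame)
  stop_data("frame must be a rendered_frame, a numeric matrix, or a file path")
}

#' Detect circular adhesive markers in a frame
#'
#' Segments dark blobs by Otsu thresholding, labels connected components,
#' keeps sufficiently circular ones (circularity 4*pi*A/P^2 at least
#' `min_circularity`), and ranks candidates by circularity times area so
#' the `expected_n` full-size markers win over specks and partial blobs.
#' Centers are intensity-weighted centroids (weight = darkness relative to
#' the background), giving sub-pixel accuracy on anti-aliased markers;
#' the diameter is the equivalent-area circle diameter of the blob.
#'
#' @param frame A `rendered_frame`, numeric pixel matrix, or image path.
#' @param expected_n Number of markers to return (5 for the standard
#'   landmark protocol).
#' @param min_circularity Minimum blob circularity retained.
#' @param min_area_px Minimum blob area (speckle rejection), px.
#' @return Data frame of class `detected_markers`, one row per marker:
#'   `center_x`, `center_y` (px, 1-based pixel-center coordinates),
#'   `diameter` (px), `circularity`, ordered by descending score (ties:
#'   smaller `center_x` first). Detection failure (fewer than `expected_n`
#'   candidates) raises an error reporting the count found.
#' @export
detect_markers <- function(frame, expected_n = 5, min_circularity = 0.6,
                           min_area_px = 9) {
  m <- as_pixel_matrix(frame)
  img <- EBImage::Image(t(m))  # EBImage expects x (columns) first
  thr <- tryCatch(EBImage::otsu(img), error = function(e) NA_real_)
  if (!is.finite(thr) || min(m) >= thr || max(m) <= thr)
    stop_detection("marker detection failed: 0 candidate blobs found (blank or untextured frame)",
                   n_found = 0L)
  lab <- EBImage::bwlabel(img < thr)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(shp) || nrow(shp) == 0)
    stop_detection("marker detection failed: 0 candidate blobs found", n_found = 0L)

  labmat <- t(EBImage::imageData(lab))    # back to row-major
  bgval <- stats::median(m[labmat == 0])
  feats <- lapply(seq_len(nrow(shp)), function(i) {
    area_b <- shp[i, "s.area"]; per <- shp[i, "s.perimeter"]
    circ <- min(4 * pi * area_b / max(per, 1)^2, 1)
    idx <- which(labmat == i, arr.ind = TRUE)
    # sub-pixel area and centroid: partial edge-pixel coverage is encoded in
    # intensity, so weight each pixel in a slightly dilated bounding box by
    # its darkness relative to the local foreground/background levels
    fgval <- as.numeric(quantile(m[idx], 0.25))
    rr <- max(1, min(idx[, 1]) - 2):min(nrow(m), max(idx[, 1]) + 2)
    cc <- max(1, min(idx[, 2]) - 2):min(ncol(m), max(idx[, 2]) + 2)
    w <- pmin(pmax((bgval - m[rr, cc, drop = FALSE]) /
                     max(bgval - fgval, 1e-6), 0), 1)
    sw <- sum(w)
    if (sw <= 0) { w[] <- 1; sw <- length(w) }
    data.frame(center_x = sum(sweep(w, 2, cc, "*")) / sw,
               center_y = sum(sweep(w, 1, rr, "*")) / sw,
               diameter = 2 * sqrt(sw / pi),
               circularity = circ, area = area_b)
  })
  cand <- do.call(rbind, feats)
  cand <- cand[cand$area >= min_area_px & cand$circularity >= min_circularity, ,
               drop = FALSE]
  if (nrow(cand) < expected_n)
    stop_detection(sprintf("marker detection failed: %d candidate blobs found, %d expected",
                           nrow(cand), expected_n), n_found = nrow(cand))
  score <- cand$circularity * cand$area
  cand <- cand[order(-score, cand$center_x), , drop = FALSE]
  if (nrow(cand) > expected_n) {
    message(sprintf("detect_markers: %d candidates, discarding %d lowest-scoring",
                    nrow(cand), nrow(cand) - expected_n))
    cand <- cand[seq_len(expected_n), , drop = FALSE]
  }
  out <- cand[, c("center_x", "center_y", "diameter", "circularity")]
  rownames(out) <- NULL
  class(out) <- c("detected_markers", "data.frame")
  out
}

#' Calibrate the physical pixel scale from detected markers
#'
#' The adhesive markers have a known physical diameter (13 mm); the scale
#' is that diameter divided by the median detected marker diameter.
#'
#' @param markers A `detected_markers` data frame (or any data frame with
#'   a `diameter` column, px).
#' @param reference_diameter_mm Physical marker diameter, mm.
#' @return Object of class `calibration`: list with `mm_per_px` and
#'   `reference_diameter_mm`.
#' @export
#' @examples
#' calibrate(data.frame(diameter = c(12, 13, 14, 13, 13)))  # 1 mm/px
calibrate <- function(markers, reference_diameter_mm = 13) {
  d <- markers$diameter
  if (is.null(d) || length(d) < 1) stop_data("at least one detected marker required")
  if (any(!is.finite(d)) || any(d <= 0))
    stop_data("invalid detection: non-positive marker diameter")
  structure(list(mm_per_px = reference_diameter_mm / stats::median(d),
                 reference_diameter_mm = reference_diameter_mm),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration: %.4f mm/px (reference marker %.1f mm)\n",
              x$mm_per_px, x$reference_diameter_mm))
  invisible(x)
}

#' Label detected markers as anatomical landmarks and convert to cm
#'
#' Sorts the five detections along the craniocaudal image axis, labels them
#' MEd, AXd, ACd, COd, EId in cranial-to-caudal order, and converts pixel
#' coordinates to the physical sagittal frame: x in cm from the MEd foot,
#' y in cm above the support-surface baseline (image rows grow downward,
#' physical y grows upward, so the row direction is flipped).
#'
#' @param markers `detected_markers` with exactly five rows.
#' @param cal A [calibrate()] result.
#' @param baseline_y_px Image row of the support surface.
#' @param axis_direction `"x_increasing_caudal"` if image x grows toward
#'   the feet, `"x_decreasing_caudal"` otherwise.
#' @return A [marker_set] with `source = "detected"`.
#' @export
assign_landmarks <- function(markers, cal,
                             baseline_y_px,
                             axis_direction = c("x_increasing_caudal",
                                                "x_decreasing_caudal")) {
  axis_direction <- match.arg(axis_direction)
  if (nrow(markers) != 5) stop_data("exactly five markers are required")
  if (!inherits(cal, "calibration")) stop_data("cal must be a calibration")
  ord <- order(markers$center_x,
               decreasing = (axis_direction == "x_decreasing_caudal"))
  mk <- markers[ord, , drop = FALSE]
  if (any(abs(diff(mk$center_x)) < 2))
    stop_geometry("ambiguous landmark ordering: two markers within 2 px along the body axis")
  cm_per_px <- cal$mm_per_px / 10
  sgn <- if (axis_direction == "x_increasing_caudal") 1 else -1
  x_cm <- sgn * (mk$center_x - mk$center_x[1]) * cm_per_px
  y_cm <- (baseline_y_px - mk$center_y) * cm_per_px
  if (any(y_cm < 0)) stop_data("marker detected below the support-surface baseline")
  marker_set(x_cm, y_cm, source = "detected")
}

#' Read pre-digitized marker coordinates
#'
#' Parses the manual-coordinate CSV dialect: header row, columns
#' `subject_id`, `phase`, `landmark`, `x_px`, `y_px`, `diameter_px`;
#' UTF-8; one row per marker per phase.
#'
#' @param path CSV file path.
#' @return Data frame with the columns above.
#' @export
read_marker_coordinates <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("coordinate file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "phase", "landmark", "x_px", "y_px", "diameter_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(sprintf("coordinate CSV missing columns: %s", paste(miss, collapse = ", ")))
  df
}
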