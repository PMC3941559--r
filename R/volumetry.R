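# craniocaudal landmark order of the five adhesive markers:
# manubrium sterni, xiphoid process, 10th-rib inferior angle, umbilicus,
# right anterior superior iliac spine
LANDMARKS <- c("MEd", "AXd", "ACd", "COd", "EId")

#' Construct a calibrated marker set
#'
#' A marker set holds the physical sagittal-plane coordinates of the five
#' anatomical landmarks in one frame. The coordinate frame is fixed by
#' convention: `x` is craniocaudal position in cm with the origin under the
#' manubrium marker (MEd), `y` is height in cm above the support surface
#' (the bed the subject lies on), increasing upward.
#'
#' @param x,y Numeric vectors of length 5, coordinates in cm, ordered
#'   MEd, AXd, ACd, COd, EId (cranial to caudal).
#' @param source `"detected"` (from marker detection) or `"manual"`
#'   (pre-digitized coordinates).
#' @return A data frame of class `marker_set` with columns `landmark`,
#'   `x_cm`, `y_cm` and attribute `source`.
#' @export
#' @examples
#' marker_set(x = c(0, 12, 22, 31, 40), y = c(24, 25, 22, 20, 18))
marker_set <- function(x, y, source = c("manual", "detected")) {
  source <- match.arg(source)
  if (length(x) != 5 || length(y) != 5)
    stop_data("a marker set requires exactly five landmarks")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_data("marker coordinates must be finite")
  if (any(y < 0))
    stop_data("marker heights must be non-negative (above the support surface)")
  if (any(diff(x) <= 0))
    stop_geometry("landmark x positions must be strictly increasing in craniocaudal order MEd, AXd, ACd, COd, EId")
  ms <- data.frame(landmark = LANDMARKS, x_cm = as.numeric(x), y_cm = as.numeric(y),
                   stringsAsFactors = FALSE)
  attr(ms, "source") <- source
  class(ms) <- c("marker_set", "data.frame")
  ms
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set (%s), sagittal coordinates in cm:\n", attr(x, "source")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param vertices A two-column matrix (or data frame) of (x, y) vertices in
#'   cm, in order around the polygon (either orientation); at least 3 rows.
#' @return Absolute enclosed area in cm^2.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2 || nrow(v) < 3)
    stop_geometry("vertices must be a numeric matrix with 2 columns and >= 3 rows")
  if (is_self_intersecting(v))
    stop_geometry("polygon is self-intersecting")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# proper-crossing test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections
is_self_intersecting <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) break
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Partition the trunk profile into compartment areas
#'
#' Each compartment is the quadrilateral bounded above by the straight
#' segment joining two adjacent landmarks, below by the support surface
#' (y = 0), and laterally by the vertical feet dropped from the two
#' landmarks: UT spans MEd-AXd, LT spans AXd-ACd, UA spans ACd-COd and LA
#' spans COd-EId.
#'
#' @param markers A [marker_set].
#' @return Object of class `compartment_areas`: named numeric vector
#'   (UT, LT, UA, LA) of sagittal profile areas in cm^2.
#' @export
#' @examples
#' ms <- marker_set(x = c(0, 5, 10, 15, 20), y = c(10, 12, 11, 9, 8))
#' build_compartments(ms)
build_compartments <- function(markers) {
  if (!inherits(markers, "marker_set")) stop_data("markers must be a marker_set")
  x <- markers$x_cm; y <- markers$y_cm
  if (any(diff(x) <= 0))
    stop_geometry("craniocaudal landmark ordering violated")
  a <- vapply(1:4, function(i) {
    quad <- rbind(c(x[i], 0), c(x[i], y[i]), c(x[i + 1], y[i + 1]), c(x[i + 1], 0))
    # degenerate (zero-height) quadrilaterals are legitimate flat profiles
    if (y[i] == 0 && y[i + 1] == 0) 0 else polygon_area(quad)
  }, numeric(1))
  structure(c(UT = a[1], LT = a[2], UA = a[3], LA = a[4]),
            class = "compartment_areas")
}

#' @export
print.compartment_areas <- function(x, ...) {
  cat("Compartment profile areas (cm^2):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Extrude compartment areas into volumes
#'
#' Converts the 2D sagittal profile areas into 3D volumes by sweeping each
#' compartment through one uniform depth, the caliper-measured thorax
#' length, and fills in the totals: TT = UT + LT (total thorax),
#' TA = UA + LA (total abdomen), thoracoabdominal = TT + TA.
#'
#' @param areas A `compartment_areas` object (cm^2), or a named numeric
#'   vector with elements UT, LT, UA, LA.
#' @param thorax_length Extrusion depth in cm (> 0).
#' @return Object of class `compartment_volumes`: named numeric vector
#'   (UT, LT, TT, UA, LA, TA, thoracoabdominal) in litres.
#' @export
#' @examples
#' extrude(c(UT = 100, LT = 80, UA = 40, LA = 50), thorax_length = 25.5)
extrude <- function(areas, thorax_length) {
  if (!is.numeric(thorax_length) || length(thorax_length) != 1 || thorax_length <= 0)
    stop_usage("thorax_length must be a single positive number (cm)")
  a <- unclass(areas)
  if (!all(c("UT", "LT", "UA", "LA") %in% names(a)))
    stop_data("areas must contain UT, LT, UA, LA")
  if (any(a[c("UT", "LT", "UA", "LA")] < 0)) stop_geometry("negative compartment area")
  v <- a[c("UT", "LT", "UA", "LA")] * thorax_length / 1000  # cm^3 -> l
  compartment_volumes(UT = v[["UT"]], LT = v[["LT"]], UA = v[["UA"]], LA = v[["LA"]])
}

#' Assemble compartment volumes with totals
#'
#' @param UT,LT,UA,LA Compartment volumes in litres (>= 0).
#' @return Object of class `compartment_volumes` with derived totals TT,
#'   TA and thoracoabdominal.
#' @export
compartment_volumes <- function(UT, LT, UA, LA) {
  v <- c(UT = UT, LT = LT, UA = UA, LA = LA)
  if (any(!is.finite(v)) || any(v < 0)) stop_data("compartment volumes must be finite and >= 0")
  out <- c(UT = UT, LT = LT, TT = UT + LT,
           UA = UA, LA = LA, TA = UA + LA,
           thoracoabdominal = UT + LT + UA + LA)
  structure(out, class = "compartment_volumes")
}

#' @export
print.compartment_volumes <- function(x, ...) {
  cat("Compartment volumes (l):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Pair expiration and inspiration volumes into a breath
#'
#' The total volumetric mobility is the thoracoabdominal volume at maximal
#' inspiration minus the thoracoabdominal volume at maximal expiration.
#'
#' @param exp,insp `compartment_volumes` for the expiration and inspiration
#'   frames.
#' @return Object of class `breath_pair`: list with `expiration`,
#'   `inspiration` and `mobility` (l). Negative mobility (inspiration
#'   smaller than expiration) is returned with a warning.
#' @export
pair_breath <- function(exp, insp) {
  for (v in list(exp, insp))
    if (!inherits(v, "compartment_volumes")) stop_data("inputs must be compartment_volumes")
  mob <- insp[["thoracoabdominal"]] - exp[["thoracoabdominal"]]
  if (mob < 0)
    warning("negative mobility: inspiration volume below expiration volume",
            call. = FALSE)
  structure(list(expiration = exp, inspiration = insp, mobility = mob),
            class = "breath_pair")
}

#' @export
print.breath_pair <- function(x, ...) {
  cat(sprintf("Breath pair: expiration %.2f l, inspiration %.2f l\n",
              x$expiration[["thoracoabdominal"]], x$inspiration[["thoracoabdominal"]]))
  cat(sprintf("Total volumetric mobility: %.2f l\n", x$mobility))
  invisible(x)
}

#' Inspiration-expiration volumetric variability
#'
#' Relative volume change of a compartment between the two respiratory
#' phases, as a percentage of the expiration volume, reported to one
#' decimal place.
#'
#' @param exp_vol,insp_vol Compartment volumes (l) at expiration and
#'   inspiration; `exp_vol` must be positive.
#' @return Percentage, rounded to one decimal.
#' @export
#' @examples
#' variability_percent(7.32, 8.41)  # 14.9
variability_percent <- function(exp_vol, insp_vol) {
  if (any(!is.finite(exp_vol)) || any(exp_vol <= 0))
    stop_usage("exp_vol must be positive")
  round(100 * (insp_vol - exp_vol) / exp_vol, 1)
}

#' Thoracic and abdominal share of the thoracoabdominal volume
#'
#' @param vol A `compartment_volumes` object with positive thoracoabdominal
#'   total.
#' @return Named numeric `c(TT_percent, TA_percent)`, each rounded to one
#'   decimal; they sum to 100 within 0.1.
#' @export
#' @examples
#' compartment_share(compartment_volumes(UT = 8.41, LT = 7.65, UA = 3.16, LA = 3.86))
compartment_share <- function(vol) {
  if (!inherits(vol, "compartment_volumes")) stop_data("vol must be compartment_volumes")
  total <- vol[["thoracoabdominal"]]
  if (total <= 0) stop_usage("thoracoabdominal total must be positive")
  c(TT_percent = round(100 * vol[["TT"]] / total, 1),
    TA_percent = round(100 * vol[["TA"]] / total, 1))
}

# forward volumetry: marker set -> breath-phase volumes
markers_to_volumes <- function(markers, thorax_length) {
  extrude(build_compartments(markers), thorax_length)
}
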