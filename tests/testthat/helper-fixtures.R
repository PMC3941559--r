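# a subject at the reference-cohort mean anthropometrics, unit pixel scale
# unless overridden
mean_subject <- function(mm_per_px = 1.0) {
  subject_spec(subject_id = "MEAN", sex = "M", age = 15L, body_mass = 61.3,
               height = 1.66, thorax_length = 25.5, mm_per_px = mm_per_px)
}

# draw one filled dark circle (analytic edge coverage) onto a matrix
draw_circle <- function(img, row_c, col_c, r, fg = 0.15, bg = 0.90) {
  rows <- max(1, floor(row_c - r - 1)):min(nrow(img), ceiling(row_c + r + 1))
  cols <- max(1, floor(col_c - r - 1)):min(ncol(img), ceiling(col_c + r + 1))
  dr <- outer(rows - row_c, cols - col_c, function(a, b) sqrt(a^2 + b^2))
  cov <- pmin(pmax(r + 0.5 - dr, 0), 1)
  img[rows, cols] <- pmin(img[rows, cols], bg - (bg - fg) * cov)
  img
}

# independent point-in-polygon test (ray casting), used as the Monte-Carlo
# oracle for polygon areas -- deliberately not the shoelace formula
point_in_polygon <- function(px, py, v) {
  n <- nrow(v); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# brute-force profile volume: rasterize the piecewise-linear skin profile
# over a fine grid and multiply the hit area by the extrusion depth
rasterized_volume <- function(ms, thorax_cm, nx = 2000, ny = 800) {
  xs <- seq(min(ms$x_cm), max(ms$x_cm), length.out = nx)
  ymax <- max(ms$y_cm) * 1.05
  ys <- seq(0, ymax, length.out = ny)
  prof <- approx(ms$x_cm, ms$y_cm, xout = xs)$y
  cell <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  hits <- sum(vapply(seq_along(xs), function(i) sum(ys < prof[i]), numeric(1)))
  hits * cell * thorax_cm / 1000
}

# random valid marker set: increasing x, positive heights
random_marker_set <- function() {
  x <- cumsum(c(0, runif(4, 5, 14)))
  y <- runif(5, 5, 28)
  marker_set(x, y)
}
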