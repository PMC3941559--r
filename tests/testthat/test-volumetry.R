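test_that("polygon_area matches hand geometry and rejects bad polygons", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1.0)
  # orientation must not matter
  expect_equal(polygon_area(rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0))), 1.0)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 rows")
  # bow-tie
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
})

test_that("polygon_area agrees with a Monte-Carlo hit-count oracle on a random convex 8-gon", {
  set.seed(42)
  ang <- sort(runif(8, 0, 2 * pi))
  rad <- runif(8, 2, 5)
  v <- cbind(rad * cos(ang), rad * sin(ang))
  a_shoelace <- polygon_area(v)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  ns <- 1e6
  px <- runif(ns, xr[1], xr[2]); py <- runif(ns, yr[1], yr[2])
  hit <- mapply(function(x, y) point_in_polygon(x, y, v), px, py)
  a_mc <- mean(hit) * diff(xr) * diff(yr)
  expect_lt(abs(a_shoelace - a_mc) / a_mc, 0.005)
})

test_that("compartments are baseline-closed trapezoids between adjacent landmarks", {
  # flat profile: four 5 x 10 rectangles
  flat <- build_compartments(marker_set(seq(0, 20, by = 5), rep(10, 5)))
  expect_equal(unclass(flat), c(UT = 50, LT = 50, UA = 50, LA = 50))
  # hand-computed trapezoids
  tr <- build_compartments(marker_set(seq(0, 20, by = 5), c(10, 12, 11, 9, 8)))
  expect_equal(unclass(tr), c(UT = 55, LT = 57.5, UA = 50, LA = 42.5))
  # degenerate zero-height profile
  zero <- build_compartments(marker_set(seq(0, 20, by = 5), rep(0, 5)))
  expect_equal(unname(unclass(zero)), rep(0, 4))
})

test_that("extrusion converts cm^2 x cm to litres and is linear in depth", {
  a <- structure(c(UT = 100, LT = 0, UA = 0, LA = 0), class = "compartment_areas")
  expect_equal(extrude(a, 25.5)[["UT"]], 2.55)
  z <- extrude(structure(c(UT = 0, LT = 0, UA = 0, LA = 0),
                         class = "compartment_areas"), 20)
  expect_equal(unname(unclass(z)), rep(0, 7))
  a2 <- structure(c(UT = 30, LT = 40, UA = 20, LA = 10), class = "compartment_areas")
  expect_equal(unclass(extrude(a2, 50)), 2 * unclass(extrude(a2, 25)))
  expect_error(extrude(a2, 0), "positive")
})

test_that("volume totals satisfy the additivity invariants", {
  set.seed(7)
  for (i in 1:20) {
    v <- extrude(build_compartments(random_marker_set()), runif(1, 20, 30))
    expect_equal(v[["TT"]], v[["UT"]] + v[["LT"]], tolerance = 1e-12)
    expect_equal(v[["TA"]], v[["UA"]] + v[["LA"]], tolerance = 1e-12)
    expect_equal(v[["thoracoabdominal"]], v[["TT"]] + v[["TA"]], tolerance = 1e-12)
  }
})

test_that("raising one marker increases adjacent compartments; scaling y scales areas", {
  ms <- marker_set(c(0, 6, 12, 18, 24), c(15, 16, 14, 12, 11))
  a0 <- build_compartments(ms)
  up <- marker_set(c(0, 6, 12, 18, 24), c(15, 17, 14, 12, 11))  # raise AXd
  a1 <- build_compartments(up)
  expect_gt(a1[["UT"]], a0[["UT"]])
  expect_gt(a1[["LT"]], a0[["LT"]])
  expect_equal(a1[["UA"]], a0[["UA"]])
  expect_equal(a1[["LA"]], a0[["LA"]])
  k <- 1.7
  ak <- build_compartments(marker_set(c(0, 6, 12, 18, 24), k * c(15, 16, 14, 12, 11)))
  expect_equal(unclass(ak), k * unclass(a0), tolerance = 1e-12)
})

test_that("breath pairing derives mobility and flags inverted phases", {
  vexp <- compartment_volumes(UT = 7.32, LT = 5.90, UA = 2.56, LA = 3.55)
  vinsp <- compartment_volumes(UT = 8.41, LT = 7.65, UA = 3.16, LA = 3.86)
  bp <- pair_breath(vexp, vinsp)
  expect_equal(bp$mobility,
               vinsp[["thoracoabdominal"]] - vexp[["thoracoabdominal"]],
               tolerance = 1e-12)
  expect_equal(pair_breath(vexp, vexp)$mobility, 0)
  expect_warning(bad <- pair_breath(vinsp, vexp), "negative mobility")
  expect_lt(bad$mobility, 0)
})

test_that("mobility from the reference totals is 3.75 l", {
  ref <- reference_cohort_summary()
  e <- ref$mean[ref$section == "expiration" & ref$variable == "thoracoabdominal"]
  i <- ref$mean[ref$section == "inspiration" & ref$variable == "thoracoabdominal"]
  expect_equal(i - e, 3.75)
})

test_that("variability percent and compartment shares follow their definitions", {
  expect_equal(variability_percent(7.32, 8.41), 14.9)
  expect_equal(variability_percent(3.56, 3.86), 8.4)
  expect_equal(variability_percent(5, 5), 0)
  expect_error(variability_percent(0, 1), "positive")

  v <- compartment_volumes(UT = 8.41, LT = 7.65, UA = 3.16, LA = 3.86)
  sh <- compartment_share(v)
  expect_equal(sum(sh), 100, tolerance = 0.1)
  even <- compartment_share(compartment_volumes(UT = 2, LT = 2, UA = 2, LA = 2))
  expect_equal(unname(even), c(50, 50))
  ta0 <- compartment_share(compartment_volumes(UT = 2, LT = 2, UA = 0, LA = 0))
  expect_equal(unname(ta0), c(100, 0))
  expect_error(compartment_share(compartment_volumes(0, 0, 0, 0)), "positive")
})

test_that("trapezoid-plus-extrusion volumes match brute-force rasterization", {
  set.seed(11)
  for (i in 1:10) {
    ms <- random_marker_set()
    th <- runif(1, 20, 30)
    v <- extrude(build_compartments(ms), th)[["thoracoabdominal"]]
    expect_lt(abs(v - rasterized_volume(ms, th)) / v, 0.005)
  }
})

test_that("marker_set enforces ordering and coordinate validity", {
  expect_error(marker_set(c(0, 5, 4, 15, 20), rep(10, 5)), "strictly increasing")
  expect_error(marker_set(c(0, 5, 10, 15, 20), c(10, 10, -1, 10, 10)), "non-negative")
  expect_error(marker_set(c(0, 5, 10, 15), rep(10, 4)), "five")
})
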