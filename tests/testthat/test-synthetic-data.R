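test_that("subject sampling is seed-deterministic and leaves the caller's RNG alone", {
  s1 <- sample_subject(rng_seed = 1)
  s2 <- sample_subject(rng_seed = 1)
  expect_identical(s1, s2)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_subject(rng_seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("sampled anthropometrics follow the reference population", {
  subs <- sample_cohort(1000, seed = 3)
  h <- vapply(subs, function(s) s$height, numeric(1))
  m <- vapply(subs, function(s) s$body_mass, numeric(1))
  th <- vapply(subs, function(s) s$thorax_length, numeric(1))
  ages <- vapply(subs, function(s) s$age, integer(1))
  expect_lt(abs(mean(h) - 1.66), 0.02)
  expect_true(all(h >= 1.52 & h <= 1.87))
  expect_true(all(m >= 43.5 & m <= 87.0))
  expect_true(all(th >= 21.5 & th <= 29.5))
  expect_true(all(ages >= 14 & ages <= 17))
  # truncation barely moves these means: 3 standard errors around the target
  expect_lt(abs(mean(m) - 61.3), 3 * 12.3 / sqrt(1000))
  expect_lt(abs(mean(th) - 25.5), 3 * 1.9 / sqrt(1000))
})

test_that("inverse kinematics reproduces the target mobility through forward volumetry", {
  s <- mean_subject()
  kt <- make_kinematics(s, 3.75, rng_seed = 2)
  expect_lt(abs(kt$true_mobility - 3.75), 1e-9)
  fwd_e <- extrude(build_compartments(kt$marker_exp), s$thorax_length)
  fwd_i <- extrude(build_compartments(kt$marker_insp), s$thorax_length)
  expect_lt(abs((fwd_i[["thoracoabdominal"]] - fwd_e[["thoracoabdominal"]]) - 3.75),
            1e-9)

  # round trip over random subjects and targets
  set.seed(21)
  for (i in 1:100) {
    sub <- sample_subject(rng_seed = 1000 + i)
    target <- runif(1, 0.5, 7)
    kt <- make_kinematics(sub, target, rng_seed = i)
    fe <- extrude(build_compartments(kt$marker_exp), sub$thorax_length)
    fi <- extrude(build_compartments(kt$marker_insp), sub$thorax_length)
    expect_lt(abs((fi[["thoracoabdominal"]] - fe[["thoracoabdominal"]]) - target), 1e-9)
    # constructive invariants: ordering, positivity, phase monotonicity
    expect_true(all(diff(kt$marker_exp$x_cm) > 0))
    expect_true(all(kt$marker_exp$y_cm > 0) && all(kt$marker_insp$y_cm > 0))
    expect_gte(kt$true_volumes_insp[["thoracoabdominal"]],
               kt$true_volumes_exp[["thoracoabdominal"]])
  }
})

test_that("zero target mobility yields identical phases; infeasible targets error", {
  s <- mean_subject()
  kt0 <- make_kinematics(s, 0, rng_seed = 4)
  expect_equal(kt0$marker_insp$y_cm, kt0$marker_exp$y_cm, tolerance = 1e-12)
  expect_equal(kt0$true_mobility, 0, tolerance = 1e-12)
  expect_error(make_kinematics(s, -1), "non-negative")
  # absurd target drives a marker below the support surface
  expect_error(make_kinematics(s, 500, rng_seed = 4), "invalid configuration")
})

test_that("expiration compartments are proportioned like the reference cohort", {
  s <- mean_subject()
  kt <- make_kinematics(s, 3.75, rng_seed = 8)
  ref <- reference_cohort_summary()
  for (cmp in c("UT", "LT", "UA", "LA")) {
    want <- ref$mean[ref$section == "expiration" & ref$variable == cmp] /
      ref$mean[ref$section == "expiration" & ref$variable == "thoracoabdominal"]
    got <- kt$true_volumes_exp[[cmp]] / kt$true_volumes_exp[["thoracoabdominal"]]
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("noiseless renders contain five disjoint circles at the nominal diameter", {
  s <- mean_subject(mm_per_px = 1.0)
  kt <- make_kinematics(s, 3.75, rng_seed = 2)
  fr <- render_frame(kt, "expiration", s)
  det <- detect_markers(fr)
  expect_equal(nrow(det), 5)
  expect_true(all(abs(det$diameter - 13) <= 0.5))
  expect_equal(fr$marker_px_diameter, 13)
})

test_that("render then detect recovers ground-truth centers", {
  s <- mean_subject(mm_per_px = 0.7)
  kt <- make_kinematics(s, 4.2, rng_seed = 5)
  for (noise in c(0, 10)) {
    fr <- render_frame(kt, "inspiration", s, noise_sd = noise, rng_seed = 9)
    det <- detect_markers(fr)
    det <- det[order(det$center_x), ]
    tru <- fr$truth_px[order(fr$truth_px$x_px), ]
    derr <- sqrt((det$center_x - tru$x_px)^2 + (det$center_y - tru$y_px)^2)
    tol_center <- if (noise == 0) 0.5 else 1.5
    tol_diam <- if (noise == 0) 0.5 else 1.5
    expect_true(all(derr <= tol_center))
    expect_true(all(abs(det$diameter - fr$marker_px_diameter) <= tol_diam))
  }
})

test_that("rendering is deterministic per seed and guards against overlap", {
  s <- mean_subject(mm_per_px = 1.0)
  kt <- make_kinematics(s, 3, rng_seed = 3)
  f1 <- render_frame(kt, "expiration", s, noise_sd = 8, rng_seed = 11)
  f2 <- render_frame(kt, "expiration", s, noise_sd = 8, rng_seed = 11)
  expect_identical(f1$pixels, f2$pixels)
  # landmarks closer than the 13 mm marker diameter cannot be drawn disjointly
  cramped <- structure(list(marker_exp = marker_set(seq(0, 2, by = 0.5), rep(5, 5)),
                            marker_insp = marker_set(seq(0, 2, by = 0.5), rep(6, 5))),
                       class = "kinematic_truth")
  expect_error(render_frame(cramped, "expiration", s), "too close")
})
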