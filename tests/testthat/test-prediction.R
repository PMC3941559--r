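test_that("Tiffeneau screening uses a strict below-threshold rule on the unrounded ratio", {
  expect_equal(screen_subject(list(FEV1 = 3.22, FVC = 3.87)), "retained")  # 0.832
  expect_equal(screen_subject(list(FEV1 = 0.80, FVC = 1.00)), "retained")  # boundary
  expect_equal(screen_subject(list(FEV1 = 0.799, FVC = 1.00)),
               "excluded_obstruction_or_restriction")
  # restriction flag only with a user-supplied FVC limit
  low <- list(FEV1 = 1.5, FVC = 1.7)  # ratio 0.88
  expect_equal(screen_subject(low), "retained")
  expect_equal(screen_subject(low, fvc_lower_limit = 2.0),
               "excluded_obstruction_or_restriction")
  expect_error(screen_subject(list(FEV1 = 0, FVC = 2)), "positive")
})

test_that("the simulated assessment roster screens down to the analyzed cohort size", {
  out <- withr::local_tempdir()
  sim <- simulate_breathing_cohort(out, n = 50, seed = 7, write_frames = FALSE)
  status <- screen_cohort(sim$subjects, threshold = 0.80, fvc_lower_limit = 2.0)
  expect_equal(sum(status == "retained"), 40)
  expect_equal(sum(status != "retained"), 10)
})

test_that("reference equations are the documented affine forms", {
  # hand-computed values of the affine combinations
  expect_equal(predict_fvc(1.87, 29.5, 10),
               -8.572 + 5.108 * 1.87 + 0.138 * 29.5 + 0.120 * 10, tolerance = 1e-12)
  expect_equal(predict_di(1.87, 29.5, 10),
               -6.373 + 3.751 * 1.87 + 0.122 * 29.5 + 0.163 * 10, tolerance = 1e-12)
  # unit slope in mobility
  expect_equal(predict_fvc(1.7, 25, 4) - predict_fvc(1.7, 25, 3), 0.120,
               tolerance = 1e-12)
  expect_equal(predict_di(1.7, 25, 4) - predict_di(1.7, 25, 3), 0.163,
               tolerance = 1e-12)
  # out-of-domain evaluation returns the intercept, with a warning
  expect_warning(v <- predict_di(0, 0, 0), "non-positive")
  expect_equal(v, -6.373)
  # affine: prediction at the mean input equals the mean prediction
  h <- c(1.55, 1.80); t <- c(22, 29); m <- c(2, 6)
  expect_equal(predict_fvc(mean(h), mean(t), mean(m)),
               mean(predict_fvc(h, t, m)), tolerance = 1e-12)
})

test_that("OLS refit recovers the generating coefficients exactly on noiseless data", {
  set.seed(31)
  d <- data.frame(height_m = runif(40, 1.52, 1.87),
                  thorax_cm = runif(40, 21.5, 29.5),
                  mobility_l = runif(40, 1.5, 7))
  d$FVC_l <- predict_fvc(d$height_m, d$thorax_cm, d$mobility_l)
  fit <- fit_mobility_model(d$FVC_l, d, outcome_name = "FVC")
  expect_equal(unname(coef(fit)), c(-8.572, 5.108, 0.138, 0.120), tolerance = 1e-8)
  expect_equal(fit$R_squared, 1, tolerance = 1e-8)
  expect_lt(fit$SE_estimate, 1e-8)
  expect_equal(fit$n, 40)
})

test_that("fit diagnostics, degeneracies and invariants behave", {
  set.seed(32)
  d <- data.frame(height_m = runif(30, 1.5, 1.9),
                  thorax_cm = runif(30, 21, 30),
                  mobility_l = runif(30, 1, 7))
  d$y <- predict_fvc(d$height_m, d$thorax_cm, d$mobility_l) + rnorm(30, 0, 0.3)

  fit <- fit_mobility_model(d$y, d)
  # OLS passes through the means
  at_mean <- predict(fit, data.frame(height_m = mean(d$height_m),
                                     thorax_cm = mean(d$thorax_cm),
                                     mobility_l = mean(d$mobility_l)))
  expect_equal(at_mean, mean(d$y), tolerance = 1e-10)
  # invariant to subject ordering
  perm <- sample(nrow(d))
  fit2 <- fit_mobility_model(d$y[perm], d[perm, ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
  # R is the correlation of fitted and observed and squares to R2
  expect_equal(fit$R, cor(fitted(fit$fit), d$y), tolerance = 1e-12)
  expect_equal(fit$R_squared, fit$R^2, tolerance = 1e-6)

  # constant outcome: zero slopes, undefined correlation flagged
  expect_warning(cfit <- fit_mobility_model(rep(2.5, 30), d), "constant outcome")
  expect_equal(unname(coef(cfit)), c(2.5, 0, 0, 0), tolerance = 1e-10)
  expect_true(is.na(cfit$R))
  expect_lt(cfit$SE_estimate, 1e-10)

  # collinear design names the offending column
  d2 <- d; d2$thorax_cm <- 2 * d2$height_m
  expect_error(fit_mobility_model(d2$y, d2), "thorax_cm")
  expect_error(fit_mobility_model(d$y[1:4], d[1:4, ]), "at least 5")
})

test_that("noisy refits are unbiased at the study's noise level", {
  # cohort of 40, outcome = reference equation + N(0, 0.353), 500 replicates
  set.seed(33)
  truth <- c(-8.572, 5.108, 0.138, 0.120)
  d <- data.frame(height_m = runif(40, 1.52, 1.87),
                  thorax_cm = runif(40, 21.5, 29.5),
                  mobility_l = runif(40, 1.5, 7))
  mu <- predict_fvc(d$height_m, d$thorax_cm, d$mobility_l)
  cf <- replicate(500, {
    fit <- fit_mobility_model(mu + rnorm(40, 0, 0.353), d)
    unname(coef(fit))
  })
  est <- rowMeans(cf)
  se <- apply(cf, 1, sd) / sqrt(500)
  expect_true(all(abs(est - truth) <= 2 * se))
})

test_that("reference models load, predict, and serialize as JSON", {
  m <- reference_model("FVC")
  expect_s3_class(m, "mobility_model")
  expect_equal(m$R_squared, m$R^2, tolerance = 1e-2)
  expect_equal(predict(m, data.frame(height_m = 1.66, thorax_cm = 25.5,
                                     mobility_l = 3.75)),
               predict_fvc(1.66, 25.5, 3.75), tolerance = 1e-12)
  expect_error(residuals(m), "no training data")

  path <- tempfile(fileext = ".json")
  model_to_json(m, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$coef$height_m, 5.108)
  expect_equal(js$outcome, "FVC")

  di <- reference_model("DI")
  expect_equal(di$intercept, -6.373)
  expect_equal(di$SE_estimate, 0.451)
})

test_that("simulate() draws outcomes around the model prediction with the fitted SEE", {
  m <- reference_model("FVC")
  nd <- data.frame(height_m = rep(1.66, 200), thorax_cm = 25.5, mobility_l = 3.75)
  sims <- simulate(m, nsim = 5, seed = 12, newdata = nd)
  expect_equal(dim(sims), c(200, 5))
  draws <- unlist(sims)
  expect_lt(abs(mean(draws) - predict_fvc(1.66, 25.5, 3.75)), 0.05)
  expect_lt(abs(sd(draws) - 0.353), 0.05)
})
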