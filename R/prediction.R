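#' Screen a spirometry record for obstruction/restriction
#'
#' Subjects whose Tiffeneau index (FEV1/FVC, computed on the unrounded
#' values) is strictly below the threshold are excluded as showing airflow
#' obstruction or restriction; a record exactly at the threshold is
#' retained. Optionally, a record with FVC below a user-supplied lower
#' limit is also excluded as a possible restrictive pattern (no default
#' limit is imposed).
#'
#' @param rec A `spirometry_record` or list/row with fields `FEV1` and
#'   `FVC` (litres).
#' @param threshold Tiffeneau ratio cutoff (default 0.80).
#' @param fvc_lower_limit Optional FVC lower limit (l); `NULL` disables
#'   the restriction check.
#' @return `"retained"` or `"excluded_obstruction_or_restriction"`.
#' @export
#' @examples
#' screen_subject(list(FEV1 = 3.22, FVC = 3.87))  # ratio 0.832: retained
screen_subject <- function(rec, threshold = 0.80, fvc_lower_limit = NULL) {
  if (is.null(rec$FEV1) || is.null(rec$FVC) || rec$FEV1 <= 0 || rec$FVC <= 0)
    stop_data("spirometry record needs positive FEV1 and FVC")
  ratio <- rec$FEV1 / rec$FVC
  if (ratio < threshold) return("excluded_obstruction_or_restriction")
  if (!is.null(fvc_lower_limit) && rec$FVC < fvc_lower_limit)
    return("excluded_obstruction_or_restriction")
  "retained"
}

#' Screen a cohort table
#'
#' @param spiro Data frame with columns `FEV1_l` and `FVC_l` (or `FEV1`,
#'   `FVC`).
#' @inheritParams screen_subject
#' @return Character vector of screening statuses, one per row.
#' @export
screen_cohort <- function(spiro, threshold = 0.80, fvc_lower_limit = NULL) {
  fev1 <- if ("FEV1_l" %in% names(spiro)) spiro$FEV1_l else spiro$FEV1
  fvc  <- if ("FVC_l" %in% names(spiro)) spiro$FVC_l else spiro$FVC
  if (is.null(fev1) || is.null(fvc)) stop_data("spirometry columns FEV1/FVC not found")
  vapply(seq_along(fev1), function(i)
    screen_subject(list(FEV1 = fev1[i], FVC = fvc[i]), threshold, fvc_lower_limit),
    character(1))
}

eval_equation <- function(intercept, coefs, height, thorax, mobility, what) {
  if (any(c(height, thorax, mobility) <= 0, na.rm = TRUE))
    warning(sprintf("%s evaluated at non-positive predictor values (out of the model's domain)", what),
            call. = FALSE)
  intercept + coefs[["height_m"]] * height + coefs[["thorax_cm"]] * thorax +
    coefs[["mobility_l"]] * mobility
}

#' Predict forced vital capacity from the reference equation
#'
#' Evaluates the shipped reference equation
#' FVC = -8.572 + 5.108 x height + 0.138 x thorax + 0.120 x mobility.
#'
#' @param height Standing height, m.
#' @param thorax Thorax length, cm.
#' @param mobility Total volumetric mobility, l.
#' @return Predicted FVC, litres (vectorized).
#' @export
#' @examples
#' predict_fvc(1.66, 25.5, 3.75)
predict_fvc <- function(height, thorax, mobility) {
  m <- reference_model("FVC")
  eval_equation(m$intercept, m$coefficients, height, thorax, mobility, "predict_fvc")
}

#' Predict deep inspiration from the reference equation
#'
#' Evaluates the shipped reference equation
#' DI = -6.373 + 3.751 x height + 0.122 x thorax + 0.163 x mobility.
#'
#' @inheritParams predict_fvc
#' @return Predicted DI, litres (vectorized).
#' @export
predict_di <- function(height, thorax, mobility) {
  m <- reference_model("DI")
  eval_equation(m$intercept, m$coefficients, height, thorax, mobility, "predict_di")
}

new_mobility_model <- function(intercept, coefficients, R, R_squared,
                               SE_estimate, n, outcome, fit = NULL, call = NULL) {
  structure(list(intercept = intercept, coefficients = coefficients,
                 R = R, R_squared = R_squared, SE_estimate = SE_estimate,
                 n = n, outcome = outcome, fit = fit, call = call),
            class = "mobility_model")
}

#' Fit the mobility prediction model to a cohort
#'
#' Ordinary least squares fit of the model form
#' `outcome ~ height_m + thorax_cm + mobility_l`, the same structure as
#' the shipped reference equations, so new cohorts can be recalibrated.
#'
#' @param outcome Numeric vector of the spirometric outcome (l), one value
#'   per subject, or the name of a column of `data`.
#' @param data Data frame with numeric columns `height_m`, `thorax_cm`
#'   and `mobility_l` (and the outcome column if `outcome` is a name).
#' @param outcome_name Label stored with the model (e.g. `"FVC"`).
#' @return Object of class `mobility_model` with elements `intercept`,
#'   `coefficients` (height_m, thorax_cm, mobility_l), `R` (multiple
#'   correlation of fitted vs observed), `R_squared`, `SE_estimate`
#'   (residual standard error, denominator n - 4), `n`, and the underlying
#'   `lm` fit. Supports `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `simulate` and `plot`.
#' @export
#' @examples
#' d <- data.frame(height_m = runif(20, 1.5, 1.9),
#'                 thorax_cm = runif(20, 21, 30),
#'                 mobility_l = runif(20, 1.5, 6))
#' d$FVC_l <- predict_fvc(d$height_m, d$thorax_cm, d$mobility_l)
#' fit <- fit_mobility_model(d$FVC_l, d, outcome_name = "FVC")
#' coef(fit)
fit_mobility_model <- function(outcome, data, outcome_name = "outcome") {
  need <- c("height_m", "thorax_cm", "mobility_l")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_data(sprintf("data is missing predictor columns: %s", paste(miss, collapse = ", ")))
  if (is.character(outcome) && length(outcome) == 1 && outcome %in% names(data)) {
    outcome_name <- outcome
    outcome <- data[[outcome]]
  }
  y <- as.numeric(outcome)
  n <- length(y)
  if (n != nrow(data)) stop_data("outcome length does not match data")
  if (n < 5) stop_usage("at least 5 subjects are required to fit the 4-parameter model")

  X <- cbind(height_m = data$height_m, thorax_cm = data$thorax_cm,
             mobility_l = data$mobility_l)
  if (any(!complete.cases(X)) || any(!is.finite(y)))
    stop_data("missing or non-finite values in outcome/predictors")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 4) {
    piv <- qrX$pivot[(qrX$rank + 1):4]
    bad <- c("(intercept)", colnames(X))[piv]
    stop_data(sprintf("singular fit: collinear predictor column(s) %s",
                      paste(bad, collapse = ", ")))
  }

  df <- data.frame(.y = y, height_m = data$height_m, thorax_cm = data$thorax_cm,
                   mobility_l = data$mobility_l)
  fit <- lm(.y ~ height_m + thorax_cm + mobility_l, data = df)
  cf <- coef(fit)
  # sqrt(RSS / (n - 4)); noiseless fixtures trip summary.lm's perfect-fit
  # warning, which is meaningless for plain SEE extraction
  see <- suppressWarnings(summary(fit))$sigma
  if (var(y) == 0) {
    warning("constant outcome: multiple correlation undefined", call. = FALSE)
    R <- NA_real_; R2 <- NA_real_
  } else {
    R <- cor(fitted(fit), y)
    R2 <- R^2
  }
  new_mobility_model(
    intercept = unname(cf[1]),
    coefficients = c(height_m = unname(cf["height_m"]),
                     thorax_cm = unname(cf["thorax_cm"]),
                     mobility_l = unname(cf["mobility_l"])),
    R = R, R_squared = R2, SE_estimate = see, n = n,
    outcome = outcome_name, fit = fit, call = match.call()
  )
}

#' @export
print.mobility_model <- function(x, digits = 3, ...) {
  cat(sprintf("Mobility prediction model for %s (n = %d)\n", x$outcome, x$n))
  cat(sprintf("  %s = %.3f + %.3f x height(m) + %.3f x thorax(cm) + %.3f x mobility(l)\n",
              x$outcome, x$intercept, x$coefficients[["height_m"]],
              x$coefficients[["thorax_cm"]], x$coefficients[["mobility_l"]]))
  cat(sprintf("  R = %.3f, R^2 = %.3f, SEE = %.3f l\n", x$R, x$R_squared, x$SE_estimate))
  invisible(x)
}

#' @export
coef.mobility_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.mobility_model <- function(object, newdata, ...) {
  need <- c("height_m", "thorax_cm", "mobility_l")
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop_data(sprintf("newdata is missing columns: %s", paste(miss, collapse = ", ")))
  eval_equation(object$intercept, object$coefficients, newdata$height_m,
                newdata$thorax_cm, newdata$mobility_l,
                sprintf("%s model", object$outcome))
}

#' @export
residuals.mobility_model <- function(object, ...) {
  if (is.null(object$fit))
    stop_data("reference models carry no training data, so no residuals")
  residuals(object$fit)
}

#' @export
summary.mobility_model <- function(object, ...) {
  out <- list(model = object,
              lm_summary = if (!is.null(object$fit)) summary(object$fit) else NULL)
  class(out) <- "summary.mobility_model"
  out
}

#' @export
print.summary.mobility_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$lm_summary)) {
    cat("\nCoefficient table (OLS refit):\n")
    stats::printCoefmat(x$lm_summary$coefficients)
  }
  invisible(x)
}

#' @export
simulate.mobility_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  mu <- predict(object, newdata)
  with_rng(seed, {
    out <- replicate(nsim, mu + rnorm(length(mu), 0, object$SE_estimate))
    as.data.frame(out)
  })
}

#' @export
plot.mobility_model <- function(x, observed = NULL, ...) {
  if (is.null(x$fit) && is.null(observed))
    stop_data("plotting a reference model requires `observed` and newdata-based predictions")
  if (is.null(observed)) observed <- x$fit$model$.y
  pred <- fitted(x$fit)
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(observed, pred, xlab = sprintf("Spirometric %s (l)", x$outcome),
       ylab = sprintf("Predicted %s (l)", x$outcome),
       main = "Prediction vs spirometry", pch = 19)
  abline(0, 1, lty = 2)
  ba <- bland_altman(pred, observed)
  plot(ba, main = sprintf("Bland-Altman: %s", x$outcome))
  invisible(x)
}

#' Export a fitted or reference model as JSON
#'
#' Writes the interchange form
#' `{"outcome", "intercept", "coef": {"height_m", "thorax_cm",
#' "mobility_l"}, "R", "R2", "SEE_l", "n"}`.
#'
#' @param model A `mobility_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  js <- list(outcome = model$outcome, intercept = model$intercept,
             coef = as.list(model$coefficients), R = model$R,
             R2 = model$R_squared, SEE_l = model$SE_estimate, n = model$n)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
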