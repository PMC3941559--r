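#' Reference cohort summary statistics
#'
#' Summary statistics (mean, SD, minimum, maximum) of the adolescent
#' reference cohort (n = 40, ages 14-17, supine forced-breathing maneuvers)
#' on which the shipped prediction equations were developed: anthropometric
#' variables, spirometric outcomes, and photogrammetric compartment volumes
#' at maximal expiration and maximal inspiration.
#'
#' @return A data frame with columns `section` (one of `anthropometric`,
#'   `pulmonary`, `expiration`, `inspiration`), `variable`, `unit`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
#' @examples
#' ref <- reference_cohort_summary()
#' subset(ref, variable == "thoracoabdominal")
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.csv",
                      package = "photoresp", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

# pull a single reference mean, e.g. ref_mean("UT", "expiration")
ref_mean <- function(variable, section) {
  ref <- reference_cohort_summary()
  row <- ref[ref$variable == variable & ref$section == section, ]
  if (nrow(row) != 1) stop_data(sprintf("no unique reference row for %s/%s", section, variable))
  row$mean
}

#' Shipped reference prediction models
#'
#' Loads one of the two read-only reference regression models relating a
#' spirometric outcome to height (m), thorax length (cm) and total
#' volumetric mobility (l):
#' \deqn{FVC = -8.572 + 5.108 \cdot height + 0.138 \cdot thorax + 0.120 \cdot mobility}
#' \deqn{DI  = -6.373 + 3.751 \cdot height + 0.122 \cdot thorax + 0.163 \cdot mobility}
#'
#' The returned object is a [mobility_model] without an embedded `lm` fit
#' (the raw development data are not distributed); `predict()`, `coef()` and
#' `print()` work as for refitted models.
#'
#' @param outcome `"FVC"` (forced vital capacity, l) or `"DI"` (deep
#'   inspiration, l).
#' @return An object of class `mobility_model`.
#' @export
#' @examples
#' m <- reference_model("FVC")
#' predict(m, data.frame(height_m = 1.66, thorax_cm = 25.5, mobility_l = 3.75))
reference_model <- function(outcome = c("FVC", "DI")) {
  outcome <- match.arg(outcome)
  file <- if (outcome == "FVC") "fvc_reference.json" else "di_reference.json"
  path <- system.file("extdata", "models", file, package = "photoresp", mustWork = TRUE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_mobility_model(
    intercept    = js$intercept,
    coefficients = c(height_m = js$coef$height_m,
                     thorax_cm = js$coef$thorax_cm,
                     mobility_l = js$coef$mobility_l),
    R = js$R, R_squared = js$R2, SE_estimate = js$SEE_l, n = js$n,
    outcome = js$outcome, fit = NULL
  )
}
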