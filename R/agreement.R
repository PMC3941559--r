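#' Pearson correlation with validity checks
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (length(x) < 3) stop_data("at least 3 paired observations are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_data("non-finite values in input")
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("undefined correlation: constant input vector")
  cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference (bias) between two measurement methods,
#' the SD of the differences (n - 1 denominator), and the limits of
#' agreement bias +/- 1.96 SD. The bias is tested against zero with a
#' two-sided one-sample t-test.
#'
#' @param method1,method2 Paired measurements (l), equal length >= 3.
#'   Differences are taken `method1 - method2`.
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `ULA`,
#'   `LLA` (upper/lower limit of agreement), `bias_p_value` (NA when the
#'   differences are constant), `n`, plus the stored `means` and `diffs`
#'   for plotting.
#' @export
#' @examples
#' ba <- bland_altman(c(3.1, 3.8, 4.2, 2.9), c(3.0, 4.0, 4.1, 3.1))
#' ba$ULA - ba$bias  # 1.96 * sd of differences
bland_altman <- function(method1, method2) {
  if (length(method1) != length(method2))
    stop_data("method1 and method2 must have equal length")
  if (length(method1) < 3) stop_data("at least 3 paired observations are required")
  d <- method1 - method2
  bias <- mean(d)
  sdd <- sd(d)
  # numerically constant differences: no dispersion to test the bias against
  p <- if (sdd <= 1e-10 * max(abs(bias), 1)) NA_real_ else t.test(d)$p.value
  structure(list(bias = bias, sd_diff = sdd,
                 ULA = bias + 1.96 * sdd, LLA = bias - 1.96 * sdd,
                 bias_p_value = p, n = length(d),
                 means = (method1 + method2) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.3f l (p = %s), SD of differences %.3f l\n",
              x$bias, ifelse(is.na(x$bias_p_value), "NA",
                             format.pval(x$bias_p_value, digits = 3)),
              x$sd_diff))
  cat(sprintf("  limits of agreement: LLA %.3f, ULA %.3f l\n", x$LLA, x$ULA))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, main = "Bland-Altman agreement",
                              xlab = "Mean of methods (l)",
                              ylab = "Difference (l)", ...) {
  ylim <- range(c(x$diffs, x$ULA, x$LLA))
  plot(x$means, x$diffs, pch = 19, main = main, xlab = xlab, ylab = ylab,
       ylim = ylim + c(-0.1, 0.1) * diff(ylim), ...)
  abline(h = x$bias, lwd = 2)
  abline(h = c(x$ULA, x$LLA), lty = 2)
  xpos <- max(x$means)
  text(xpos, x$ULA, sprintf("ULA = %.2f", x$ULA), pos = 3, cex = 0.8, adj = 1)
  text(xpos, x$LLA, sprintf("LLA = %.2f", x$LLA), pos = 1, cex = 0.8, adj = 1)
  invisible(x)
}

#' Correlation table between photogrammetric and spirometric measures
#'
#' @param photo Data frame of photogrammetric quantities (e.g. compartment
#'   volumes per phase, mobility), one row per subject.
#' @param spiro Data frame of spirometric outcomes (FEV1, FVC, PEF, DI),
#'   one row per subject.
#' @return Matrix of Pearson r, photogrammetric variables in rows.
#' @export
correlation_table <- function(photo, spiro) {
  if (nrow(photo) != nrow(spiro)) stop_data("row counts differ")
  out <- matrix(NA_real_, nrow = ncol(photo), ncol = ncol(spiro),
                dimnames = list(names(photo), names(spiro)))
  for (i in seq_len(ncol(photo)))
    for (j in seq_len(ncol(spiro)))
      out[i, j] <- pearson_r(photo[[i]], spiro[[j]])
  out
}

#' Cohort summary table
#'
#' Mean, SD (n - 1 denominator), minimum and maximum of every numeric
#' variable, in the standard reporting order: anthropometrics, pulmonary
#' function, then photogrammetric volumes by phase.
#'
#' @param subjects Data frame of anthropometrics (and optionally
#'   spirometry columns `FEV1_l`, `FVC_l`, `PEF_l_s`, `DI_l`), one row per
#'   subject.
#' @param volumes Optional long data frame of compartment volumes with
#'   columns `phase` and the volume columns `UT_l` ... `thoracoabdominal_l`.
#' @return Data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_cohort <- function(subjects, volumes = NULL) {
  if (is.null(subjects) || nrow(subjects) == 0) stop_data("empty cohort")
  one <- function(v, name) {
    v <- v[is.finite(v)]
    data.frame(variable = name, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  rows <- list()
  order1 <- c("age", "body_mass_kg", "height_m", "bmi", "thorax_cm",
              "FEV1_l", "FVC_l", "PEF_l_s", "DI_l")
  for (nm in intersect(order1, names(subjects)))
    rows[[length(rows) + 1]] <- one(subjects[[nm]], nm)
  for (nm in setdiff(names(subjects)[vapply(subjects, is.numeric, logical(1))],
                     c(order1, "mm_per_px")))
    rows[[length(rows) + 1]] <- one(subjects[[nm]], nm)
  if (!is.null(volumes)) {
    vcols <- intersect(c("UT_l", "LT_l", "TT_l", "UA_l", "LA_l", "TA_l",
                         "thoracoabdominal_l", "mobility_l"), names(volumes))
    for (ph in c("expiration", "inspiration")) {
      sub <- volumes[volumes$phase == ph, , drop = FALSE]
      if (nrow(sub) == 0) next
      for (nm in vcols) {
        v <- sub[[nm]]
        if (all(!is.finite(v))) next
        rows[[length(rows) + 1]] <- one(v, paste0(ph, ".", nm))
      }
    }
  }
  do.call(rbind, rows)
}
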