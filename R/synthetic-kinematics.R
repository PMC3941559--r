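# reference compartment structure used by the inverse model: expiration
# volume proportions and inspiration-expiration increment proportions of
# the reference cohort (UT, LT, UA, LA order)
ref_compartment_structure <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- reference_cohort_summary()
      g <- function(section) vapply(c("UT", "LT", "UA", "LA"), function(v)
        ref$mean[ref$section == section & ref$variable == v], numeric(1))
      e <- g("expiration"); i <- g("inspiration")
      cache <<- list(exp_prop = e / sum(e), delta_prop = (i - e) / sum(i - e),
                     exp_total = ref$mean[ref$section == "expiration" &
                                            ref$variable == "thoracoabdominal"])
    }
    cache
  }
})

#' Ground-truth marker kinematics for a synthetic subject
#'
#' Inverse kinematic model: given a subject and a target total volumetric
#' mobility, places the five markers at expiration and inspiration so that
#' the package's own forward volumetry reproduces the target exactly.
#'
#' Expiration compartment volumes are proportioned as in the reference
#' cohort (with a small seeded log-normal jitter) and scaled with body
#' size (height squared times thorax length relative to the cohort means).
#' The mobility is distributed over compartments proportionally to the
#' cohort's compartment-wise inspiration-expiration increments (greatest
#' recruitment in the lower thorax and upper thorax). Between phases only
#' marker heights change; craniocaudal x positions are fixed, reflecting
#' supine breathing in which the anterior wall moves essentially
#' perpendicular to the bed.
#'
#' @param subject A `subject_spec`.
#' @param target_mobility Target inspiration-expiration thoracoabdominal
#'   volume difference, litres (>= 0).
#' @param rng_seed Integer seed controlling the proportion jitter; `NULL`
#'   gives the unjittered reference proportions.
#' @return Object of class `kinematic_truth`: list with `marker_exp` and
#'   `marker_insp` ([marker_set]s, cm), `true_volumes_exp`,
#'   `true_volumes_insp` (`compartment_volumes`) and `true_mobility` (l).
#' @export
#' @examples
#' s <- sample_subject(rng_seed = 1)
#' kt <- make_kinematics(s, target_mobility = 3.75)
#' kt$true_mobility
make_kinematics <- function(subject, target_mobility, rng_seed = NULL) {
  if (!inherits(subject, "subject_spec")) stop_data("subject must be a subject_spec")
  if (!is.numeric(target_mobility) || length(target_mobility) != 1 ||
      !is.finite(target_mobility) || target_mobility < 0)
    stop_usage("target_mobility must be a single non-negative number (l)")

  st <- ref_compartment_structure()
  jit <- with_rng(rng_seed, list(e = exp(rnorm(4, 0, 0.02)), d = exp(rnorm(4, 0, 0.02))))
  p_exp <- st$exp_prop * jit$e; p_exp <- p_exp / sum(p_exp)
  p_del <- st$delta_prop * jit$d; p_del <- p_del / sum(p_del)

  th <- subject$thorax_length
  total_exp <- st$exp_total * (subject$height / 1.66)^2 * (th / 25.5)
  A <- 1000 * total_exp * p_exp / th           # expiration profile areas, cm^2
  dA <- 1000 * target_mobility * p_del / th    # area increments, cm^2

  # landmark x spacing: widths proportional to A^0.85 over a span scaling
  # with stature, so compartment mean heights vary gently and stay positive
  span <- 40 * subject$height / 1.66
  w <- span * A^0.85 / sum(A^0.85)
  x <- c(0, cumsum(w))

  solve_heights <- function(areas, y1) {
    y <- numeric(5); y[1] <- y1
    for (i in 1:4) y[i + 1] <- 2 * areas[i] / w[i] - y[i]
    y
  }
  y_exp <- solve_heights(A, A[1] / w[1])
  dy1 <- dA[1] / w[1]
  y_insp <- solve_heights(A + dA, y_exp[1] + dy1)
  if (any(y_exp <= 0) || any(y_insp <= 0))
    stop_geometry("invalid configuration: target mobility/anthropometry would place a marker at or below the support surface")

  me <- marker_set(x, y_exp, source = "manual")
  mi <- marker_set(x, y_insp, source = "manual")
  ve <- markers_to_volumes(me, th)
  vi <- markers_to_volumes(mi, th)
  structure(list(marker_exp = me, marker_insp = mi,
                 true_volumes_exp = ve, true_volumes_insp = vi,
                 true_mobility = vi[["thoracoabdominal"]] - ve[["thoracoabdominal"]]),
            class = "kinematic_truth")
}

#' @export
print.kinematic_truth <- function(x, ...) {
  cat(sprintf("Kinematic truth: expiration %.2f l, inspiration %.2f l, mobility %.3f l\n",
              x$true_volumes_exp[["thoracoabdominal"]],
              x$true_volumes_insp[["thoracoabdominal"]], x$true_mobility))
  invisible(x)
}
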