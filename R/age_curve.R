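#' Age-indexed parameter curve
#'
#' Several natural-history transition probabilities are reported only at a
#' handful of anchor ages (30, 50, 70 and 100 years). An `age_curve` stores
#' those anchors and is evaluated at intermediate ages by piecewise-linear
#' interpolation, which is exact at every anchor.
#'
#' @param ages Numeric vector of anchor ages in years, strictly increasing.
#' @param values Numeric vector of annual probabilities (or rates) at the
#'   anchor ages; must lie in `[0, 1]` when `probability = TRUE`.
#' @param probability Logical; enforce the `[0, 1]` range (default `TRUE`).
#'
#' @return An object of class `age_curve`.
#' @examples
#' onset <- age_curve(c(30, 50, 70, 100), c(0.021, 0.020, 0.045, 0.011))
#' interpolate_age_curve(onset, 60)
#' @export
age_curve <- function(ages, values, probability = TRUE) {
  stopifnot(is.numeric(ages), is.numeric(values), length(ages) == length(values),
            length(ages) >= 1L)
  if (any(!is.finite(ages)) || any(!is.finite(values)))
    stop("age_curve anchors must be finite")
  if (is.unsorted(ages, strictly = TRUE))
    stop("age_curve anchor ages must be strictly increasing")
  if (probability && (any(values < 0) || any(values > 1)))
    stop("age_curve probabilities must lie in [0, 1]")
  structure(list(ages = as.numeric(ages), values = as.numeric(values)),
            class = "age_curve")
}

#' Evaluate an age curve by piecewise-linear interpolation
#'
#' Exact at anchors; linear between bracketing anchors. Ages outside the
#' anchor range raise an error unless `rule = "clamp"`, in which case the
#' nearest anchor value is returned (used for the gFOBT specificity curve,
#' which is only anchored at ages 50 and 70).
#'
#' @param curve An [age_curve()].
#' @param age Numeric vector of ages in years.
#' @param rule `"error"` (default) or `"clamp"` for out-of-range ages.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_age_curve <- function(curve, age, rule = c("error", "clamp")) {
  stopifnot(inherits(curve, "age_curve"), is.numeric(age))
  rule <- match.arg(rule)
  lo <- curve$ages[1L]; hi <- curve$ages[length(curve$ages)]
  if (rule == "error" && (any(age < lo) || any(age > hi)))
    stop(sprintf("age out of range [%g, %g] for age_curve", lo, hi))
  if (length(curve$ages) == 1L) return(rep(curve$values, length(age)))
  stats::approx(curve$ages, curve$values, xout = pmin(pmax(age, lo), hi),
                method = "linear", rule = 2)$y
}

#' @export
print.age_curve <- function(x, ...) {
  cat("age_curve with", length(x$ages), "anchors\n")
  print(stats::setNames(x$values, x$ages))
  invisible(x)
}
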