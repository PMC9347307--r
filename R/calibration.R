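#' Fit the film calibration curve from co-exposed standards
#'
#' Builds the monotone piecewise-linear interpolant through the
#' `(optical density, activity)` pairs of the calibration standards.
#' Replicate standards at the same activity are averaged first. The curve is
#' exactly invertible at its knots and avoids the overshoot of polynomial
#' fits; a zero-activity standard folds film fog into the curve itself, so no
#' separate background subtraction is applied downstream.
#'
#' @param standards data frame with columns `activity_nCi_per_g` and `od`
#'   (or `activity`/`od`).
#' @param policy behaviour outside the fitted OD domain: `"error"` (reject),
#'   `"clamp"` (return the boundary activity) or `"linear_flagged"` (continue
#'   the boundary segment linearly). All out-of-domain conversions are
#'   flagged as extrapolated.
#' @return An object of class `calibration_curve` with knots, domain and
#'   policy.
#' @export
fit_calibration <- function(standards,
                            policy = c("linear_flagged", "clamp", "error")) {
  policy <- match.arg(policy)
  if (!is.data.frame(standards)) standards <- as.data.frame(standards)
  act_col <- intersect(c("activity_nCi_per_g", "activity"), names(standards))[1]
  if (is.na(act_col) || !"od" %in% names(standards)) {
    stop("standards must have columns 'activity_nCi_per_g' (or 'activity') and 'od'",
         call. = FALSE)
  }
  act <- standards[[act_col]]
  od <- standards[["od"]]
  if (any(!is.finite(act)) || any(act < 0) || any(!is.finite(od)) || any(od < 0)) {
    stop("standards must have finite non-negative activity and od", call. = FALSE)
  }
  # average replicates at the same activity
  agg <- stats::aggregate(list(od = od), by = list(activity = act), FUN = mean)
  agg <- agg[order(agg$activity), ]
  if (nrow(agg) < 3L) {
    stop("need at least 3 distinct standard activities to fit a calibration curve",
         call. = FALSE)
  }
  dmono <- diff(agg$od)
  if (any(dmono <= 0)) {
    i <- which(dmono <= 0)[1]
    stop(sprintf(paste0("standards are not strictly monotone: activity %g (od %g) ",
                        "vs activity %g (od %g)"),
                 agg$activity[i], agg$od[i], agg$activity[i + 1], agg$od[i + 1]),
         call. = FALSE)
  }
  structure(
    list(knots = data.frame(od = agg$od, activity = agg$activity),
         domain = range(agg$od), policy = policy),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Film calibration curve: %d knots, OD domain [%.4g, %.4g], policy '%s'\n",
              nrow(x$knots), x$domain[1], x$domain[2], x$policy))
  invisible(x)
}

#' Convert optical density to tissue 14C concentration
#'
#' Evaluates the piecewise-linear calibration curve. Values outside the
#' fitted OD domain are handled per the curve's extrapolation policy and
#' flagged in the `extrapolated` attribute of the result.
#'
#' @param curve a [fit_calibration()] object.
#' @param od optical density value(s).
#' @return Numeric activities in nCi/g with a logical attribute
#'   `extrapolated` marking out-of-domain conversions.
#' @export
od_to_activity <- function(curve, od) {
  stopifnot(inherits(curve, "calibration_curve"))
  k <- curve$knots
  lo <- od < curve$domain[1]
  hi <- od > curve$domain[2]
  out <- numeric(length(od))
  inside <- !(lo | hi)
  if (any(inside)) {
    out[inside] <- stats::approx(k$od, k$activity, xout = od[inside],
                                 ties = "ordered")$y
  }
  if (any(lo | hi)) {
    if (curve$policy == "error") {
      stop(sprintf("OD %s outside calibration domain [%.4g, %.4g]",
                   paste(signif(od[lo | hi], 6), collapse = ", "),
                   curve$domain[1], curve$domain[2]), call. = FALSE)
    }
    n <- nrow(k)
    if (curve$policy == "clamp") {
      out[lo] <- k$activity[1]
      out[hi] <- k$activity[n]
    } else {                             # linear_flagged
      slope_lo <- (k$activity[2] - k$activity[1]) / (k$od[2] - k$od[1])
      slope_hi <- (k$activity[n] - k$activity[n - 1]) / (k$od[n] - k$od[n - 1])
      out[lo] <- k$activity[1] + slope_lo * (od[lo] - k$od[1])
      out[hi] <- k$activity[n] + slope_hi * (od[hi] - k$od[n])
    }
  }
  attr(out, "extrapolated") <- lo | hi
  out
}
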