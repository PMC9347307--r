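#' Film response models
#'
#' A film response maps tissue (or standard) 14C concentration in nCi/g to
#' optical density on the developed autoradiogram. [hill_film()] is a
#' saturating Hill-type characteristic `OD = od_max * a / (a + K)` — film
#' blackening rises steeply at low exposure and saturates at `od_max`.
#' [identity_film()] returns the activity unchanged (OD numerically equal to
#' nCi/g), the transparent response used for exact pipeline checks.
#'
#' @param od_max saturation optical density (dimensionless), default 2.
#' @param K activity at half-saturation in nCi/g, default 4000. The default
#'   places the working range (0 to ~5000 nCi/g) below ~56% of saturation,
#'   matching a film exposed inside its dynamic range.
#' @return A function `activity -> OD` of class `film_response`, carrying a
#'   `params` attribute used by the simulator manifest.
#' @export
hill_film <- function(od_max = 2, K = 4000) {
  check_number(od_max, "od_max", lower = 0, allow_equal_lower = FALSE)
  check_number(K, "K", lower = 0, allow_equal_lower = FALSE)
  f <- function(activity) od_max * activity / (activity + K)
  structure(f, class = "film_response",
            params = list(type = "hill", od_max = od_max, K = K))
}

#' @rdname hill_film
#' @export
identity_film <- function() {
  structure(function(activity) activity, class = "film_response",
            params = list(type = "identity"))
}

#' Default calibration standards set
#'
#' Fourteen graded 14C activity levels (nCi/g) including a zero (blank/fog)
#' step, spaced approximately uniformly in optical density under the default
#' [hill_film()] so that the piecewise-linear calibration curve inverts the
#' film accurately across the whole span. Mirrors the ~14-step graded strips
#' of commercial 14C autoradiography microscales.
#'
#' @return Numeric vector of activities in nCi/g.
#' @export
default_standards <- function() {
  c(0, 30, 60, 110, 200, 340, 560, 860, 1250, 1750, 2400, 3100, 4000, 5000)
}
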