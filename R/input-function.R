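#' Continuous arterial input-function model
#'
#' Models the time course of labelled leucine activity `C*p(t)` (nCi/mL) and
#' total plasma leucine `Cp(t)` (nmol/mL) after an intravenous tracer bolus.
#' The specific activity `C*p(t)/Cp(t)` is the integrand of the operational
#' equation's input integral.
#'
#' Two shapes are available:
#' \describe{
#'   \item{`biexponential`}{`C*p(t) = amplitude * (exp(-decay_rate*t) -
#'     exp(-rise_rate*t))`, the standard two-rate description of an IV bolus
#'     (fast mixing, slow clearance). Requires `rise_rate > decay_rate > 0`.
#'     The peak occurs at `log(rise/decay)/(rise - decay)`.}
#'   \item{`gamma_variate`}{a gamma-variate bolus normalized so its peak value
#'     equals `amplitude`, with shape `rise_rate/decay_rate` and rate
#'     `decay_rate`.}
#' }
#'
#' For the gamma variate, `C*p(t) = amplitude * (t/tp)^a * exp(a*(1 - t/tp))`
#' with `a = rise_rate/decay_rate` and peak time `tp = a/decay_rate`.
#'
#' Plasma leucine `Cp` is constant when `leucine_conc` is a single value; a
#' length-2 value `c(start, end)` applies a linear drift across `[0, t_end]`
#' (both endpoints must be positive).
#'
#' @param shape `"biexponential"` (default) or `"gamma_variate"`.
#' @param amplitude positive scale of `C*p` in nCi/mL (coefficient for the
#'   biexponential, peak value for the gamma variate).
#' @param rise_rate,decay_rate rate constants in 1/min.
#' @param leucine_conc plasma leucine in nmol/mL; length 1 (constant) or
#'   2 (linear drift over `[0, t_end]`).
#' @param t_end end of the modelled interval in minutes.
#'
#' @return An object of class `input_function`: a list with component
#'   functions `cpstar(t)`, `cp(t)`, `sa(t)` (specific activity, nCi/nmol)
#'   and the parameter list `params`.
#'
#' @examples
#' fn <- input_function()
#' fn$cpstar(0)        # 0: no tracer before injection
#' fn$sa(5)            # specific activity at 5 min
#' @export
input_function <- function(shape = c("biexponential", "gamma_variate"),
                           amplitude = 2000, rise_rate = 1.0, decay_rate = 0.05,
                           leucine_conc = 137, t_end = 60) {
  shape <- match.arg(shape)
  check_number(amplitude, "amplitude", lower = 0, allow_equal_lower = FALSE)
  check_number(rise_rate, "rise_rate", lower = 0, allow_equal_lower = FALSE)
  check_number(decay_rate, "decay_rate", lower = 0, allow_equal_lower = FALSE)
  check_number(t_end, "t_end", lower = 0, allow_equal_lower = FALSE)
  if (shape == "biexponential" && rise_rate <= decay_rate) {
    stop("'rise_rate' must exceed 'decay_rate' for the biexponential bolus",
         call. = FALSE)
  }
  if (!is.numeric(leucine_conc) || !length(leucine_conc) %in% c(1L, 2L) ||
      any(leucine_conc <= 0)) {
    stop("'leucine_conc' must be one or two positive values (nmol/mL)",
         call. = FALSE)
  }

  cpstar <- switch(shape,
    biexponential = function(t) {
      amplitude * (exp(-decay_rate * t) - exp(-rise_rate * t))
    },
    gamma_variate = {
      a <- rise_rate / decay_rate
      tp <- a / decay_rate
      function(t) {
        out <- numeric(length(t))
        pos <- t > 0
        out[pos] <- amplitude * (t[pos] / tp)^a * exp(a * (1 - t[pos] / tp))
        out
      }
    })

  cp <- if (length(leucine_conc) == 1L) {
    function(t) rep(leucine_conc, length(t))
  } else {
    function(t) leucine_conc[1] + (leucine_conc[2] - leucine_conc[1]) * t / t_end
  }

  structure(
    list(cpstar = cpstar, cp = cp, sa = function(t) cpstar(t) / cp(t),
         params = list(shape = shape, amplitude = amplitude,
                       rise_rate = rise_rate, decay_rate = decay_rate,
                       leucine_conc = leucine_conc, t_end = t_end)),
    class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  p <- x$params
  cat("Arterial input function (", p$shape, ")\n", sep = "")
  cat(sprintf("  amplitude %g nCi/mL, rise %g /min, decay %g /min, t_end %g min\n",
              p$amplitude, p$rise_rate, p$decay_rate, p$t_end))
  cat(sprintf("  plasma leucine: %s nmol/mL\n",
              paste(p$leucine_conc, collapse = " -> ")))
  invisible(x)
}

#' Default arterial sampling schedule
#'
#' Ten timed draws over 60 min with dense early coverage of the bolus peak:
#' 0.25, 0.5, 1, 2, 5, 10, 20, 30, 45, 60 min.
#'
#' @return Numeric vector of sample times in minutes.
#' @export
plasma_schedule <- function() c(0.25, 0.5, 1, 2, 5, 10, 20, 30, 45, 60)

#' Draw timed arterial plasma samples from a continuous input function
#'
#' Evaluates the input function at the requested times and applies independent
#' multiplicative lognormal measurement noise (unit mean, coefficient of
#' variation `noise_cv`) to the activity and concentration channels.
#'
#' @param fn an [input_function()].
#' @param times strictly increasing sample times in `[0, t_end]` (minutes).
#' @param noise_cv measurement coefficient of variation (0 = noise free).
#' @param seed optional integer; when given, sampling is reproducible and does
#'   not disturb the caller's RNG stream.
#' @param subject_id identifier stored on the returned table.
#'
#' @return A `data.frame` of class `plasma_timecourse` with columns
#'   `time_min`, `cpstar_nCi_per_mL`, `cp_nmol_per_mL`, and attributes
#'   `subject_id` and `T` (the terminal time, `t_end` of `fn`).
#' @export
sample_plasma <- function(fn, times = plasma_schedule(), noise_cv = 0,
                          seed = NULL, subject_id = "s1") {
  stopifnot(inherits(fn, "input_function"))
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  check_number(times, "times", lower = 0, upper = fn$params$t_end,
               len = length(times))
  check_number(noise_cv, "noise_cv", lower = 0)
  act <- fn$cpstar(times)
  conc <- fn$cp(times)
  if (noise_cv > 0) {
    with_seed(seed, {
      act <- act * rlnorm_cv(length(act), noise_cv)
      conc <- conc * rlnorm_cv(length(conc), noise_cv)
    })
  }
  out <- data.frame(time_min = times,
                    cpstar_nCi_per_mL = act,
                    cp_nmol_per_mL = conc)
  attr(out, "subject_id") <- subject_id
  attr(out, "T") <- fn$params$t_end
  class(out) <- c("plasma_timecourse", "data.frame")
  out
}

#' Quadrature value of the specific-activity integral
#'
#' Adaptive quadrature of `C*p(t)/Cp(t)` over `[0, T]` on the continuous
#' input function; the reference value that sampled-table trapezoid
#' integration approximates.
#'
#' @param fn an [input_function()].
#' @param T upper limit in minutes (defaults to the function's `t_end`).
#' @return Integral in nCi*min/nmol.
#' @export
sa_integral <- function(fn, T = NULL) {
  stopifnot(inherits(fn, "input_function"))
  T <- T %||% fn$params$t_end
  check_number(T, "T", lower = 0, upper = fn$params$t_end,
               allow_equal_lower = FALSE)
  stats::integrate(fn$sa, 0, T, rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Forward kinetic model: tissue labelling from a known synthesis rate
#'
#' Inverts the operational equation to generate the terminal tissue
#' concentration of labelled protein: `P* = R * lambda * integral(C*p/Cp)`,
#' with the integral taken by adaptive quadrature on the continuous input
#' function. `P*` is linear in both the rate and `lambda`.
#'
#' @param true_rcps synthesis rate(s) in nmol/g/min (vectorized).
#' @param lambda fraction of the tissue precursor pool derived from plasma,
#'   in (0, 1].
#' @param fn an [input_function()].
#' @param T terminal time in minutes (`<= t_end`).
#' @return Tissue labelled-protein concentration(s) in nCi/g.
#' @export
forward_label <- function(true_rcps, lambda, fn, T = NULL) {
  check_number(true_rcps, "true_rcps", lower = 0, len = length(true_rcps))
  check_number(lambda, "lambda", lower = 0, upper = 1, allow_equal_lower = FALSE)
  true_rcps * lambda * sa_integral(fn, T)
}
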