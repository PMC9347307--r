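#' Read a timed arterial plasma sample table
#'
#' Expects a CSV with (at least) the exact columns `time_min`,
#' `cpstar_nCi_per_mL` (labelled leucine activity concentration) and
#' `cp_nmol_per_mL` (total plasma leucine). Extra columns are tolerated.
#' Rows must be sorted by strictly increasing time; activities must be
#' non-negative and leucine concentrations strictly positive.
#'
#' @param path CSV file path.
#' @param subject_id identifier; defaults to the file name without extension.
#' @return A `plasma_timecourse` data frame (see [sample_plasma()]).
#' @export
read_plasma <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("plasma file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, check.names = FALSE)
  required <- c("time_min", "cpstar_nCi_per_mL", "cp_nmol_per_mL")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("plasma table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0L) stop("plasma table ", path, ": no samples", call. = FALSE)
  bad <- which(!is.finite(x$time_min) | x$time_min < 0)
  if (length(bad)) stop("plasma table ", path, ": invalid time at row ", bad[1],
                        call. = FALSE)
  nonmono <- which(diff(x$time_min) <= 0)
  if (length(nonmono)) {
    stop("plasma table ", path, ": sample times not strictly increasing at row ",
         nonmono[1] + 1L, call. = FALSE)
  }
  bad <- which(!is.finite(x$cpstar_nCi_per_mL) | x$cpstar_nCi_per_mL < 0)
  if (length(bad)) stop("plasma table ", path, ": negative or missing activity at row ",
                        bad[1], call. = FALSE)
  bad <- which(!is.finite(x$cp_nmol_per_mL) | x$cp_nmol_per_mL <= 0)
  if (length(bad)) stop("plasma table ", path, ": non-positive leucine concentration at row ",
                        bad[1], call. = FALSE)
  out <- x[, required]
  attr(out, "subject_id") <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  class(out) <- c("plasma_timecourse", "data.frame")
  out
}

#' Write a plasma time course as CSV
#' @param tc a `plasma_timecourse` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plasma <- function(tc, path) {
  utils::write.csv(as.data.frame(tc)[, c("time_min", "cpstar_nCi_per_mL",
                                         "cp_nmol_per_mL")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specific activity of a plasma sample
#'
#' Ratio of labelled leucine activity to total leucine concentration,
#' `C*p/Cp`, in nCi/nmol. Vectorized.
#'
#' @param cpstar activity concentration(s), nCi/mL.
#' @param cp leucine concentration(s), nmol/mL; must be positive.
#' @return Specific activity in nCi/nmol.
#' @export
sa_ratio <- function(cpstar, cp) {
  if (any(!is.finite(cp)) || any(cp <= 0)) {
    stop("'cp' must be strictly positive (division guard)", call. = FALSE)
  }
  cpstar / cp
}

#' Trapezoid integral of plasma specific activity over [0, T]
#'
#' Integrates the sampled ratio `C*p/Cp` by the trapezoidal rule. The curve
#' is anchored at `(0, 0)` when the first draw is after injection (no tracer
#' is present before the bolus), and the final observed ratio is carried flat
#' from the last sample to `T` when sampling stops early. If samples extend
#' beyond `T` the ratio is interpolated at `T` and later samples are dropped.
#'
#' @param tc a `plasma_timecourse` data frame.
#' @param T terminal time in minutes; defaults to the table's `T` attribute,
#'   falling back to the last sample time.
#' @param cp_mode `"per_sample"` (ratio formed sample by sample; default) or
#'   `"constant"` (divide activities by the mean sampled leucine
#'   concentration, the pooled-denominator convention).
#' @return The integral in nCi*min/nmol.
#' @export
integrate_sa <- function(tc, T = NULL, cp_mode = c("per_sample", "constant")) {
  cp_mode <- match.arg(cp_mode)
  t <- tc$time_min
  if (is.null(t) || length(t) == 0L) stop("no samples", call. = FALSE)
  T <- T %||% attr(tc, "T") %||% max(t)
  check_number(T, "T", lower = 0, allow_equal_lower = FALSE)
  if (T < t[1]) {
    stop(sprintf("terminal time T = %g precedes the first sample at %g min",
                 T, t[1]), call. = FALSE)
  }
  ratio <- switch(cp_mode,
    per_sample = sa_ratio(tc$cpstar_nCi_per_mL, tc$cp_nmol_per_mL),
    constant = sa_ratio(tc$cpstar_nCi_per_mL, mean(tc$cp_nmol_per_mL)))
  if (t[1] > 0) {            # tracer absent before injection
    t <- c(0, t)
    ratio <- c(0, ratio)
  }
  last <- max(t)
  if (last < T) {
    if (last < 0.9 * T) {
      warning(sprintf("last sample (%g min) covers less than 90%% of T = %g min; ",
                      last, T),
              "flat carry-forward may bias the integral", call. = FALSE)
    }
    t <- c(t, T)
    ratio <- c(ratio, ratio[length(ratio)])
  } else if (last > T) {
    rT <- stats::approx(t, ratio, xout = T)$y
    keep <- t < T
    t <- c(t[keep], T)
    ratio <- c(ratio[keep], rT)
  }
  trapz(t, ratio)
}
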