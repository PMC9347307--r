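#' Operational equation: rate of protein synthesis from tissue label
#'
#' `R = P* / (lambda * integral)` where `P*` is the terminal tissue
#' concentration of labelled protein (nCi/g), `integral` is the time integral
#' of plasma specific activity (nCi*min/nmol) and `lambda` is the fraction of
#' the tissue precursor leucine pool derived from plasma. Vectorized over
#' `pstar` and `integral`.
#'
#' @param pstar tissue labelled-protein concentration(s), nCi/g.
#' @param integral specific-activity integral(s), nCi*min/nmol; must be
#'   positive (no tracer delivered otherwise).
#' @param lambda precursor fraction in (0, 1]. The published value for this
#'   preparation is not reprinted here; the default 0.6 is a placeholder that
#'   every report echoes, and users should supply the value evaluated for
#'   their preparation.
#' @return Synthesis rate(s) in nmol/g/min.
#' @export
compute_rcps <- function(pstar, integral, lambda = 0.6) {
  check_number(pstar, "pstar", lower = 0, len = length(pstar))
  if (any(!is.finite(integral)) || any(integral <= 0)) {
    stop("'integral' must be strictly positive (no tracer delivered)",
         call. = FALSE)
  }
  check_number(lambda, "lambda", lower = 0, upper = 1, allow_equal_lower = FALSE)
  pstar / (lambda * integral)
}

#' Signed integer percent difference between group means
#'
#' `round(100 * (mean_mut - mean_wt) / mean_wt)`, rounded to the nearest
#' integer with ties away from zero — the convention that reproduces 22 of
#' the 23 printed differences in the reference table (the ventral
#' hippocampus row was evidently computed from unrounded means).
#' Unit-free and invariant to common rescaling of both means, hence also to
#' the choice of lambda and to any shared calibration factor.
#'
#' @param mean_wt reference (wild-type) mean(s); must be positive.
#' @param mean_mut comparison (mutant) mean(s).
#' @return Integer percent difference(s), negative for decreases.
#' @export
percent_difference <- function(mean_wt, mean_mut) {
  if (any(!is.finite(mean_wt)) || any(mean_wt <= 0)) {
    stop("'mean_wt' must be strictly positive", call. = FALSE)
  }
  round_half_away(100 * (mean_mut - mean_wt) / mean_wt)
}

#' Fit regional protein synthesis rates for a cohort
#'
#' The central estimator: joins each subject's plasma specific-activity
#' integral with that subject's per-region tissue measurements and applies
#' the operational equation, producing one rate per (subject, region).
#' Measurements flagged as extrapolated (outside the film calibration
#' domain) are excluded by default, mirroring the practice of dropping ROIs
#' whose autoradiograms cannot be quantified reliably.
#'
#' @param tissue data frame of tissue measurements with columns `subject`,
#'   `region`, `pstar_nCi_per_g` and optionally `extrapolated` (see
#'   [quantify_regions()]).
#' @param plasma named list of `plasma_timecourse` tables (names = subject
#'   ids), or a directory containing `<subject>.csv` plasma files.
#' @param subjects optional data frame `subject`, `genotype` (or other
#'   grouping columns) carried into summaries.
#' @param lambda precursor fraction in (0, 1].
#' @param T terminal time in minutes, passed to [integrate_sa()].
#' @param cp_mode denominator convention for the specific-activity ratio,
#'   see [integrate_sa()].
#' @param include_extrapolated keep flagged measurements instead of dropping
#'   them.
#' @param free_fraction fraction of the measured tissue signal attributed to
#'   free (unincorporated) tracer and subtracted before the operational
#'   equation. Default 0: fixation is assumed to wash out free tracer, and
#'   this parameter exists to expose that assumption.
#' @return An object of class `rcps_fit` with components `records`
#'   (subject, region, pstar, integral, lambda, rcps), `integrals`
#'   (per-subject), `subjects`, `lambda`, `T`, `n_excluded` and `call`.
#'   Methods: [print()], [summary.rcps_fit()], [coef.rcps_fit()],
#'   [plot.rcps_fit()].
#' @export
rcps_fit <- function(tissue, plasma, subjects = NULL, lambda = 0.6, T = 60,
                     cp_mode = c("per_sample", "constant"),
                     include_extrapolated = FALSE, free_fraction = 0) {
  cp_mode <- match.arg(cp_mode)
  check_number(lambda, "lambda", lower = 0, upper = 1, allow_equal_lower = FALSE)
  check_number(free_fraction, "free_fraction", lower = 0, upper = 1,
               allow_equal_upper = FALSE)
  check_number(T, "T", lower = 0, allow_equal_lower = FALSE)
  stopifnot(is.data.frame(tissue),
            all(c("subject", "region", "pstar_nCi_per_g") %in% names(tissue)))
  if (is.character(plasma) && length(plasma) == 1L) {
    files <- list.files(plasma, pattern = "\\.csv$", full.names = TRUE)
    plasma <- lapply(files, read_plasma)
    names(plasma) <- vapply(plasma, attr, "", "subject_id")
  }
  subj_ids <- unique(tissue$subject)
  orphan <- setdiff(subj_ids, names(plasma))
  if (length(orphan)) {
    stop("no plasma table for subject(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  integrals <- vapply(subj_ids, function(s) {
    integrate_sa(plasma[[s]], T = T, cp_mode = cp_mode)
  }, numeric(1))
  names(integrals) <- subj_ids

  n_excluded <- 0L
  if (!include_extrapolated && "extrapolated" %in% names(tissue)) {
    n_excluded <- sum(tissue$extrapolated)
    tissue <- tissue[!tissue$extrapolated, , drop = FALSE]
  }
  pstar_bound <- tissue$pstar_nCi_per_g * (1 - free_fraction)
  records <- data.frame(
    subject = tissue$subject,
    region = tissue$region,
    pstar = pstar_bound,
    integral = unname(integrals[tissue$subject]),
    lambda = lambda,
    rcps = compute_rcps(pstar_bound, unname(integrals[tissue$subject]), lambda),
    stringsAsFactors = FALSE)
  structure(
    list(records = records, integrals = integrals, subjects = subjects,
         lambda = lambda, T = T, cp_mode = cp_mode,
         free_fraction = free_fraction, n_excluded = n_excluded,
         call = match.call()),
    class = "rcps_fit")
}

#' @export
print.rcps_fit <- function(x, ...) {
  cat("Regional cerebral protein synthesis fit (operational equation)\n")
  cat(sprintf("  %d subjects x %d regions; lambda = %.3g, T = %g min (%s Cp)\n",
              length(x$integrals), length(unique(x$records$region)),
              x$lambda, x$T, x$cp_mode))
  cat(sprintf("  SA integrals: %.3g - %.3g nCi*min/nmol\n",
              min(x$integrals), max(x$integrals)))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d extrapolated measurement(s) excluded\n", x$n_excluded))
  }
  cat(sprintf("  rCPS range: %.3g - %.3g nmol/g/min\n",
              min(x$records$rcps), max(x$records$rcps)))
  invisible(x)
}

#' Extract the subject-by-region rate matrix
#' @param object an `rcps_fit`.
#' @param ... unused.
#' @return Numeric matrix, subjects in rows, regions in columns (nmol/g/min).
#' @export
coef.rcps_fit <- function(object, ...) {
  r <- object$records
  regions <- unique(r$region)
  subj <- unique(r$subject)
  m <- matrix(NA_real_, length(subj), length(regions),
              dimnames = list(subj, regions))
  m[cbind(match(r$subject, subj), match(r$region, regions))] <- r$rcps
  m
}

#' Genotype comparison of fitted regional rates
#'
#' Per-region group means +/- SEM with per-cell n, integer percent
#' differences, Bonferroni-corrected Welch t tests, and the mixed-design
#' ANOVA (group as between-subject factor, region as within-subject factor).
#'
#' @param object an `rcps_fit` whose `subjects` table carries the grouping
#'   column.
#' @param group name of the grouping column (default `"genotype"`).
#' @param ref reference level for percent differences (default `"WT"`, else
#'   the first level encountered).
#' @param m number of comparisons for the Bonferroni correction; defaults to
#'   the number of regions fitted.
#' @param var.equal use the pooled-variance t test instead of Welch.
#' @param min_n regions entering the mixed ANOVA need at least this many
#'   subjects per group (complete-case policy; default 3).
#' @param ... unused.
#' @return An object of class `summary.rcps_fit` with components
#'   `comparison` (one row per region), `anova`, `lambda`, `m`, `policy`.
#' @export
summary.rcps_fit <- function(object, group = "genotype", ref = "WT",
                             m = NULL, var.equal = FALSE, min_n = 3, ...) {
  if (is.null(object$subjects) || !group %in% names(object$subjects)) {
    stop("the fit carries no '", group,
         "' metadata; pass 'subjects' to rcps_fit()", call. = FALSE)
  }
  r <- merge(object$records, object$subjects, by = "subject")
  levels_g <- unique(r[[group]])
  if (length(levels_g) != 2L) {
    stop("group comparison requires exactly 2 levels, got ",
         length(levels_g), call. = FALSE)
  }
  if (!ref %in% levels_g) ref <- levels_g[1]
  other <- setdiff(levels_g, ref)
  regions <- unique(r$region)
  m <- m %||% length(regions)

  cells <- summarize_groups(r, value = "rcps", by = c("region", group))
  ph <- posthoc_bonferroni(r, value = "rcps", between = group, within = "region",
                           m = m, var.equal = var.equal, ref = ref)
  comparison <- do.call(rbind, lapply(regions, function(rg) {
    a <- cells[cells$region == rg & cells[[group]] == ref, ]
    b <- cells[cells$region == rg & cells[[group]] == other, ]
    p <- ph[ph$cell == rg, ]
    data.frame(region = rg,
               wt_mean = a$mean, wt_sem = a$sem, n_wt = a$n,
               mut_mean = b$mean, mut_sem = b$sem, n_mut = b$n,
               pct_diff = percent_difference(a$mean, b$mean),
               t = if (nrow(p)) p$t else NA_real_,
               p_raw = if (nrow(p)) p$p_raw else NA_real_,
               p_bonferroni = if (nrow(p)) p$p_adj else NA_real_,
               stringsAsFactors = FALSE)
  }))
  an <- tryCatch(
    mixed_anova(r, value = "rcps", between = group, within = "region",
                subject = "subject", min_n = min_n),
    error = function(e) {
      warning("mixed ANOVA unavailable: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  structure(list(comparison = comparison, anova = an, lambda = object$lambda,
                 m = m, ref = ref,
                 policy = sprintf("complete-case regions with >= %d per group; Bonferroni m = %d; %s t",
                                  min_n, m, if (var.equal) "pooled" else "Welch")),
            class = "summary.rcps_fit")
}

#' @export
print.summary.rcps_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Regional rCPS group comparison (lambda = %.3g, reference = %s)\n",
              x$lambda, x$ref))
  cat(" ", x$policy, "\n\n")
  cmp <- x$comparison
  out <- data.frame(
    region = cmp$region,
    ref = sprintf("%.2f ± %.2f (n=%d)", cmp$wt_mean, cmp$wt_sem, cmp$n_wt),
    other = sprintf("%.2f ± %.2f (n=%d)", cmp$mut_mean, cmp$mut_sem, cmp$n_mut),
    `diff%` = cmp$pct_diff,
    p_bonf = signif(cmp$p_bonferroni, digits),
    check.names = FALSE)
  print(out, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("\nMixed-design ANOVA:\n")
    print(format_anova(x$anova), row.names = FALSE)
  }
  invisible(x)
}

#' Plot fitted regional rates by group
#'
#' Dot-and-error-bar chart of per-region group means +/- SEM, the visual
#' analogue of the comparison table. Base graphics.
#'
#' @param x an `rcps_fit`.
#' @param group grouping column in the fit's subject table (default
#'   `"genotype"`; ignored when no metadata is present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.rcps_fit <- function(x, group = "genotype", ...) {
  r <- x$records
  has_group <- !is.null(x$subjects) && group %in% names(x$subjects)
  if (has_group) {
    r <- merge(r, x$subjects, by = "subject")
    cells <- summarize_groups(r, value = "rcps", by = c("region", group))
    gl <- unique(cells[[group]])
  } else {
    cells <- summarize_groups(r, value = "rcps", by = "region")
    cells$.g <- "all"; group <- ".g"; gl <- "all"
  }
  regions <- unique(cells$region)
  yi <- rev(seq_along(regions))
  graphics::plot(NA, xlim = c(0, max(cells$mean + ifelse(is.na(cells$sem), 0, cells$sem)) * 1.05),
                 ylim = range(yi) + c(-0.5, 0.5), yaxt = "n",
                 xlab = "rCPS (nmol/g/min)", ylab = "", ...)
  graphics::axis(2, at = yi, labels = regions, las = 2, cex.axis = 0.6)
  for (k in seq_along(gl)) {
    cc <- cells[cells[[group]] == gl[k], ]
    idx <- match(cc$region, regions)
    off <- (k - (length(gl) + 1) / 2) * 0.2
    graphics::points(cc$mean, yi[idx] + off, pch = c(16, 1, 17)[k], col = k + 1)
    ok <- !is.na(cc$sem) & cc$sem > 0
    if (any(ok)) {
      graphics::arrows(cc$mean[ok] - cc$sem[ok], yi[idx][ok] + off,
                       cc$mean[ok] + cc$sem[ok], yi[idx][ok] + off,
                       angle = 90, code = 3, length = 0.02, col = k + 1)
    }
  }
  if (length(gl) > 1) {
    graphics::legend("bottomright", legend = gl, col = seq_along(gl) + 1,
                     pch = c(16, 1, 17)[seq_along(gl)], bty = "n")
  }
  invisible(x)
}
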