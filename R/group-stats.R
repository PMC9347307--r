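# Group statistics for rCPS tables and normalized Western-intensity tables.
# The ANOVA fits go through stats::aov with an Error(subject) stratum for the
# within-subject factor (split-plot layout); the test suite cross-checks the
# F values against an independent cell-means sums-of-squares oracle.

# tidy one or more aov summary strata into (effect, F, df_num, df_den, p)
tidy_aov <- function(fit) {
  sm <- summary(fit)
  # aovlist (Error strata) vs plain aov
  strata <- if (inherits(fit, "aovlist")) sm else list(sm)
  rows <- list()
  for (st in strata) {
    tab <- as.data.frame(st[[1]])
    resid_df <- tab[trimws(rownames(tab)) == "Residuals", "Df"]
    for (i in seq_len(nrow(tab))) {
      eff <- trimws(rownames(tab)[i])
      if (eff == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", eff),
        F = tab[i, "F value"],
        df_num = tab[i, "Df"],
        df_den = if (length(resid_df)) resid_df else NA_real_,
        p = tab[i, "Pr(>F)"],
        order = lengths(regmatches(eff, gregexpr(":", eff))) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# report order used in the tables of this literature: highest-order
# interactions first, then lower interactions, main effects last
order_effects <- function(tab) {
  tab <- tab[order(-tab$order, seq_len(nrow(tab))), ]
  tab$order <- NULL
  rownames(tab) <- NULL
  tab
}

format_anova <- function(tab) {
  data.frame(effect = tab$effect,
             F = sprintf("F(%g,%g) = %.3f", tab$df_num, tab$df_den, tab$F),
             p = ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p)),
             stringsAsFactors = FALSE)
}

check_design <- function(data, value, factors, subject) {
  need <- c(value, factors, subject)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in factors) {
    if (length(unique(data[[f]])) < 2L) {
      stop("factor '", f, "' needs at least 2 levels", call. = FALSE)
    }
  }
}

#' Mixed-design (split-plot) ANOVA
#'
#' One between-subject factor crossed with one within-subject factor, the
#' design used for genotype x region analyses of regional synthesis rates.
#' Fits `value ~ between * within + Error(subject)` so the between effect is
#' tested against subject-to-subject variation and the within and
#' interaction effects against the within-subject residual. No sphericity
#' correction is applied (uncorrected degrees of freedom, as reported in
#' this literature); incomplete data are handled by a declared
#' complete-case policy: within levels observed in fewer than `min_n`
#' subjects per group are dropped, then subjects missing any remaining level
#' are dropped, and the policy applied is recorded in the `policy` attribute.
#'
#' @param data long-format data frame.
#' @param value,between,within,subject column names.
#' @param min_n minimum subjects per between-group cell for a within level
#'   to enter the ANOVA (default 3).
#' @return Data frame (effect, F, df_num, df_den, p), interaction first,
#'   with a `policy` attribute.
#' @export
mixed_anova <- function(data, value, between, within, subject, min_n = 3) {
  check_design(data, value, c(between, within), subject)
  data <- data[, c(value, between, within, subject)]
  names(data) <- c(".y", ".b", ".w", ".s")
  if (anyDuplicated(data[, c(".s", ".w")])) {
    stop("each (subject, within-level) pair may appear at most once",
         call. = FALSE)
  }
  # between level fixed per subject
  bs <- unique(data[, c(".s", ".b")])
  if (anyDuplicated(bs$.s)) {
    stop("a subject appears under more than one between-group level",
         call. = FALSE)
  }
  # missing-data policy
  cnt <- stats::aggregate(list(n = data$.s),
                          by = list(w = data$.w, b = data$.b),
                          FUN = function(s) length(unique(s)))
  nb <- length(unique(data$.b))
  ok_w <- tapply(cnt$n, cnt$w, min) >= min_n &
    tapply(cnt$b, cnt$w, function(b) length(unique(b))) == nb
  keep_w <- names(which(ok_w))
  dropped_w <- setdiff(unique(as.character(data$.w)), keep_w)
  data <- data[data$.w %in% keep_w, ]
  full <- table(data$.s)
  keep_s <- names(full)[full == length(keep_w)]
  dropped_s <- setdiff(unique(data$.s), keep_s)
  data <- data[data$.s %in% keep_s, ]
  if (length(unique(data$.w)) < 2L || length(unique(data$.b)) < 2L) {
    stop("fewer than 2 levels remain after the complete-case policy",
         call. = FALSE)
  }
  per_cell <- table(unique(data[, c(".s", ".b")])$.b)
  if (any(per_cell < 2L)) {
    stop("each between-group cell needs at least 2 subjects", call. = FALSE)
  }
  data$.b <- factor(data$.b); data$.w <- factor(data$.w)
  data$.s <- factor(data$.s)
  fit <- stats::aov(.y ~ .b * .w + Error(.s), data = data)
  tab <- tidy_aov(fit)
  tab$effect <- sub("\\.b", between, tab$effect)
  tab$effect <- sub("\\.w", within, tab$effect)
  tab <- order_effects(tab)
  attr(tab, "policy") <- sprintf(
    "complete-case: dropped %d within level(s) [%s], %d subject(s) [%s]; min_n = %d",
    length(dropped_w), paste(dropped_w, collapse = ","),
    length(dropped_s), paste(dropped_s, collapse = ","), min_n)
  tab
}

#' Factorial ANOVA for normalized Western-intensity tables
#'
#' Between-subject factors fully crossed (e.g. genotype x treatment), with an
#' optional within-subject factor (band or phosphorylation site) added as a
#' split-plot stratum. Effects are reported with the highest-order
#' interaction first and main effects last, the layout of the ANOVA tables
#' in this literature.
#'
#' @param data long-format data frame.
#' @param value response column name.
#' @param between character vector of between-subject factor columns.
#' @param within optional single within-subject factor column.
#' @param subject subject id column.
#' @return Data frame (effect, F, df_num, df_den, p).
#' @export
factorial_anova <- function(data, value, between, within = NULL, subject) {
  check_design(data, value, c(between, within), subject)
  cols <- c(value, between, within, subject)
  d <- data[, cols]
  bn <- paste0(".b", seq_along(between))
  names(d) <- c(".y", bn, if (!is.null(within)) ".w", ".s")
  for (f in c(bn, if (!is.null(within)) ".w")) d[[f]] <- factor(d[[f]])
  d$.s <- factor(d$.s)
  per_cell <- stats::aggregate(list(n = d$.s),
                               by = d[, bn, drop = FALSE],
                               FUN = function(s) length(unique(s)))
  if (any(per_cell$n < 2L)) {
    stop("each between-subject cell needs at least 2 subjects", call. = FALSE)
  }
  if (is.null(within)) {
    fit <- stats::aov(stats::as.formula(paste(".y ~", paste(bn, collapse = "*"))),
                      data = d)
  } else {
    if (anyDuplicated(d[, c(".s", ".w")])) {
      stop("each (subject, within-level) pair may appear at most once",
           call. = FALSE)
    }
    fit <- stats::aov(stats::as.formula(
      paste(".y ~", paste(c(bn, ".w"), collapse = "*"), "+ Error(.s)")),
      data = d)
  }
  tab <- tidy_aov(fit)
  for (i in seq_along(between)) {
    tab$effect <- gsub(bn[i], between[i], tab$effect, fixed = TRUE)
  }
  if (!is.null(within)) tab$effect <- gsub(".w", within, tab$effect, fixed = TRUE)
  order_effects(tab)
}

#' Bonferroni-corrected per-level two-sample t tests
#'
#' For each level of the within factor, a two-sample t test between the two
#' between-group levels (Welch by default), with `p_adj = min(1, m * p_raw)`.
#' `m` may exceed the number of tested levels (the full family size). Levels
#' with fewer than 2 subjects in either group are skipped with a warning,
#' mirroring the unequal per-region counts of film-quality-limited studies.
#' Degenerate levels where both groups are constant give `t = 0, p = 1` when
#' the means agree.
#'
#' @param data long-format data frame.
#' @param value,between,within column names; `between` must have exactly two
#'   levels.
#' @param m family size for the Bonferroni correction (default: number of
#'   within levels present).
#' @param var.equal pooled-variance t instead of Welch.
#' @param ref optional reference level of `between` (difference is
#'   other - ref).
#' @return Data frame (cell, n_ref, n_other, t, df, p_raw, p_adj, m).
#' @export
posthoc_bonferroni <- function(data, value, between, within, m = NULL,
                               var.equal = FALSE, ref = NULL) {
  check_design(data, value, c(between, within), subject = character(0))
  lv <- unique(as.character(data[[between]]))
  if (length(lv) != 2L) stop("'between' must have exactly 2 levels", call. = FALSE)
  if (!is.null(ref) && ref %in% lv) lv <- c(ref, setdiff(lv, ref))
  cells <- unique(as.character(data[[within]]))
  m <- m %||% length(cells)
  if (m < length(cells)) {
    stop("'m' must be at least the number of tested levels", call. = FALSE)
  }
  skipped <- character(0)
  rows <- lapply(cells, function(cl) {
    x <- data[data[[within]] == cl & data[[between]] == lv[2], value, drop = TRUE]
    y <- data[data[[within]] == cl & data[[between]] == lv[1], value, drop = TRUE]
    if (length(x) < 2L || length(y) < 2L) {
      skipped <<- c(skipped, cl)
      return(NULL)
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      same <- isTRUE(all.equal(mean(x), mean(y)))
      tt <- list(statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                 parameter = length(x) + length(y) - 2,
                 p.value = if (same) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = var.equal)
    }
    data.frame(cell = cl, n_ref = length(y), n_other = length(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, m * tt$p.value), m = m,
               stringsAsFactors = FALSE)
  })
  if (length(skipped)) {
    warning("skipped level(s) with < 2 subjects per group: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell = character(0), n_ref = integer(0),
                      n_other = integer(0), t = numeric(0), df = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0), m = integer(0))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Per-cell mean, SEM and n
#'
#' Summarizes a long table into the mean +/- SEM format of group-comparison
#' tables. SEM uses the n-1 standard deviation over subjects and is `NA` for
#' singleton cells.
#'
#' @param data long-format data frame.
#' @param value response column.
#' @param by character vector of grouping columns.
#' @return Data frame with the grouping columns plus `mean`, `sem`, `n`.
#' @export
summarize_groups <- function(data, value, by) {
  check_design(data, value, factors = character(0), subject = character(0))
  miss <- setdiff(by, names(data))
  if (length(miss)) stop("missing grouping column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(
    data[, value, drop = FALSE], by = data[, by, drop = FALSE],
    FUN = function(v) c(mean = mean(v),
                        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                        n = length(v)))
  stats_mat <- agg[[value]]
  out <- cbind(agg[, by, drop = FALSE],
               data.frame(mean = stats_mat[, "mean"], sem = stats_mat[, "sem"],
                          n = as.integer(stats_mat[, "n"])))
  rownames(out) <- NULL
  out
}
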