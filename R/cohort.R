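#' Published regional rCPS reference table (Tsc2+/- study)
#'
#' Group means, SEMs, per-region animal counts and printed integer percent
#' differences for 23 brain regions in wild-type versus Tsc2 heterozygous
#' mice, as reported in the study this package operationalizes. Used to seed
#' realistic synthetic cohorts (wild-type means and effect sizes) and as the
#' worked-example input for [percent_difference()].
#'
#' Note: per-region n varies (2-8) because the number of animals analyzed
#' depended on autoradiogram quality at each level; the ventral hippocampus
#' row prints -41 although the printed means give -40 under any standard
#' rounding (presumably computed from unrounded means).
#'
#' @return Data frame with columns `region`, `division`, `wt_mean`, `wt_sem`,
#'   `n_wt`, `het_mean`, `het_sem`, `n_het`, `pct_printed`, `p_printed`.
#' @export
tsc2_regions <- function() {
  df <- data.frame(
    region = c("frontal cortex", "parietal cortex", "auditory cortex",
               "visual cortex", "medial corpus callosum",
               "lateral corpus callosum", "anterodorsal thalamus",
               "paraventricular thalamus", "dorsomedial thalamus",
               "lateral dorsal thalamus", "medial geniculate",
               "ventral posterior thalamus", "suprachiasmatic nucleus",
               "paraventricular hypothalamus", "supraoptic nucleus",
               "basolateral amygdala", "dorsal hippocampus",
               "ventral hippocampus", "interpeduncular nucleus", "flocculus",
               "arbor vitae", "simple lobule", "culmen"),
    division = c(rep("cortex", 4), rep("corpus callosum", 2),
                 rep("thalamus", 6), rep("hypothalamus", 3), "amygdala",
                 rep("hippocampus", 2), rep("cerebellum", 5)),
    wt_mean = c(6.99, 8.73, 8.33, 8.85, 2.94, 3.31, 14.67, 13.94, 7.65, 7.39,
                7.87, 8.37, 10.25, 15.65, 18.09, 8.87, 7.08, 7.02, 9.05, 9.93,
                3.00, 10.13, 3.63),
    wt_sem = c(0.48, 0.50, 0.53, 0.75, 0.14, 0.18, 1.13, 1.59, 0.39, 0.48,
               0.60, 0.62, 0.82, 0.85, 1.67, 0.60, 0.39, 0.43, 0.62, 0.88,
               0.21, 0.86, 0.23),
    n_wt = c(8L, 7L, 5L, 6L, 8L, 8L, 5L, 6L, 6L, 6L, 4L, 8L, 5L, 8L, 6L, 8L,
             8L, 6L, 3L, 4L, 5L, 5L, 5L),
    het_mean = c(4.82, 5.50, 5.22, 5.37, 2.07, 2.22, 8.44, 9.15, 4.64, 4.50,
                 4.21, 5.41, 6.96, 9.97, 9.52, 5.66, 4.81, 4.18, 4.89, 4.01,
                 1.32, 5.43, 2.25),
    het_sem = c(0.32, 0.27, 0.30, 0.34, 0.12, 0.14, 0.86, 0.73, 0.40, 0.32,
                0.53, 0.36, 1.29, 1.09, 0.90, 0.36, 0.38, 0.27, 0.56, 0.44,
                0.14, 0.64, 0.09),
    n_het = c(5L, 5L, 5L, 4L, 5L, 5L, 4L, 4L, 3L, 4L, 5L, 5L, 4L, 5L, 4L, 5L,
              5L, 5L, 3L, 2L, 4L, 3L, 3L),
    pct_printed = c(-31L, -37L, -37L, -39L, -30L, -33L, -42L, -34L, -39L,
                    -39L, -47L, -35L, -32L, -36L, -47L, -36L, -32L, -41L,
                    -46L, -60L, -56L, -46L, -38L),
    p_printed = c("0.008", "<0.001", "<0.001", "0.001", "0.001", "0.001",
                  "<0.001", "0.011", "<0.001", "<0.001", "<0.001", "0.005",
                  "0.007", "0.002", "<0.001", "0.002", "0.002", "<0.001",
                  "<0.001", "<0.001", "<0.001", "<0.001", "<0.001"),
    stringsAsFactors = FALSE)
  df
}

#' Specify a synthetic two-genotype rCPS cohort
#'
#' Collects every parameter of the forward simulation: the regions and their
#' true wild-type rates, the per-region fractional decrease in the mutant,
#' group sizes, biological and measurement noise levels, the true precursor
#' fraction lambda, the input-function model, the sampling schedule, the film
#' and the calibration standards. The defaults reproduce the study
#' conditions: 23 regions with wild-type means from the published table,
#' effects equal to the printed percent decreases, n = 8 vs 5, 15%
#' between-subject coefficient of variation, 5% plasma measurement CV and
#' 0.01 OD film noise.
#'
#' @param regions data frame with columns `region` and `wt_mean`
#'   (nmol/g/min); default [tsc2_regions()].
#' @param effect per-region fractional decrease in the mutant, in `[0, 1)`;
#'   recycled. Defaults to `-pct_printed/100` when `regions` carries a
#'   `pct_printed` column.
#' @param n_wt,n_mut group sizes (>= 1).
#' @param between_subject_cv lognormal biological CV of true rates.
#' @param plasma_noise_cv multiplicative measurement CV of plasma draws.
#' @param od_noise_sd additive film noise, OD units.
#' @param lambda_true true precursor fraction in (0, 1].
#' @param seed master seed; all per-subject noise streams derive from it.
#' @param input an [input_function()].
#' @param sample_times arterial sampling schedule (minutes).
#' @param film a `film_response`.
#' @param standards calibration standard activities, nCi/g.
#' @param T terminal time in minutes.
#' @param subject_ids optional list with character vectors `wt` and `mut`
#'   overriding the generated subject identifiers.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(regions = tsc2_regions(), effect = NULL,
                        n_wt = 8, n_mut = 5, between_subject_cv = 0.15,
                        plasma_noise_cv = 0.05, od_noise_sd = 0.01,
                        lambda_true = 0.6, seed = 1L,
                        input = input_function(),
                        sample_times = plasma_schedule(),
                        film = hill_film(), standards = default_standards(),
                        T = 60, subject_ids = NULL) {
  stopifnot(is.data.frame(regions), all(c("region", "wt_mean") %in% names(regions)))
  if (anyDuplicated(regions$region)) {
    stop("duplicate region names in 'regions'", call. = FALSE)
  }
  check_number(regions$wt_mean, "wt_mean", lower = 0, allow_equal_lower = FALSE,
               len = nrow(regions))
  if (is.null(effect)) {
    if (!"pct_printed" %in% names(regions)) {
      stop("'effect' must be given when 'regions' has no pct_printed column",
           call. = FALSE)
    }
    effect <- -regions$pct_printed / 100
  }
  effect <- rep_len(effect, nrow(regions))
  check_number(effect, "effect", lower = 0, upper = 1, allow_equal_upper = FALSE,
               len = length(effect))
  check_number(n_wt, "n_wt", lower = 1)
  check_number(n_mut, "n_mut", lower = 1)
  check_number(between_subject_cv, "between_subject_cv", lower = 0)
  check_number(plasma_noise_cv, "plasma_noise_cv", lower = 0)
  check_number(od_noise_sd, "od_noise_sd", lower = 0)
  check_number(lambda_true, "lambda_true", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_number(T, "T", lower = 0, allow_equal_lower = FALSE)
  stopifnot(inherits(input, "input_function"), inherits(film, "film_response"))
  if (T > input$params$t_end) {
    stop("terminal time T exceeds the input function's t_end", call. = FALSE)
  }
  ids <- list(
    wt = subject_ids$wt %||% sprintf("wt%02d", seq_len(n_wt)),
    mut = subject_ids$mut %||% sprintf("mut%02d", seq_len(n_mut)))
  if (anyDuplicated(c(ids$wt, ids$mut))) {
    stop("duplicate subject ids", call. = FALSE)
  }
  if (length(ids$wt) != n_wt || length(ids$mut) != n_mut) {
    stop("subject_ids lengths must match n_wt and n_mut", call. = FALSE)
  }
  structure(
    list(regions = regions, effect = effect, n_wt = as.integer(n_wt),
         n_mut = as.integer(n_mut), between_subject_cv = between_subject_cv,
         plasma_noise_cv = plasma_noise_cv, od_noise_sd = od_noise_sd,
         lambda_true = lambda_true, seed = as.integer(seed), input = input,
         sample_times = sample_times, film = film, standards = standards,
         T = T, subject_ids = ids),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic rCPS cohort spec: %d regions, n = %d WT vs %d mutant\n",
              nrow(x$regions), x$n_wt, x$n_mut))
  cat(sprintf("  effects %.0f-%.0f%% decrease; CVs: subject %.2f, plasma %.2f; OD sd %.3g\n",
              100 * min(x$effect), 100 * max(x$effect), x$between_subject_cv,
              x$plasma_noise_cv, x$od_noise_sd))
  cat(sprintf("  lambda %.2f, T %g min, seed %d\n", x$lambda_true, x$T, x$seed))
  invisible(x)
}

#' Forward-simulate a complete synthetic rCPS study
#'
#' Draws per-subject true synthesis rates (regional mean x genotype
#' multiplier x lognormal between-subject variation), generates each
#' subject's timed arterial plasma table from the shared continuous input
#' function with measurement noise, computes terminal tissue labelling via
#' the forward kinetic model, and renders one phantom autoradiogram per
#' subject with the co-exposed standards strip. All noise streams derive
#' deterministically from the spec's master seed, so an identical spec
#' regenerates an identical bundle.
#'
#' @param spec a [cohort_spec()].
#' @return An in-memory bundle of class `rcps_bundle`: subject table, plasma
#'   tables, OD images, shared mask/regions/standards, the truth table
#'   `(subject, region, true_rcps)` and a serializable manifest. Write it to
#'   disk with [write_bundle()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- data.frame(
    subject = c(spec$subject_ids$wt, spec$subject_ids$mut),
    genotype = c(rep("WT", spec$n_wt), rep("HET", spec$n_mut)),
    stringsAsFactors = FALSE)
  nreg <- nrow(spec$regions)
  i_true <- sa_integral(spec$input, spec$T)

  plasma <- list()
  images <- list()
  truth <- list()
  mask <- NULL; regions <- NULL; standards <- NULL
  warnings <- character(0)

  for (s in seq_len(nrow(subjects))) {
    sid <- subjects$subject[s]
    is_mut <- subjects$genotype[s] == "HET"
    gmult <- if (is_mut) (1 - spec$effect) else rep(1, nreg)
    bio <- with_seed(child_seed(spec$seed, s),
                     rlnorm_cv(nreg, spec$between_subject_cv))
    true_rcps <- spec$regions$wt_mean * gmult * bio
    names(true_rcps) <- spec$regions$region

    plasma[[sid]] <- sample_plasma(spec$input, spec$sample_times,
                                   noise_cv = spec$plasma_noise_cv,
                                   seed = child_seed(spec$seed, 1000L + s),
                                   subject_id = sid)
    pstars <- true_rcps * spec$lambda_true * i_true
    ar <- render_autoradiogram(pstars, standards = spec$standards,
                               film = spec$film,
                               od_noise_sd = spec$od_noise_sd,
                               seed = child_seed(spec$seed, 2000L + s))
    images[[sid]] <- ar$image
    if (is.null(mask)) {
      mask <- ar$mask; regions <- ar$regions; standards <- ar$standards
    }
    warnings <- union(warnings, ar$warnings)
    truth[[sid]] <- data.frame(subject = sid, region = spec$regions$region,
                               true_rcps = unname(true_rcps),
                               stringsAsFactors = FALSE)
  }

  manifest <- list(
    tool = "rcpskit",
    seed = spec$seed,
    n_wt = spec$n_wt, n_mut = spec$n_mut,
    regions = spec$regions$region,
    wt_mean = spec$regions$wt_mean,
    effect = spec$effect,
    between_subject_cv = spec$between_subject_cv,
    plasma_noise_cv = spec$plasma_noise_cv,
    od_noise_sd = spec$od_noise_sd,
    lambda_true = spec$lambda_true,
    T = spec$T,
    input = spec$input$params,
    film = attr(spec$film, "params"),
    standards = spec$standards,
    sample_times = spec$sample_times,
    sa_integral_true = i_true,
    pixel_size_um = 11,
    warnings = warnings)

  structure(
    list(spec = spec, subjects = subjects, plasma = plasma, images = images,
         mask = mask, regions = regions, standards = standards,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         manifest = manifest),
    class = "rcps_bundle")
}

#' @export
print.rcps_bundle <- function(x, ...) {
  cat(sprintf("Synthetic rCPS bundle: %d subjects (%d WT, %d HET), %d regions\n",
              nrow(x$subjects), sum(x$subjects$genotype == "WT"),
              sum(x$subjects$genotype == "HET"), nrow(x$regions)))
  if (length(x$manifest$warnings)) {
    cat("  warnings:", paste(x$manifest$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Lays out the file-based interface consumed by the pipeline stages:
#' `plasma/<subject>.csv`, `images/<subject>.tif` (+ sidecar JSON),
#' `mask.tif`, `regions.tsv`, `standards.csv`, `truth.tsv`, `subjects.tsv`
#' and `manifest.json`.
#'
#' @param bundle an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "rcps_bundle"))
  dir.create(file.path(dir, "plasma"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  for (sid in names(bundle$plasma)) {
    write_plasma(bundle$plasma[[sid]], file.path(dir, "plasma", paste0(sid, ".csv")))
  }
  for (sid in names(bundle$images)) {
    write_autoradiogram(bundle$images[[sid]],
                        file.path(dir, "images", paste0(sid, ".tif")))
  }
  write_mask(bundle$mask, file.path(dir, "mask.tif"))
  utils::write.table(bundle$regions, file.path(dir, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
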