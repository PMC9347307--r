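# shared builders for small synthetic studies

tiny_regions <- function(k = 3) tsc2_regions()[seq_len(k), ]

# noise-free spec with identity film and dense sampling: the configuration
# under which the pipeline should reproduce truth almost exactly
noiseless_spec <- function(k = 3, n_wt = 2, n_mut = 2, seed = 1,
                           dense_by = 0.25) {
  cohort_spec(regions = tiny_regions(k), n_wt = n_wt, n_mut = n_mut,
              between_subject_cv = 0, plasma_noise_cv = 0, od_noise_sd = 0,
              sample_times = seq(dense_by, 60, by = dense_by),
              film = identity_film(), seed = seed)
}

# run calibrate -> quantify -> fit over an in-memory bundle
fit_bundle <- function(b, lambda = b$spec$lambda_true,
                       policy = "linear_flagged") {
  curve <- fit_calibration(b$standards, policy = policy)
  tissue <- do.call(rbind, lapply(b$subjects$subject, function(s) {
    quantify_regions(b$images[[s]], b$mask, b$regions, curve, subject = s)
  }))
  rcps_fit(tissue, b$plasma, subjects = b$subjects, lambda = lambda,
           T = b$spec$T)
}

# minimal constant-specific-activity input object (ratio == s everywhere);
# only the pieces forward_label()/sa_integral() touch
constant_sa_fn <- function(s = 1, t_end = 60) {
  structure(list(sa = function(t) rep(s, length(t)),
                 cpstar = function(t) rep(s * 100, length(t)),
                 cp = function(t) rep(100, length(t)),
                 params = list(shape = "constant", t_end = t_end)),
            class = "input_function")
}
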