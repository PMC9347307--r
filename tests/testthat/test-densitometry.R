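std_df <- function(activity, od) {
  data.frame(activity_nCi_per_g = activity, od = od)
}

test_that("calibration curve interpolates linearly and round-trips its knots", {
  curve <- fit_calibration(std_df(c(0, 50, 100), c(0, 0.5, 1.0)))
  expect_equal(as.numeric(od_to_activity(curve, 0.75)), 75)
  # knot round-trip exactness, including for an arbitrary monotone film
  for (f in list(identity_film(), hill_film(2, 800),
                 structure(function(a) log1p(a) / 3, class = "film_response"))) {
    acts <- c(0, 40, 160, 640, 2560)
    curve <- fit_calibration(std_df(acts, f(acts)))
    got <- od_to_activity(curve, f(acts))
    expect_equal(as.numeric(got), acts)
    expect_false(any(attr(got, "extrapolated")))
  }
})

test_that("replicate standards are averaged before fitting", {
  curve <- fit_calibration(std_df(c(0, 50, 50, 100), c(0, 0.4, 0.6, 1.0)))
  expect_equal(nrow(curve$knots), 3)
  expect_equal(as.numeric(od_to_activity(curve, 0.5)), 50)
})

test_that("degenerate standards sets are rejected informatively", {
  expect_error(fit_calibration(std_df(c(0, 50), c(0, 0.5))), "at least 3")
  expect_error(fit_calibration(std_df(c(0, 50, 100), c(0, 0.7, 0.6))),
               "not strictly monotone")
  expect_error(fit_calibration(std_df(c(0, 50, 100), c(0, -0.1, 0.6))),
               "non-negative")
})

test_that("extrapolation policies clamp, continue or reject as declared", {
  s <- std_df(c(0, 50, 100, 200), c(0.1, 0.5, 0.9, 1.7))
  clamp <- fit_calibration(s, policy = "clamp")
  lo <- od_to_activity(clamp, 0.05)
  expect_equal(as.numeric(lo), 0)
  expect_true(attr(lo, "extrapolated"))
  # linear continuation of the last segment: slope (200-100)/(1.7-0.9)
  lin <- fit_calibration(s, policy = "linear_flagged")
  hi <- od_to_activity(lin, 1.9)
  expect_equal(as.numeric(hi), 200 + (1.9 - 1.7) * 100 / 0.8)
  expect_true(attr(hi, "extrapolated"))
  err <- fit_calibration(s, policy = "error")
  expect_error(od_to_activity(err, 2.0), "outside calibration domain")
  inside <- od_to_activity(err, c(0.5, 0.9))
  expect_equal(as.numeric(inside), c(50, 100))
})

test_that("standards through the Hill film invert it within 1% in the interior", {
  film <- hill_film()
  curve <- fit_calibration(std_df(default_standards(), film(default_standards())))
  set.seed(8)
  acts <- runif(50, 50, 4900)
  est <- od_to_activity(curve, film(acts))
  expect_false(any(attr(est, "extrapolated")))
  expect_lt(max(abs(as.numeric(est) - acts) / acts), 0.01)
})

test_that("ROI measurement averages exactly the labelled pixels", {
  img <- matrix(0.1, 4, 5)
  mask <- matrix(0L, 4, 5)
  mask[2:3, 2:3] <- 1L
  img[mask == 1L] <- 0.7
  m <- measure_roi(img, mask, 1L)
  expect_equal(m, list(mean_od = 0.7, od_sd = 0, n_pixels = 4L))
  # two-pixel ROI, hand-computed n-1 SD
  mask2 <- matrix(0L, 1, 2); mask2[1, ] <- 2L
  img2 <- matrix(c(0.2, 0.4), 1, 2)
  m2 <- measure_roi(img2, mask2, 2L)
  expect_equal(m2$mean_od, 0.3)
  expect_equal(m2$od_sd, sqrt(0.02), tolerance = 1e-12)
  # whole-image label
  m3 <- measure_roi(matrix(1, 3, 3), matrix(5L, 3, 3), 5L)
  expect_equal(m3$n_pixels, 9L)
  expect_error(measure_roi(img, mask, 9L), "not present")
  expect_error(measure_roi(img, matrix(0L, 2, 2), 1L), "dimensions")
})

test_that("region quantification reproduces rendered truth and flags extrapolation", {
  pstars <- c(ra = 120, rb = 900, rc = 3000)
  ar <- render_autoradiogram(pstars, film = identity_film(), od_noise_sd = 0)
  curve <- fit_calibration(ar$standards)
  q <- quantify_regions(ar$image, ar$mask, ar$regions, curve, subject = "sx")
  expect_equal(q$pstar_nCi_per_g, unname(pstars), tolerance = 1e-9)
  expect_equal(q$n_pixels, rep(16L * 20L, 3))
  expect_false(any(q$extrapolated))
  # a region beyond the standards span is flagged (and warned at render time)
  ar2 <- render_autoradiogram(c(ra = 120, rb = 9000), film = identity_film())
  expect_match(ar2$warnings, "outside standards span")
  q2 <- quantify_regions(ar2$image, ar2$mask, ar2$regions, curve, subject = "sx")
  expect_equal(q2$extrapolated, c(FALSE, TRUE))
  # missing label is an error
  bad <- data.frame(label = c(1L, 7L), region = c("ra", "zz"))
  expect_error(quantify_regions(ar$image, ar$mask, bad, curve), "7")
})

test_that("P* depends only on the curve, not the OD unit scale", {
  pstars <- c(ra = 300, rb = 2000)
  film <- hill_film()
  ar <- render_autoradiogram(pstars, film = film, od_noise_sd = 0)
  for (k in c(1, 3.7)) {
    std <- ar$standards; std$od <- std$od * k
    curve <- fit_calibration(std)
    q <- quantify_regions(ar$image * k, ar$mask, ar$regions, curve)
    expect_equal(q$pstar_nCi_per_g,
                 as.numeric(od_to_activity(fit_calibration(ar$standards),
                                           film(unname(pstars)))),
                 tolerance = 1e-12)
  }
})

test_that("16-bit TIFF OD encoding round-trips through the sidecar scale", {
  img <- matrix(runif(60, 0, 1.4), 6, 10)
  p <- tempfile(fileext = ".tif")
  write_autoradiogram(img, p)
  back <- read_autoradiogram(p)
  expect_equal(attr(back, "od_scale"), 10000)
  expect_equal(attr(back, "pixel_size_um"), 11)
  expect_lt(max(abs(back - img)), 1 / 10000)
  # large ODs (identity-film phantoms) shrink the scale instead of clipping
  big <- matrix(c(0, 2500, 4999, 120), 2, 2)
  p2 <- tempfile(fileext = ".tif")
  write_autoradiogram(big, p2)
  back2 <- read_autoradiogram(p2)
  expect_lt(attr(back2, "od_scale"), 10000)
  expect_lt(max(abs(back2 - big) / pmax(big, 1)), 1e-3)
  # masks round-trip exactly
  mk <- matrix(sample.int(23, 40, replace = TRUE), 5, 8)
  p3 <- tempfile(fileext = ".tif")
  write_mask(mk, p3)
  expect_identical(read_mask(p3), matrix(as.integer(mk), 5, 8))
})
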