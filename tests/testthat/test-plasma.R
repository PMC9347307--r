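make_plasma_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("plasma tables read back validated, with extra columns tolerated", {
  df <- data.frame(time_min = c(1, 5, 10), cpstar_nCi_per_mL = c(10, 8, 5),
                   cp_nmol_per_mL = c(130, 131, 132), note = "x")
  tc <- read_plasma(make_plasma_csv(df), subject_id = "s9")
  expect_s3_class(tc, "plasma_timecourse")
  expect_equal(nrow(tc), 3)
  expect_equal(attr(tc, "subject_id"), "s9")
  expect_named(tc, c("time_min", "cpstar_nCi_per_mL", "cp_nmol_per_mL"))
})

test_that("malformed plasma tables are rejected with the offending row", {
  base <- data.frame(time_min = c(1, 5), cpstar_nCi_per_mL = c(1, 2),
                     cp_nmol_per_mL = c(100, 100))
  expect_error(read_plasma(make_plasma_csv(base[, -2])), "cpstar_nCi_per_mL")
  expect_error(read_plasma(make_plasma_csv(base[0, ])), "no samples")
  bad_t <- base; bad_t$time_min <- c(5, 2)
  expect_error(read_plasma(make_plasma_csv(bad_t)), "row 2")
  bad_a <- base; bad_a$cpstar_nCi_per_mL[2] <- -1
  expect_error(read_plasma(make_plasma_csv(bad_a)), "row 2")
  bad_c <- base; bad_c$cp_nmol_per_mL[1] <- 0
  expect_error(read_plasma(make_plasma_csv(bad_c)), "row 1")
})

test_that("specific-activity ratio is elementwise and scale invariant", {
  expect_equal(sa_ratio(100, 100), 1)
  expect_equal(sa_ratio(0, 50), 0)
  expect_equal(sa_ratio(137, 137), sa_ratio(274, 274))
  expect_error(sa_ratio(1, 0), "cp")
})

ratio_table <- function(t, ratio, cp = 100) {
  structure(data.frame(time_min = t, cpstar_nCi_per_mL = ratio * cp,
                       cp_nmol_per_mL = cp),
            class = c("plasma_timecourse", "data.frame"))
}

test_that("trapezoid integral is exact on constant and linear ratios", {
  t <- seq(0, 60, by = 10)
  expect_equal(integrate_sa(ratio_table(t, rep(1, 7)), T = 60), 60)
  expect_equal(integrate_sa(ratio_table(t, t / 60), T = 60), 30)
})

test_that("zero anchor, flat carry-forward and truncation behave as specified", {
  # first draw after injection: segment [0, t1] uses the zero anchor
  tc <- ratio_table(c(10, 20), c(1, 1))
  expect_equal(integrate_sa(tc, T = 20), 10 / 2 + 10)
  # sampling stops early: last ratio carried flat to T (with coverage warning)
  tc2 <- ratio_table(seq(0, 40, 10), rep(2, 5))
  expect_warning(v <- integrate_sa(tc2, T = 60), "90%")
  expect_equal(v, 120)
  expect_equal(suppressWarnings(integrate_sa(tc2, T = 58)), 116)
  # samples beyond T: interpolate at T, drop the rest
  tc3 <- ratio_table(seq(0, 60, 10), seq(0, 60, 10) / 60)
  expect_equal(integrate_sa(tc3, T = 45), 45^2 / (2 * 60))
  expect_error(integrate_sa(ratio_table(c(10, 20), c(1, 1)), T = 5),
               "precedes")
})

test_that("flat carry-forward equals integrating an explicitly constant tail", {
  set.seed(4)
  t <- c(0, sort(runif(8, 1, 59)), 60)
  r <- runif(10, 0, 3)
  t1 <- t[6]
  # truncated table with flat extension vs full table whose tail is constant
  r_const_tail <- c(r[1:6], rep(r[6], 4))
  flat <- suppressWarnings(integrate_sa(ratio_table(t[1:6], r[1:6]), T = 60))
  full <- integrate_sa(ratio_table(t, r_const_tail), T = 60)
  expect_equal(flat, full)
  # and it decomposes as the [0, t1] integral plus the constant rectangle
  left <- integrate_sa(ratio_table(t[1:6], r[1:6]), T = t1)
  expect_equal(flat, left + r[6] * (60 - t1))
})

test_that("constant-Cp mode divides by the mean sampled concentration", {
  tc <- data.frame(time_min = c(0, 30, 60), cpstar_nCi_per_mL = c(0, 90, 60),
                   cp_nmol_per_mL = c(80, 100, 120))
  v <- integrate_sa(tc, T = 60, cp_mode = "constant")
  ratio <- tc$cpstar_nCi_per_mL / 100   # mean(cp) = 100
  expect_equal(v, sum(diff(tc$time_min) * (ratio[-3] + ratio[-1]) / 2))
})

test_that("sampled trapezoid converges to quadrature under refinement", {
  set.seed(11)
  worse_than_before <- 0
  for (i in 1:20) {
    fn <- input_function(rise_rate = runif(1, 0.7, 1.5),
                         decay_rate = runif(1, 0.02, 0.05))
    oracle <- sa_integral(fn)
    errs <- vapply(c(2, 1, 0.5, 0.25), function(h) {
      tc <- sample_plasma(fn, times = seq(h, 60, by = h))
      abs(integrate_sa(tc, T = 60) - oracle)
    }, numeric(1))
    worse_than_before <- worse_than_before + any(diff(errs) >= 0)
  }
  expect_equal(worse_than_before, 0)
})
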