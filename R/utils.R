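# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE,
                         len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop(sprintf("'%s' must be a numeric vector of length %d with no NAs", name, len),
         call. = FALSE)
  }
  lo_ok <- if (allow_equal_lower) all(x >= lower) else all(x > lower)
  hi_ok <- if (allow_equal_upper) all(x <= upper) else all(x < upper)
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' must lie in %s%g, %g%s (got %s)", name,
                 if (allow_equal_lower) "[" else "(", lower, upper,
                 if (allow_equal_upper) "]" else ")",
                 paste(signif(x, 6), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# evaluate expr with a private RNG stream, leaving the caller's stream intact
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seed for an independent noise stream; keeps results
# reproducible from one master seed while decoupling the streams
child_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + as.double(stream) * 10007) %% 2147483629)
}

# round to nearest integer, ties away from zero (the convention that matches
# printed percent-difference tables in this literature)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# composite trapezoid on sampled points
trapz <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
}

# lognormal multiplier with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}
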