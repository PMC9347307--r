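# Independent statistics oracles: direct cell-means sums-of-squares
# computations for balanced designs, coded without aov() so ANOVA results
# can be cross-checked against textbook arithmetic.

# split-plot (one between factor A, one within factor B, n subjects per
# A level, complete balanced data)
splitplot_oracle <- function(y, A, B, S) {
  A <- as.character(A); B <- as.character(B); S <- as.character(S)
  a <- length(unique(A)); b <- length(unique(B))
  n <- length(unique(S)) / a
  grand <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  mS <- tapply(y, S, mean)
  sA <- tapply(A, S, function(x) x[1])   # A level of each subject
  ss_A <- n * b * sum((mA - grand)^2)
  ss_SwA <- b * sum((mS - mA[sA[names(mS)]])^2)
  ss_B <- a * n * sum((mB - grand)^2)
  ss_AB <- n * sum((mAB - matrix(mA, a, b) -
                      matrix(mB, a, b, byrow = TRUE) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_A - ss_SwA - ss_B - ss_AB
  df_A <- a - 1; df_SwA <- a * (n - 1)
  df_B <- b - 1; df_AB <- (a - 1) * (b - 1); df_err <- a * (n - 1) * (b - 1)
  list(
    F_A = (ss_A / df_A) / (ss_SwA / df_SwA),
    F_B = (ss_B / df_B) / (ss_err / df_err),
    F_AB = (ss_AB / df_AB) / (ss_err / df_err),
    df = list(A = c(df_A, df_SwA), B = c(df_B, df_err), AB = c(df_AB, df_err)))
}

# two-way fully-between factorial, balanced
twoway_oracle <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  a <- length(unique(A)); b <- length(unique(B))
  n <- length(y) / (a * b)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  ss_AB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_err <- sum((y - grand)^2) - ss_A - ss_B - ss_AB
  df_err <- a * b * (n - 1)
  list(F_A = (ss_A / (a - 1)) / (ss_err / df_err),
       F_B = (ss_B / (b - 1)) / (ss_err / df_err),
       F_AB = (ss_AB / ((a - 1) * (b - 1))) / (ss_err / df_err),
       df_err = df_err)
}
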