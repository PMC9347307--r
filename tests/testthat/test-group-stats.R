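long_design <- function(values, genotypes = c("WT", "HET"), regions = c("r1", "r2"),
                        n = 3) {
  subj <- paste0("s", seq_len(length(genotypes) * n))
  d <- expand.grid(subject = subj, region = regions, stringsAsFactors = FALSE)
  d$genotype <- rep(rep(genotypes, each = n), times = length(regions))
  d$value <- values
  d
}

test_that("mixed ANOVA gives zero between-group F when group means are equal", {
  # values constructed so both genotype means are 5 in every region
  v <- c(4, 5, 6, 4, 5, 6,   # region r1: WT then HET
         7, 5, 3, 3, 5, 7)   # region r2
  d <- long_design(v)
  tab <- mixed_anova(d, "value", "genotype", "region", "subject")
  expect_equal(tab$F[tab$effect == "genotype"], 0, tolerance = 1e-12)
  expect_equal(tab$effect[1], "genotype x region")   # interaction reported first
})

test_that("mixed ANOVA matches the cell-means split-plot oracle", {
  set.seed(31)
  for (rep in 1:5) {
    d2 <- long_design(rnorm(18, mean = 10, sd = 2),
                      regions = c("r1", "r2", "r3"), n = 3)
    tab <- mixed_anova(d2, "value", "genotype", "region", "subject")
    orc <- splitplot_oracle(d2$value, d2$genotype, d2$region, d2$subject)
    expect_equal(tab$F[tab$effect == "genotype"], orc$F_A, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "region"], orc$F_B, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "genotype x region"], orc$F_AB,
                 tolerance = 1e-8)
    expect_equal(tab$df_num[tab$effect == "genotype"], orc$df$A[1])
    expect_equal(tab$df_den[tab$effect == "genotype"], orc$df$A[2])
    expect_equal(tab$df_den[tab$effect == "genotype x region"], orc$df$AB[2])
  }
})

test_that("four-subject 2x2 split-plot matches hand-computable sums of squares", {
  # two subjects per genotype, two regions; textbook small case
  d <- data.frame(subject = rep(c("a", "b", "c", "d"), times = 2),
                  genotype = rep(c("WT", "WT", "HET", "HET"), times = 2),
                  region = rep(c("r1", "r2"), each = 4),
                  value = c(10, 12, 6, 8, 15, 16, 8, 11))
  tab <- mixed_anova(d, "value", "genotype", "region", "subject", min_n = 2)
  orc <- splitplot_oracle(d$value, d$genotype, d$region, d$subject)
  expect_equal(tab$F[tab$effect == "genotype"], orc$F_A, tolerance = 1e-12)
  expect_equal(tab$F[tab$effect == "region"], orc$F_B, tolerance = 1e-12)
  expect_equal(tab$F[tab$effect == "genotype x region"], orc$F_AB,
               tolerance = 1e-12)
})

test_that("complete-case policy drops sparse regions and partial subjects", {
  set.seed(9)
  d <- long_design(rnorm(18, 10), regions = c("r1", "r2", "r3"), n = 3)
  # region r3 observed in only 1 HET subject -> dropped under min_n = 3
  d <- d[!(d$region == "r3" & d$subject %in% c("s4", "s5")), ]
  tab <- mixed_anova(d, "value", "genotype", "region", "subject", min_n = 3)
  expect_match(attr(tab, "policy"), "dropped 1 within level")
  expect_match(attr(tab, "policy"), "r3")
  # F values equal the oracle on the retained complete submatrix
  sub <- d[d$region != "r3", ]
  orc <- splitplot_oracle(sub$value, sub$genotype, sub$region, sub$subject)
  expect_equal(tab$F[tab$effect == "genotype"], orc$F_A, tolerance = 1e-8)
  # dropping everything leaves too little design and errors clearly
  d2 <- long_design(rnorm(12, 10), n = 3)
  d2 <- d2[!(d2$region == "r2" & d2$subject %in% c("s4", "s5")), ]
  expect_error(mixed_anova(d2, "value", "genotype", "region", "subject",
                           min_n = 3), "fewer than 2 levels")
})

test_that("design violations are rejected", {
  d <- long_design(rnorm(12, 10))
  dup <- rbind(d, d[1, ])
  expect_error(mixed_anova(dup, "value", "genotype", "region", "subject"),
               "at most once")
  # a subject in two genotype groups
  d2 <- d; d2$genotype[d2$subject == "s1"][1] <- "HET"
  expect_error(mixed_anova(d2, "value", "genotype", "region", "subject"),
               "more than one")
  # < 2 subjects per between cell
  d3 <- long_design(rnorm(4, 10), n = 1)
  expect_error(mixed_anova(d3, "value", "genotype", "region", "subject",
                           min_n = 1), "at least 2 subjects")
})

test_that("factorial ANOVA matches the two-way oracle and reports in table order", {
  set.seed(77)
  d <- expand.grid(subject = paste0("s", 1:20), stringsAsFactors = FALSE)
  d$genotype <- rep(c("WT", "HET"), each = 10)
  d$treatment <- rep(c("ctrl", "iso"), times = 10)
  d$value <- rnorm(20, 1, 0.2) + ifelse(d$genotype == "HET", -0.25, 0)
  tab <- factorial_anova(d, "value", between = c("genotype", "treatment"),
                         subject = "subject")
  orc <- twoway_oracle(d$value, d$genotype, d$treatment)
  expect_equal(tab$effect, c("genotype x treatment", "genotype", "treatment"))
  expect_equal(tab$F[1], orc$F_AB, tolerance = 1e-8)
  expect_equal(tab$F[2], orc$F_A, tolerance = 1e-8)
  expect_equal(tab$F[3], orc$F_B, tolerance = 1e-8)
  expect_equal(tab$df_den[1], orc$df_err)
  # location invariance
  d$value <- d$value + 100
  tab2 <- factorial_anova(d, "value", between = c("genotype", "treatment"),
                          subject = "subject")
  expect_equal(tab2$F, tab$F, tolerance = 1e-8)
})

test_that("within-factor main effect is zero when band shifts cancel per cell", {
  set.seed(5)
  base <- rnorm(12, 1, 0.3)
  d <- expand.grid(subject = paste0("s", 1:12), band = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$genotype <- rep(rep(c("WT", "HET"), each = 6), 2)
  d$treatment <- rep(rep(c("ctrl", "iso"), 6), 2)
  # band-2 offsets sum to zero inside every genotype x treatment cell, so
  # every band-related effect has zero sum of squares but the residual does not
  delta <- rep(c(0.2, 0.2, -0.2, -0.2, 0, 0), 2)
  d$value <- c(base, base + delta)
  tab <- factorial_anova(d, "value", between = c("genotype", "treatment"),
                         within = "band", subject = "subject")
  expect_equal(tab$F[tab$effect == "band"], 0, tolerance = 1e-12)
  expect_equal(tab$effect[1], "genotype x treatment x band")
})

test_that("Bonferroni post hocs apply p_adj = min(1, m p) and skip sparse cells", {
  set.seed(13)
  d <- long_design(rnorm(12, 10), n = 3)
  d$value[d$genotype == "HET" & d$region == "r1"] <- 20 + rnorm(3, 0, 0.1)
  ph <- posthoc_bonferroni(d, "value", "genotype", "region", m = 23)
  expect_equal(ph$p_adj, pmin(1, 23 * ph$p_raw))
  expect_equal(ph$m, c(23, 23))
  # adjustment is order preserving and idempotent for fixed m
  expect_equal(order(ph$p_adj), order(ph$p_raw))
  expect_equal(pmin(1, 1 * ph$p_adj * (23 / 23)), ph$p_adj)
  # cross-check one cell against t.test directly
  tt <- t.test(d$value[d$genotype == "HET" & d$region == "r1"],
               d$value[d$genotype == "WT" & d$region == "r1"])
  expect_equal(ph$p_raw[ph$cell == "r1"], tt$p.value)
  expect_equal(ph$t[ph$cell == "r1"], unname(tt$statistic))
  # identical groups: t = 0, p_adj = 1
  d0 <- long_design(rep(4, 12), n = 3)
  ph0 <- posthoc_bonferroni(d0, "value", "genotype", "region")
  expect_equal(ph0$t, c(0, 0))
  expect_equal(ph0$p_adj, c(1, 1))
  # a level with < 2 per group is skipped with a warning
  d1 <- long_design(rnorm(12, 10), n = 3)
  d1 <- d1[!(d1$region == "r2" & d1$subject %in% c("s4", "s5")), ]
  expect_warning(ph1 <- posthoc_bonferroni(d1, "value", "genotype", "region",
                                           m = 2), "skipped")
  expect_equal(ph1$cell, "r1")
  expect_error(posthoc_bonferroni(d, "value", "genotype", "region", m = 1),
               "at least")
})

test_that("cell summaries report mean, n-1 SEM and n", {
  d <- data.frame(g = c("a", "a", "a", "b"), value = c(1, 2, 3, 7))
  s <- summarize_groups(d, "value", by = "g")
  expect_equal(s$mean, c(2, 7))
  expect_equal(s$sem[1], sd(1:3) / sqrt(3))
  expect_equal(s$sem[1], 0.5774, tolerance = 1e-4)
  expect_true(is.na(s$sem[2]))   # singleton cell: SEM undefined
  expect_equal(s$n, c(3L, 1L))
})
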