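test_that("one-way ANOVA matches the sum-of-squares oracle", {
  set.seed(11)
  for (i in 1:20) {
    g <- factor(rep(1:4, times = sample(3:8, 4, replace = TRUE)))
    v <- rnorm(length(g), mean = as.integer(g) * runif(1))
    a <- anova_oneway(v, g)
    o <- oracle_anova(v, g)
    expect_equal(a$F, o$F, tolerance = 1e-10)
    expect_equal(a$p, o$p, tolerance = 1e-10)
  }
})

test_that("ANOVA handles equal means and degenerate zero within-variance", {
  r <- anova_oneway(c(1, 2, 1, 2), factor(c("a", "a", "b", "b")))
  expect_equal(r$F, 0)
  d <- anova_oneway(c(0, 0, 0, 1, 1, 1), factor(rep(c("a", "b"), each = 3)))
  expect_identical(d$F, Inf)
  expect_identical(d$p, 0)
  expect_true(d$degenerate)
  expect_error(anova_oneway(c(1, 2, 3), factor(c("a", "a", "b"))), "at least 2 values")
})

test_that("post-hoc t-tests match the pooled-variance formula with Bonferroni", {
  set.seed(12)
  v <- c(rnorm(5), rnorm(5, 1), rnorm(5, 2), rnorm(5, 0.5))
  g <- factor(rep(c("H", "T1", "T2", "T3"), each = 5))
  tab <- posthoc_ttests(v, g)
  expect_equal(nrow(tab), 6L)
  for (i in seq_len(nrow(tab))) {
    o <- oracle_t(v[g == tab$group1[i]], v[g == tab$group2[i]])
    expect_equal(tab$t[i], o$t, tolerance = 1e-10)
    expect_equal(tab$p_raw[i], o$p, tolerance = 1e-10)
  }
  expect_equal(tab$p_adj, pmin(1, tab$p_raw * 6))
  # printed-arithmetic case: raw 0.01 over 6 pairs adjusts to 0.06
  expect_equal(min(1, 0.01 * 6), 0.06)

  same <- posthoc_ttests(c(1, 2, 3, 1, 2, 3), factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  const <- posthoc_ttests(c(1, 1, 2, 2), factor(c("a", "a", "b", "b")))
  expect_true(const$degenerate)
  expect_identical(const$p_raw, 0)
})

test_that("significance stars follow the three-level convention", {
  expect_identical(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("", "*", "**", "***", NA))
})

test_that("shell comparisons compose per-shell ANOVA and T1 outcome t-tests", {
  set.seed(13)
  n <- 40
  sh <- data.frame(cell_id = sprintf("c%03d", 1:n),
                   component = "overall",
                   group = rep(c("H", "T1", "T2", "T3"), each = 10),
                   outcome = "not-applicable", stringsAsFactors = FALSE)
  sh$outcome[sh$group == "T1"] <- rep(c("survivor", "non-survivor"), each = 5)
  for (k in 1:8) sh[[paste0("d", k)]] <- runif(n)
  sh$d8 <- sh$d8 + (sh$group == "T1") * 0.8   # strong outer-shell effect

  res <- shell_comparisons(sh)
  a8 <- res[res$test == "anova_status" & res$shell == 8, ]
  o8 <- anova_oneway(sh$d8, sh$group)
  expect_equal(a8$statistic, o8$F, tolerance = 1e-12)
  expect_equal(a8$p_adj, min(1, o8$p * 8))
  expect_true(a8$p_adj < 0.05)
  t5 <- res[res$test == "ttest_T1_outcome" & res$shell == 5, ]
  t1dat <- sh[sh$group == "T1", ]
  ot <- posthoc_ttests(t1dat$d5, t1dat$outcome)
  expect_equal(t5$statistic, ot$t, tolerance = 1e-12)

  expect_error(shell_comparisons(sh[sh$group != "T2", ]), "T2")
  sh2 <- sh; sh2$outcome[sh2$group == "T1"] <- "survivor"
  expect_error(shell_comparisons(sh2), "non-survivor")
})

test_that("subject-level aggregation tests per-subject means", {
  set.seed(21)
  df <- data.frame(subject_id = rep(sprintf("s%02d", 1:12), each = 5),
                   group = rep(c("H", "T1", "T2", "T3"), each = 15),
                   volume_fl = rnorm(60, rep(c(100, 130, 115, 105), each = 15), 5))
  res <- group_comparisons(df, feature_cols = "volume_fl", by_subject = TRUE)
  # oracle: ANOVA on the 12 per-subject means
  sm <- tapply(df$volume_fl, df$subject_id, mean)
  sg <- tapply(df$group, df$subject_id, `[`, 1)
  o <- oracle_anova(as.numeric(sm), sg[names(sm)])
  expect_equal(res$anova$F, o$F, tolerance = 1e-10)
})

test_that("under the null, raw per-shell rejections run near the nominal rate", {
  set.seed(14)
  reps <- 400
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    v <- rnorm(40)
    g <- factor(rep(c("H", "T1", "T2", "T3"), each = 10))
    p <- anova_oneway(v, g)$p
    hits <- hits + (p < 0.05); total <- total + 1
  }
  rate <- hits / total
  ci <- qbinom(c(0.0005, 0.9995), reps, 0.05) / reps
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Pearson correlation modes behave on exact, null and generated data", {
  df <- data.frame(group = c("T1", "T2", "T3"),
                   subject_id = c("a", "b", "c"),
                   mean_overall_ri = c(1, 2, 3), cov = c(2, 4, 6))
  out <- correlate_features(df, "cov", mode = "timepoint_means")
  expect_equal(out$rho, 1.0)
  expect_equal(out$n, 3L)

  set.seed(15)
  dn <- data.frame(subject_id = sprintf("s%04d", 1:1000), group = "H",
                   mean_overall_ri = rnorm(1000), cov = rnorm(1000))
  on <- correlate_features(dn, "cov", mode = "per_subject")
  expect_lt(abs(on$rho), 0.1)

  expect_error(correlate_features(df[1:2, ], "cov", mode = "timepoint_means"),
               "fewer than 3 pairs")
})
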