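test_that("virtual mRNA levels follow both readings of the formula", {
  # equal cts: literal 0, exponential 1
  expect_equal(as.numeric(virtual_mrna_level(20, 20, -3.32, "literal")), 0)
  expect_equal(as.numeric(virtual_mrna_level(20, 20, -3.32, "exponential")), 1)
  # a tenfold-diluted target: delta-ct of one slope unit
  expect_equal(as.numeric(virtual_mrna_level(23.32, 20, -3.32, "exponential")),
               0.1, tolerance = 1e-12)
  expect_equal(as.numeric(virtual_mrna_level(23.32, 20, -3.32, "literal")),
               10 * 3.32 / -3.32, tolerance = 1e-12)
  expect_error(virtual_mrna_level(20, 19, 0), "slope")
  expect_identical(attr(virtual_mrna_level(20, 19, -3.32), "mode"), "literal")
})

test_that("exponential-mode levels ignore a common shift of both cycle thresholds", {
  lv1 <- virtual_mrna_level(24.1, 20.3, -3.1, "exponential")
  lv2 <- virtual_mrna_level(24.1 + 5, 20.3 + 5, -3.1, "exponential")
  expect_equal(as.numeric(lv1), as.numeric(lv2), tolerance = 1e-12)
})

test_that("technical replicates enter as their mean", {
  expect_equal(mean_ct(c(20.1, 20.3, 20.2)), 20.2)
  tab <- simulate_qpcr_run(c(s1 = 0.5), noise_sd_ct = 0.2, n_technical = 3,
                           seed = 2)$table
  lv <- qpcr_levels(tab, mode = "exponential")
  expect_equal(lv$ct_target,
               mean(c(tab$ct_rep1, tab$ct_rep2, tab$ct_rep3)))
})

test_that("densitometry normalization divides by the reference band", {
  df <- data.frame(sample_id = c("a", "b"), band = c(1000, 2000),
                   reference = c(1000, 1000))
  out <- normalize_densitometry(df)
  expect_equal(out$ratio, c(1, 2))
  empty <- normalize_densitometry(df[0, ])
  expect_equal(nrow(empty), 0L)
  df$reference[2] <- 0
  expect_error(normalize_densitometry(df), "b")
})

test_that("one-way ANOVA agrees with a from-definitions oracle", {
  vals <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  res <- group_anova_bonferroni(vals)
  orc <- anova_oracle(vals)
  expect_equal(res$F, orc$F, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    v <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3)))
    names(v) <- paste0("g", seq_len(k))
    res <- group_anova_bonferroni(v)
    orc <- anova_oracle(v)
    expect_equal(res$F, orc$F, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
    expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw - 1e-15))
    expect_true(all(res$posthoc$p_adj <= 1))
  }
})

test_that("ANOVA degenerates as expected", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- group_anova_bonferroni(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # two groups: F equals the squared pooled t statistic
  two <- list(a = c(1.2, 2.5, 3.1, 2.2), b = c(2.4, 3.3, 4.0, 3.1))
  res2 <- group_anova_bonferroni(two)
  tt <- two_group_ttest(two$a, two$b)
  expect_equal(res2$F, tt$t^2, tolerance = 1e-12)
  expect_equal(res2$p, tt$p, tolerance = 1e-12)
  expect_error(group_anova_bonferroni(list(a = 1, b = c(1, 2))), "a")
})

test_that("two-group t test handles identity and degeneracy", {
  out <- two_group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_error(two_group_ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               "zero variance")
  expect_error(two_group_ttest(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("the t test is calibrated under the null and powered under a shift", {
  set.seed(5)
  p_null <- replicate(200, two_group_ttest(rnorm(10), rnorm(10))$p)
  rej <- mean(p_null < 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
  p_shift <- replicate(100, two_group_ttest(rnorm(10), rnorm(10, 2))$p)
  expect_gte(mean(p_shift < 0.05), 0.9)
})
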