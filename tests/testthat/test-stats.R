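test_that("ANOVA degenerate and two-group identities hold", {
  same <- list(a = rep(5, 8), b = rep(5, 6), c = rep(5, 7))
  a0 <- anova_oneway(same)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  set.seed(41)
  g1 <- rnorm(12, 10, 2); g2 <- rnorm(9, 11, 2)
  a2 <- anova_oneway(list(g1 = g1, g2 = g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)

  expect_error(anova_oneway(list(a = 1:5)), "at least 2")
  expect_error(anova_oneway(list(a = 1:5, b = 3)), "n >= 2")
})

test_that("summary-statistics ANOVA equals the raw decomposition exactly", {
  set.seed(8)
  groups <- list(a = rnorm(11, 0, 1), b = rnorm(23, 0.4, 1.5),
                 c = rnorm(17, -0.2, 0.7), d = rnorm(30, 0.9, 1.1))
  raw <- anova_oneway(groups)
  sm <- data.frame(label = names(groups),
                   n = lengths(groups),
                   mean = vapply(groups, mean, 0),
                   sd = vapply(groups, stats::sd, 0))
  from_sm <- anova_from_summary(sm)
  expect_equal(from_sm$F, raw$F, tolerance = 1e-9)
  expect_equal(from_sm$p, raw$p, tolerance = 1e-9)
  expect_equal(from_sm$df_between, raw$df_between)
  expect_equal(from_sm$df_within, raw$df_within)

  # permutation invariance
  perm <- anova_from_summary(sm[c(3, 1, 4, 2), ])
  expect_equal(perm$F, from_sm$F, tolerance = 1e-12)

  ident <- data.frame(n = c(10, 12), mean = c(3, 3), sd = c(1, 1))
  expect_equal(anova_from_summary(ident)$F, 0)
  expect_error(anova_from_summary(data.frame(n = 5, mean = 1)), "n, mean and sd")
})

test_that("published angle summaries give the reported significance bounds", {
  tabs <- rop_reference_tables()
  tva <- tabs$summaries[tabs$summaries$variable == "TVA", ]
  expect_lt(anova_from_summary(tva)$p, 1e-4)
  taa <- tabs$summaries[tabs$summaries$variable == "TAA", ]
  expect_lt(anova_from_summary(taa)$p, 1e-4)
})

test_that("Tukey-Kramer reproduces the published pairwise pattern for TAA", {
  tabs <- rop_reference_tables()
  taa <- tabs$summaries[tabs$summaries$variable == "TAA", ]
  tk <- tukey_hsd(taa)
  sig <- sort(tk$pair[tk$significant])
  expect_setequal(sig, c("stage1-none", "stage2-none", "stage3-none",
                         "stage3-stage1", "stage3-stage2"))
  expect_false(tk$significant[tk$pair == "stage2-stage1"])
})

test_that("Tukey limits: identical groups, k = 2 reduction, monotone adjustment", {
  same <- list(a = rep(2, 6) + (1:6) * 1e-12, b = rep(2, 6), c = rep(2, 6))
  set.seed(3)
  noisy <- lapply(same, function(x) x + rnorm(length(x), 0, 1))
  tk0 <- tukey_hsd(lapply(noisy, function(x) x - mean(x)))
  expect_false(any(vapply(split(tk0$p_adj, seq_along(tk0$p_adj)),
                          function(p) p < 1e-3, TRUE)))

  set.seed(13)
  g1 <- rnorm(10, 0, 1); g2 <- rnorm(14, 1, 1)
  tk2 <- tukey_hsd(list(g1 = g1, g2 = g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-6)

  # adjusted p never below the unadjusted pairwise p
  set.seed(14)
  gs <- list(a = rnorm(8), b = rnorm(9, 0.5), c = rnorm(10, 1), d = rnorm(7, 0.2))
  tk <- tukey_hsd(gs)
  a <- anova_oneway(gs)
  for (i in seq_len(nrow(tk))) {
    pr <- strsplit(tk$pair[i], "-")[[1]]
    se <- sqrt(a$ms_within * (1 / length(gs[[pr[1]]]) + 1 / length(gs[[pr[2]]])))
    tstat <- abs(mean(gs[[pr[1]]]) - mean(gs[[pr[2]]])) / se
    p_unadj <- 2 * stats::pt(-tstat, a$df_within)
    expect_gte(tk$p_adj[i] + 1e-12, p_unadj)
  }

  # raw-data and summary-statistics routes agree
  sm <- data.frame(label = names(gs), n = lengths(gs),
                   mean = vapply(gs, mean, 0), sd = vapply(gs, stats::sd, 0))
  tk_sm <- tukey_hsd(sm)
  expect_equal(tk$p_adj, tk_sm$p_adj, tolerance = 1e-6)
})

test_that("Pearson correlation: exact linearity, printed-r p-values, null draws", {
  x <- seq(1, 20)
  ct <- pearson(x, 2 * x + 1)
  expect_equal(ct$r, 1, tolerance = 1e-12)
  expect_lt(ct$p, 1e-12)

  # the reported angle-width association at the published sample size
  pr <- pearson_from_r(-0.162, 176)
  expect_gt(pr$p, 0.028); expect_lt(pr$p, 0.035)

  set.seed(77)
  xn <- rnorm(10000); yn <- rnorm(10000)
  expect_lt(abs(pearson(xn, yn)$r), 0.03)

  # symmetry and positive-affine invariance
  set.seed(78)
  u <- rnorm(50); v <- rnorm(50) + 0.5 * u
  expect_equal(pearson(u, v)$r, pearson(v, u)$r, tolerance = 1e-12)
  expect_equal(pearson(3 * u + 7, v)$r, pearson(u, v)$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson(1:2, 1:2), "length")
})

test_that("simulated cohorts reproduce the staging pattern through the pipeline", {
  # At the published group sizes the strict four-group ordering of TAA means
  # holds at the rate fixed by the published stage1/stage2 gap (2.36 deg)
  # against its sampling error (3.37 deg): about 3 in 4 replicates. The
  # headline decrease (no ROP vs stage 3) is essentially certain. The
  # pipeline should reproduce both rates, not inflate them.
  ord <- c("none", "stage1", "stage2", "stage3")
  n_rep <- 60L
  strict <- 0L; headline <- 0L
  for (r in seq_len(n_rep)) {
    cohort <- sample_cohort(cohort_spec(seed = 1000 + r))
    m <- tapply(cohort$TAA, cohort$stage, mean)[ord]
    if (all(diff(m) < 0)) strict <- strict + 1L
    if (m[1] > m[4]) headline <- headline + 1L
  }
  expect_equal(headline, n_rep)
  expect_gt(strict / n_rep, 0.5)   # binomial range around the analytic 0.76
  expect_lt(strict / n_rep, 0.95)

  rep <- cohort_report(sample_cohort(cohort_spec(seed = 5)))
  expect_lt(rep$anova$TAA$p, 1e-4)
  expect_true(all(c("TAA", "TVA", "TAW", "TVW") %in% names(rep$anova)))
})

test_that("normality report covers every stage-variable cell", {
  cohort <- sample_cohort(cohort_spec(seed = 2))
  nr <- normality_report(cohort)
  expect_equal(nrow(nr), 4 * 4)
  expect_true(all(nr$W > 0 & nr$W <= 1))
})
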