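test_that("ddCt fold changes hit the algebraic anchors", {
  q <- simulate_qpcr(c(g = 2), n = 4, noise_sd = 0, seed = 1)
  f <- ddct_fold_change(q)
  expect_equal(f$fold[f$group == "control"], 1)
  expect_equal(f$fold[f$group == "treatment"], 2)
  expect_error(ddct_fold_change(q, control_group = "nope"), "control")
  bad <- q; bad$ct_target[1] <- 60
  expect_error(ddct_fold_change(bad), "cycle range")
})

test_that("ddCt is invariant to per-sample plate offsets", {
  q <- simulate_qpcr(c(g1 = 4, g2 = 0.5), n = 6, noise_sd = 0.2, seed = 7)
  f1 <- ddct_fold_change(q)
  shifted <- q
  set.seed(11)
  off <- rnorm(nrow(q), 0, 2)
  shifted$ct_target <- shifted$ct_target + off
  shifted$ct_reference <- shifted$ct_reference + off
  f2 <- ddct_fold_change(shifted)
  expect_equal(f2$fold, f1$fold, tolerance = 1e-10)
})

test_that("percent reduction handles the boundary cases and both scales", {
  expect_equal(percent_reduction(c(5, 5, 5), c(5, 5, 5))$estimate, 0)
  expect_equal(percent_reduction(c(0, 0, 0), c(4, 5, 6))$estimate, 100)
  pr_sd <- percent_reduction(c(2, 3, 4), c(8, 9, 10), scale = "sd")
  pr_sem <- percent_reduction(c(2, 3, 4), c(8, 9, 10), scale = "sem")
  expect_equal(pr_sd$uncertainty / pr_sem$uncertainty, sqrt(3),
               tolerance = 1e-10)
  pr_b <- percent_reduction(c(2, 3, 4), c(8, 9, 10), method = "bootstrap",
                            n_boot = 500, seed = 2)
  expect_true(is.finite(pr_b$uncertainty))
})

test_that("percent reduction is antisymmetric under the role-swap transform", {
  a <- c(2.1, 2.4, 2.8, 2.2); b <- c(5.2, 4.7, 5.5, 5.1)
  p <- percent_reduction(a, b)$estimate
  q <- percent_reduction(b, a)$estimate
  # swapping roles maps p -> 100 * (1 - 1 / (1 - p/100))
  expect_equal(q, 100 * (1 - 1 / (1 - p / 100)), tolerance = 1e-10)
})

test_that("the reduction estimator is unbiased at the planted in vivo effect", {
  ests <- vapply(seq_len(800), function(i) {
    g <- simulate_group_counts(c(il1b = 5e8, treated = 5e8 * 0.49),
                               cv = 0.19, n = 5, seed = 5000 + i)
    percent_reduction(g$value[g$group == "treated"],
                      g$value[g$group == "il1b"])$estimate
  }, numeric(1))
  # mean over replicate studies approaches the planted 51% (small
  # second-order bias from the ratio of means is tolerated)
  expect_equal(mean(ests), 51, tolerance = 0.03)
})

test_that("one-way ANOVA matches its algebraic identities", {
  # identical groups: zero between-group variance
  v <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  a <- anova_tukey(v, g)
  expect_equal(a$f_statistic, 0)
  expect_gt(a$p_value, 0.99)
  # two groups: F equals the square of the two-sample t statistic
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8, 1)
  a2 <- anova_tukey(c(x, y), rep(c("x", "y"), each = 8))
  tt <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(a2$f_statistic, unname(tt^2), tolerance = 1e-10)
  expect_error(anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("a 5-SD-shifted group is flagged in all its pairwise comparisons", {
  hits <- vapply(seq_len(400), function(i) {
    set.seed(6000 + i)
    v <- c(rnorm(5, 10, 1), rnorm(5, 10, 1), rnorm(5, 10, 1),
           rnorm(5, 15, 1))
    g <- rep(c("a", "b", "c", "shifted"), each = 5)
    a <- anova_tukey(v, g)
    sh <- grepl("shifted", a$tukey$comparison)
    all(a$tukey$p_adj[sh] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("EV dose-response reuses the logistic machinery", {
  ev <- simulate_ev_study(emax = 90, ec50 = 0.3, dispersion_cv = 0,
                          seed = 1)
  f <- ev_dose_response(ev[ev$arm == "active", ])
  expect_equal(f$ec50, 0.3, tolerance = 0.01)
  expect_equal(f$emax, 90, tolerance = 0.5)
  # the inactive-analog arm shows no effect
  f0 <- ev_dose_response(ev[ev$arm == "inactive_analog", ])
  expect_lt(abs(f0$emax), 5)
  expect_equal(crc_classify(f0), 4)
  # a single nonzero dose cannot support a fit
  one <- ev[ev$dose_um %in% c(0, 1), ]
  expect_error(ev_dose_response(one), "2 nonzero doses")
})
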