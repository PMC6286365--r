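test_that("percent_inhibition complements the activity ratio", {
  expect_equal(percent_inhibition(5, 5), 0)
  expect_equal(percent_inhibition(0, 5), 100)
  expect_equal(percent_inhibition(2.5, 5), 50)
  expect_equal(percent_inhibition(-10, 5), 110) # clipped overshoot
  expect_equal(percent_inhibition(-10, 5, clip = FALSE), 300)
  expect_error(percent_inhibition(1, 0), "control rate")
})

test_that("fit_4pl recovers noise-free parameters to 4 significant figures", {
  d <- 10^seq(-3, 2, length.out = 11)
  y <- make_curve(d, top = 100, ic50 = 1, hill = 1)
  f <- fit_4pl(d, y)
  expect_true(f$converged)
  expect_equal(f$ic50, 1, tolerance = 1e-4)
  expect_equal(f$top, 100, tolerance = 1e-4)
  expect_equal(f$bottom, 0, tolerance = 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  expect_equal(f$r2, 1, tolerance = 1e-8)
  expect_equal(f$n_asymptotes, 2L)
})

test_that("fitted IC50 is equivariant under dose rescaling", {
  d <- 10^seq(-2, 2, length.out = 9)
  y <- make_curve(d, top = 90, ic50 = 0.5, hill = 1.5)
  f1 <- fit_4pl(d, y)
  for (k in c(0.01, 3, 1000)) {
    f2 <- fit_4pl(d * k, y)
    expect_equal(f2$ic50, f1$ic50 * k, tolerance = 1e-4)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
    expect_equal(f2$efficacy, f1$efficacy, tolerance = 1e-6)
    expect_equal(crc_classify(f2), crc_classify(f1))
  }
})

test_that("activation (negative response) curves classify as inactive", {
  d <- 10^seq(-2, 2, length.out = 8)
  y <- -make_curve(d, top = 40, ic50 = 1) # monotone-decreasing activation
  f <- fit_4pl(d, y)
  expect_equal(crc_classify(f), 4)
})

test_that("curve-response classes follow completeness and efficacy", {
  d <- 10^seq(-3, 2, length.out = 11)
  # flat: inactive
  expect_equal(crc_classify(fit_4pl(d, rep(0, 11))), 4)
  # complete curve, high efficacy
  expect_equal(crc_classify(fit_4pl(d, make_curve(d, 95, 0.3))), -1.1)
  # complete curve, partial efficacy
  expect_equal(crc_classify(fit_4pl(d, make_curve(d, 50, 0.3))), -1.2)
  # upper plateau missing (midpoint near top dose), high efficacy
  f2 <- fit_4pl(d, make_curve(d, 85 / (1 + 30 / 1e5), 30))
  expect_lt(f2$n_asymptotes, 2)
  expect_equal(crc_classify(f2), -2.1)
  # single-dose spike: activity without an interpretable curve
  spike <- c(rep(0, 10), 80)
  expect_equal(crc_classify(fit_4pl(d, spike)), -3)
  # weak partial curve below the floor
  expect_equal(crc_classify(fit_4pl(d, make_curve(d, 20, 0.3))), 4)
})

test_that("completing a partial curve never demotes its class", {
  d_part <- 10^seq(-3, 1, length.out = 8)
  d_full <- 10^seq(-3, 3, length.out = 12)
  for (ic50 in c(3, 10, 30)) {
    cls_part <- crc_classify(fit_4pl(d_part, make_curve(d_part, 90, ic50)))
    cls_full <- crc_classify(fit_4pl(d_full, make_curve(d_full, 90, ic50)))
    rank <- function(cl) match(cl, c(4, -3, -2.2, -2.1, -1.2, -1.1))
    expect_gte(rank(cls_full), rank(cls_part))
  }
})

test_that("far-extrapolated midpoints demote the curve subclass", {
  d <- 10^seq(-1, 1, length.out = 8)
  # true midpoint 3 logs above the top dose: fitted IC50 extrapolates
  y <- make_curve(d, 95, 1e4) + c(rep(0, 7), 45) # force visible response
  f <- fit_4pl(d, make_curve(10^seq(-1, 1, length.out = 8), 95, 500))
  if (f$converged && is.finite(f$ic50)) {
    expect_true(f$extrapolated)
    expect_false(crc_classify(f) %in% c(-1.1, -2.1))
  }
})

test_that("constrained 4-dose fits pin the bottom and bound the slope", {
  d <- dose_scheme()
  y <- make_curve(d, 90, 2)
  f <- fit_4pl(d, y)
  expect_true(f$constrained)
  expect_equal(f$bottom, 0)
  expect_gte(f$hill, 0.5)
  expect_lte(f$hill, 3)
  expect_equal(f$ic50, 2, tolerance = 0.01)
})

test_that("bootstrap IC50 intervals behave at the noise extremes", {
  d <- 10^seq(-3, 2, length.out = 16)
  y <- make_curve(d, 100, 0.5)
  f <- fit_4pl(d, y)
  ci0 <- ic50_with_ci(f, n_boot = 50, seed = 1)
  expect_equal(ci0$lower, ci0$upper, tolerance = 1e-6) # zero-width
  pt <- ic50_with_ci(f, n_boot = 0)
  expect_equal(pt$ic50, f$ic50)
  expect_true(is.na(pt$lower))
})

test_that("bootstrap intervals cover the planted IC50", {
  cover <- vapply(seq_len(120), function(i) {
    set.seed(3000 + i)
    d <- 10^seq(-3, 2, length.out = 16)
    y <- make_curve(d, 100, 0.5, cv = 0.05)
    f <- fit_4pl(d, y)
    ci <- ic50_with_ci(f, n_boot = 200, seed = i)
    ci$lower <= 0.5 && 0.5 <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("fit_screen returns one classified row per compound", {
  s <- small_screen(n = 80, noise = FALSE, seed = 4)
  res <- fit_screen(plate_inhibition(s$plates))
  expect_equal(sort(res$compound_id), sort(s$compounds$compound_id))
  expect_true(all(res$crc_class %in% c(-1.1, -1.2, -2.1, -2.2, -3, 4)))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1, na.rm = TRUE))
  # planted inactives are classified inactive without noise
  inert <- s$compounds$compound_id[s$compounds$class_label == "inactive"]
  expect_true(all(res$crc_class[res$compound_id %in% inert] == 4))
})
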