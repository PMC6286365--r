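test_that("simulate_rate reproduces Michaelis-Menten and noncompetitive anchors", {
  am <- assay_model()
  # at S = Km with no inhibitor the rate is Vmax/2
  expect_equal(simulate_rate(am, substrate = am$Km_SM, inhibitor = 0,
                             mode = "none"),
               am$Vmax / 2)
  # at I = Ki the noncompetitive rate is half the uninhibited rate at any S
  for (S in c(2, 10, 20, 80)) {
    v0 <- simulate_rate(am, S, 0, true_ic50 = 0.03)
    expect_equal(simulate_rate(am, S, 0.03, true_ic50 = 0.03), v0 / 2)
  }
  # partial efficacy scales the inhibited fraction
  v0 <- simulate_rate(am, 20, 0, true_ic50 = 1)
  expect_equal(simulate_rate(am, 20, 1e9, true_ic50 = 1, efficacy = 60),
               v0 * 0.4, tolerance = 1e-6)
})

test_that("simulate_rate validates kinetic parameters", {
  am <- assay_model()
  expect_error(simulate_rate(am, substrate = 0, inhibitor = 1,
                             true_ic50 = 1), "substrate")
  expect_error(simulate_rate(am, 20, -1, true_ic50 = 1), "inhibitor")
  expect_error(simulate_rate(am, 20, 1, true_ic50 = -2), "true_ic50")
  expect_error(assay_model(Vmax = -1), "Vmax")
  expect_error(assay_model(Km_SM = 0), "Km_SM")
})

test_that("a noncompetitive rate sweep refits to its planted midpoint", {
  am <- assay_model()
  d <- 10^seq(-4, 2, length.out = 16)
  v0 <- simulate_rate(am, 20, 0, mode = "none")
  v <- simulate_rate(am, 20, d, true_ic50 = 0.03)
  fit <- fit_4pl(d, percent_inhibition(v, v0))
  expect_equal(fit$ic50, 0.03, tolerance = 1e-4)
  expect_equal(fit$top, 100, tolerance = 1e-3)
})

test_that("expected signal is nondecreasing in time, enzyme and substrate", {
  am <- assay_model(Vmax = 0.5) # keep product under the depletion guard
  times <- seq(15, 150, by = 15)
  enz <- seq(0.03, 0.2, length.out = 6)
  sm <- seq(5, 40, length.out = 6)
  expect_true(all(diff(expected_rfu(am, time = times)) >= 0))
  expect_true(all(diff(expected_rfu(am, enzyme = enz)) >= 0))
  expect_true(all(diff(expected_rfu(am, substrate = sm)) >= 0))
})

test_that("plate layout assigns every well exactly one role and a 1:2 series", {
  lay <- plate_layout()
  expect_equal(nrow(lay$wells), 1536)
  expect_false(any(is.na(lay$wells$role)))
  expect_equal(anyDuplicated(paste(lay$wells$row, lay$wells$col)), 0L)
  doses <- lay$pos_series_doses
  expect_equal(length(doses), 16)
  expect_equal(doses[1], 285)
  expect_equal(unique(round(doses[-length(doses)] / doses[-1], 10)), 2)
})

test_that("noise-free plates put every inactive test well at the positive-control mean", {
  am <- noise_free_assay()
  cmp <- compound_library(60, prop_true = 0, prop_counter_fp = 0,
                          prop_promiscuous = 0, seed = 1)
  pl <- simulate_plate(plate_layout(), am, cmp, doses = 57, seed = 1)
  pos_mean <- mean(pl$rfu[pl$role == "pos_control"])
  test_wells <- pl$rfu[pl$role == "compound" & !is.na(pl$compound_id)]
  expect_equal(test_wells, rep(pos_mean, length(test_wells)))
})

test_that("default generator reproduces the ~2500 RFU working signal", {
  s <- small_screen(n = 100, noise = TRUE, seed = 42)
  pos <- s$plates$rfu[s$plates$role == "pos_control"]
  # within 2 CV of the nominal 2500 RFU
  expect_lt(abs(mean(pos) - 2500), 2 * 0.05 * 2500)
})

test_that("plate simulation is a pure function of (parameters, seed)", {
  am <- assay_model()
  cmp <- compound_library(50, seed = 3)
  a <- simulate_plate(plate_layout(), am, cmp, seed = 9)
  b <- simulate_plate(plate_layout(), am, cmp, seed = 9)
  expect_identical(a, b)
  pk1 <- simulate_pk(seed = 4)
  pk2 <- simulate_pk(seed = 4)
  expect_identical(pk1, pk2)
  expect_identical(simulate_qpcr(c(a = 2), seed = 8),
                   simulate_qpcr(c(a = 2), seed = 8))
})

test_that("counter plates separate target inhibitors from cascade inhibitors", {
  am <- noise_free_assay()
  cmp <- data.frame(
    compound_id = c("TRUE1", "CFP1", "INERT"),
    class_label = c("true_inhibitor", "counter_false_positive",
                    "inactive"),
    true_ic50 = c(0.1, NA, NA),
    true_efficacy = c(100, 100, 0),
    counter_ic50 = c(NA, 1, NA),
    promiscuity_flag = FALSE, stringsAsFactors = FALSE)
  pl <- simulate_counter_plate(plate_layout(), am, cmp, doses = 100,
                               seed = 1)
  inh <- plate_inhibition(pl)
  # a genuine target inhibitor shows no inhibition of the cascade at 100 uM
  expect_equal(inh$pct_inhibition[inh$compound_id == "TRUE1"], 0)
  expect_equal(inh$pct_inhibition[inh$compound_id == "INERT"], 0)
  # a cascade inhibitor at its counter IC50 gives 50%
  pl2 <- simulate_counter_plate(plate_layout(), am, cmp, doses = 1,
                                seed = 1)
  inh2 <- plate_inhibition(pl2)
  expect_equal(inh2$pct_inhibition[inh2$compound_id == "CFP1"], 50)
  # and suppresses the main-assay readout too
  pl3 <- simulate_plate(plate_layout(), am, cmp, doses = 1, seed = 1)
  inh3 <- plate_inhibition(pl3)
  expect_equal(inh3$pct_inhibition[inh3$compound_id == "CFP1"], 50)
})

test_that("empty dose scheme and malformed ground truth are rejected", {
  am <- assay_model()
  cmp <- compound_library(10, seed = 1)
  expect_error(simulate_plate(plate_layout(), am, cmp, doses = numeric(0)),
               "dose")
  bad <- cmp; bad$true_ic50[bad$class_label == "true_inhibitor"] <- -1
  if (any(bad$class_label == "true_inhibitor")) {
    expect_error(simulate_plate(plate_layout(), am, bad, doses = 57),
                 "true_ic50")
  }
  bad2 <- cmp; bad2$counter_ic50 <- NULL
  expect_error(validate_ground_truth(bad2), "counter_ic50")
})

test_that("PK generator recovers its own elimination and partition constants", {
  # near-instant absorption: monoexponential decay, lambda_z = ke
  pk <- simulate_pk(A = 10, ka = 500, ke = 1, noise_cv = 0, seed = 1,
                    times = c(0.25, 0.5, 1, 2, 4, 6))
  r <- nca(pk[pk$matrix == "plasma", ])
  expect_equal(r$lambda_z, 1, tolerance = 0.02)
  # brain partition round-trips through the AUC ratio exactly (noise-free)
  pk2 <- simulate_pk(noise_cv = 0, seed = 1)
  rb <- nca(pk2[pk2$matrix == "brain", ])
  rp <- nca(pk2[pk2$matrix == "plasma", ])
  expect_equal(auc_ratio(rb, rp), 0.26, tolerance = 1e-6)
})

test_that("per-time PK means have the expected composite-design CV", {
  vals <- vapply(seq_len(600), function(i) {
    pk <- simulate_pk(noise_cv = 0.1, n_per_time = 3, seed = 1000 + i,
                      times = 0.5)
    mean(pk$conc[pk$matrix == "plasma"])
  }, numeric(1))
  expect_equal(sd(vals) / mean(vals), 0.1 / sqrt(3), tolerance = 0.12)
})

test_that("EV study generator plants its dose-response truth", {
  # zero effect: every dose mean equals the baseline (noise-free)
  ev0 <- simulate_ev_study(emax = 0, dispersion_cv = 0, seed = 1,
                           include_inactive_analog = FALSE)
  expect_equal(unique(ev0$ev_per_ml), 1e9)
  # complete inhibition far above the EC50 drops counts to the floor
  ev1 <- simulate_ev_study(doses = c(0, 1e5), emax = 100, ec50 = 0.3,
                           floor = 2e7, dispersion_cv = 0, seed = 1,
                           include_inactive_analog = FALSE)
  expect_equal(mean(ev1$ev_per_ml[ev1$dose_um == 1e5]), 2e7,
               tolerance = 1e-3)
  # the inactive-analog arm carries no dose trend
  ev2 <- simulate_ev_study(dispersion_cv = 0, seed = 1)
  ana <- ev2[ev2$arm == "inactive_analog", ]
  expect_equal(unique(ana$ev_per_ml), 1e9)
})

test_that("qPCR generator and ddCt analysis invert each other", {
  # fold 1: ddCt 0, fold recovered exactly
  q1 <- simulate_qpcr(c(gene1 = 1), n = 4, noise_sd = 0, seed = 1)
  f1 <- ddct_fold_change(q1)
  expect_equal(f1$fold[f1$group == "treatment"], 1)
  # fold 2 implies ddCt exactly -1 without noise
  q2 <- simulate_qpcr(c(gene1 = 2), n = 4, noise_sd = 0, seed = 1)
  f2 <- ddct_fold_change(q2)
  expect_equal(f2$mean_ddct[f2$group == "treatment"], -1)
  expect_equal(f2$fold[f2$group == "treatment"], 2)
  # planted fold 4 with 0.1-cycle noise: mean recovered fold within 5%
  folds <- vapply(seq_len(500), function(i) {
    q <- simulate_qpcr(c(g = 4), n = 5, noise_sd = 0.1, seed = 2000 + i)
    f <- ddct_fold_change(q)
    f$fold[f$group == "treatment"]
  }, numeric(1))
  expect_equal(mean(folds), 4, tolerance = 0.05)
})
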