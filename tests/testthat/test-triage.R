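# helper to fabricate a results row
res_row <- function(id, crc, ic50 = 1, max_resp = 90, eff = 90) {
  data.frame(compound_id = id, assay_id = "x", n_doses = 7,
             max_response = max_resp, bottom = 0, top = eff, ic50 = ic50,
             hill = 1, r2 = 0.99, efficacy = eff, n_asymptotes = 2,
             converged = TRUE, extrapolated = FALSE, crc_class = crc,
             stringsAsFactors = FALSE)
}

test_that("primary selection enforces the response and class rules", {
  res <- rbind(
    res_row("A", -1.1, max_resp = 90),   # selected
    res_row("B", -1.1, max_resp = 49),   # boundary: excluded at <= 50
    res_row("C", -3, max_resp = 80),     # single-dose class: excluded
    res_row("D", -2.2, max_resp = 60),   # selected
    res_row("E", 4, max_resp = 20))      # inactive
  sel <- select_primary(res)
  expect_equal(sel$primary_selected, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_true(all(nzchar(sel$reasons[!sel$primary_selected])))
})

test_that("the promiscuity flag removes selected compounds", {
  res <- rbind(res_row("A", -1.1), res_row("B", -1.1))
  cmp <- data.frame(compound_id = c("A", "B"),
                    promiscuity_flag = c(TRUE, FALSE))
  sel <- select_primary(res, cmp)
  expect_true(sel$promiscuous_removed[sel$compound_id == "A"])
  expect_false(sel$promiscuous_removed[sel$compound_id == "B"])
  expect_equal(sel$reasons[sel$compound_id == "A"], "promiscuous")
})

test_that("confirmation requires a selectable class in the refit", {
  expect_equal(nrow(confirm(res_row("X", -1.1)[0, ])), 0)
  c1 <- confirm(rbind(res_row("A", -1.2), res_row("B", -3)))
  expect_equal(c1$confirmed, c(TRUE, FALSE))
})

test_that("counter-screen filter separates bona fide, differential and false positives", {
  # counter flat at 100 uM: bona fide
  main <- res_row("A", -1.1, ic50 = 0.5)
  ctr_flat <- res_row("A", 4, ic50 = NA, max_resp = 3, eff = 2)
  expect_equal(counter_screen_filter(main, ctr_flat)$counter_verdict,
               "bona_fide")
  # main 0.1 uM vs counter 50 uM full curves: 2.7-log gap, differential
  main2 <- res_row("B", -1.1, ic50 = 0.1)
  ctr2 <- res_row("B", -1.1, ic50 = 50)
  expect_equal(counter_screen_filter(main2, ctr2)$counter_verdict,
               "differential")
  # identical curves in both assays: counter-active
  main3 <- res_row("C", -1.1, ic50 = 1)
  expect_equal(counter_screen_filter(main3, res_row("C", -1.1, ic50 = 1))$counter_verdict,
               "counter_active")
  # weak counter efficacy rescues even without a potency gap
  ctr4 <- res_row("D", -1.2, ic50 = 1, eff = 40)
  main4 <- res_row("D", -1.1, ic50 = 1)
  expect_equal(counter_screen_filter(main4, ctr4)$counter_verdict,
               "differential")
})

test_that("the potency gate is inclusive at 10 uM", {
  v <- data.frame(compound_id = c("A", "B", "C"),
                  confirmed = c(TRUE, TRUE, TRUE),
                  counter_active = c(FALSE, TRUE, FALSE),
                  main_ic50 = c(10, 9, 10.5),
                  reasons = "", stringsAsFactors = FALSE)
  out <- finalize(v)
  expect_equal(out$final_hit, c(TRUE, FALSE, FALSE))
})

test_that("flowchart arithmetic identities hold", {
  tc <- triage_counts(1990, 1782, 1718, 156)
  expect_identical(tc$bona_fide, 64)
  expect_identical(tc$advanced, 220)
  expect_equal(round(tc$confirmation_rate_pct), 90)
  expect_equal(round(tc$counter_fp_rate_pct), 86)
  expect_error(triage_counts(10, 12, 1, 0), "confirmed")
  expect_error(triage_counts(10, 8, 9, 0), "counter_fp")
})

test_that("triage stages are monotone and conservative", {
  cfg <- default_config()
  cfg$synth$n_compounds <- 200L
  out <- run_pipeline(cfg, seed = 21, outdir = tempfile())
  rep <- out$flowchart
  # subset chain: selected >= confirmed >= bona fide; conservation
  expect_lte(rep$confirmed, rep$selected)
  expect_lte(rep$counter_fp, rep$confirmed)
  expect_equal(rep$advanced, rep$bona_fide + rep$differential)
  expect_lte(rep$final_hits, rep$advanced)
  expect_equal(rep$screened, 200)
})

test_that("an empty screen produces an all-zero report", {
  v <- data.frame(compound_id = character(0),
                  primary_selected = logical(0),
                  promiscuous_removed = logical(0),
                  confirmed = logical(0), counter_active = logical(0),
                  differential_rescued = logical(0),
                  final_hit = logical(0), main_ic50 = numeric(0),
                  reasons = character(0))
  rep <- triage_report(v)
  expect_equal(rep$screened, 0)
  expect_equal(rep$advanced, 0)
  expect_equal(rep$final_hits, 0)
})

test_that("noise-free triage recovers the planted hit set exactly", {
  cfg <- default_config()
  cfg$synth$n_compounds <- 200L
  cfg$synth$noise_cv <- 0
  cfg$synth$read_noise_sd <- 0
  out <- run_pipeline(cfg, seed = 31, outdir = tempfile())
  expect_equal(out$recovery$sensitivity, 1)
  expect_equal(out$recovery$specificity, 1)
  expect_equal(out$recovery$false_positives, 0)
})
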