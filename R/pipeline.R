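#' Run the full synthetic screening pipeline end-to-end
#'
#' Generates a synthetic compound library and primary 4-dose screen, runs
#' plate QC, fits and classifies every compound, applies the triage cascade
#' (primary selection, promiscuity removal, 7-dose confirmation, 7-dose
#' counter screen with differential rescue, potency gate), and compares the
#' final hit set against the planted ground truth. Stage outputs are
#' written as CSV files plus a machine-readable `summary.json`; the run is
#' a pure function of (config, seed), so a rerun writes a byte-identical
#' summary.
#'
#' @param config Configuration list ([default_config()] /
#'   [read_config()]).
#' @param seed Integer seed for all stochastic stages.
#' @param outdir Output directory (created; default a tempdir run folder).
#' @return Invisibly, the summary list (config hash, seed, QC summary,
#'   flowchart counts from [triage_report()], ground-truth recovery).
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         outdir = file.path(tempdir(), "qhts_run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sy <- config$synth
  layout <- plate_layout()
  assay <- assay_model(noise_cv = sy$noise_cv,
                       read_noise_sd = sy$read_noise_sd)
  thresholds <- do.call(crc_thresholds, config$dose_response)
  rules <- do.call(triage_rules, config$triage)

  compounds <- compound_library(
    n = sy$n_compounds, prop_true = sy$prop_true,
    prop_counter_fp = sy$prop_counter_fp,
    prop_promiscuous = sy$prop_promiscuous,
    ic50_range = sy$ic50_range, efficacy_range = sy$efficacy_range,
    counter_ic50_range = sy$counter_ic50_range, seed = seed)
  write_table_csv(compounds, file.path(outdir, "compounds.csv"))

  primary_doses <- dose_scheme(sy$primary_doses$top, sy$primary_doses$n,
                               sy$primary_doses$fold)
  plates <- simulate_plate(layout, assay, compounds, primary_doses,
                           seed = seed,
                           pos_series_ic50 = sy$pos_series_ic50)
  write_plate_csv(plates, file.path(outdir, "plates_primary.csv"))

  qc_tab <- plate_qc(plates, threshold = config$qc$positional_threshold,
                     z_min = config$qc$z_min)
  write_table_csv(qc_tab, file.path(outdir, "plate_qc.csv"))

  primary <- fit_screen(plate_inhibition(plates), assay_id = "primary",
                        thresholds = thresholds)
  write_table_csv(primary, file.path(outdir, "results_primary.csv"))

  sel <- select_primary(primary, compounds, rules)
  advancing <- sel$compound_id[sel$primary_selected &
                                 !sel$promiscuous_removed]
  confirm_doses <- dose_scheme(sy$confirm_doses$top, sy$confirm_doses$n,
                               sy$confirm_doses$fold)
  confirmation <- counter <- NULL
  if (length(advancing)) {
    sub <- compounds[compounds$compound_id %in% advancing, , drop = FALSE]
    conf_plates <- simulate_plate(layout, assay, sub, confirm_doses,
                                  seed = seed + 1L,
                                  pos_series_ic50 = sy$pos_series_ic50,
                                  plate_prefix = "confirm")
    confirmation <- fit_screen(plate_inhibition(conf_plates),
                               assay_id = "confirmation",
                               thresholds = thresholds)
    write_table_csv(confirmation,
                    file.path(outdir, "results_confirmation.csv"))
    counter_plates <- simulate_counter_plate(layout, assay, sub,
                                             confirm_doses,
                                             seed = seed + 2L)
    counter <- fit_screen(plate_inhibition(counter_plates),
                          assay_id = "counter", thresholds = thresholds)
    write_table_csv(counter, file.path(outdir, "results_counter.csv"))
  }

  verdicts <- triage_screen(primary, confirmation, counter, compounds,
                            rules)
  write_table_csv(verdicts, file.path(outdir, "verdicts.csv"))
  report <- triage_report(verdicts)

  recovery <- recovery_stats(verdicts, compounds, rules$potency_gate)

  summary <- list(
    seed = seed,
    config_hash = config_hash(config),
    config = config,
    qc = list(plates = nrow(qc_tab),
              all_pass = all(qc_tab$pass),
              mean_z_prime = mean(qc_tab$z_prime),
              mean_signal_to_background =
                mean(qc_tab$signal_to_background)),
    flowchart = report,
    recovery = recovery
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outdir, "summary.json"))
  invisible(summary)
}

#' Compare triage verdicts against planted ground truth
#'
#' The expected hit set is the planted true inhibitors whose true IC50
#' passes the potency gate; sensitivity is the fraction of those recovered
#' as final hits, specificity the fraction of all other compounds correctly
#' rejected.
#'
#' @param verdicts Verdict table from [triage_screen()].
#' @param compounds Ground-truth table.
#' @param potency_gate Final IC50 gate, uM.
#' @return List: expected_hits, recovered, false_positives, sensitivity,
#'   specificity.
#' @export
recovery_stats <- function(verdicts, compounds, potency_gate = 10) {
  i <- match(verdicts$compound_id, compounds$compound_id)
  truth <- compounds$class_label[i] == "true_inhibitor" &
    !is.na(compounds$true_ic50[i]) & compounds$true_ic50[i] <= potency_gate
  hit <- verdicts$final_hit
  list(
    expected_hits = sum(truth),
    recovered = sum(hit & truth),
    false_positives = sum(hit & !truth),
    sensitivity = if (sum(truth)) sum(hit & truth) / sum(truth) else NaN,
    specificity = if (sum(!truth)) sum(!hit & !truth) / sum(!truth)
                  else NaN
  )
}
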