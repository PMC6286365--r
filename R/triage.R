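#' Default triage rule settings
#'
#' @param min_top_response Percent inhibition required at the highest tested
#'   dose for primary selection.
#' @param selectable_classes CRC classes admissible for selection and
#'   confirmation.
#' @param partial_floor Percent efficacy below which a counter curve counts
#'   as inactive under the threshold rule.
#' @param pic50_gap Log10 potency difference (main vs counter) that rescues
#'   a counter-active compound as a differential hit.
#' @param counter_eff_max Counter-assay efficacy (percent) below which a
#'   counter-active compound is rescued.
#' @param counter_rule "class" (counter inactive iff its CRC is 4) or
#'   "threshold" (counter inactive iff its efficacy is below
#'   `partial_floor`).
#' @param potency_gate Final IC50 gate, uM (inclusive).
#' @return Named list of triage settings.
#' @export
triage_rules <- function(min_top_response = 50,
                         selectable_classes = c(-1.1, -1.2, -2.1, -2.2),
                         partial_floor = 30, pic50_gap = 1,
                         counter_eff_max = 50,
                         counter_rule = c("class", "threshold"),
                         potency_gate = 10) {
  list(min_top_response = min_top_response,
       selectable_classes = selectable_classes,
       partial_floor = partial_floor, pic50_gap = pic50_gap,
       counter_eff_max = counter_eff_max,
       counter_rule = match.arg(counter_rule),
       potency_gate = potency_gate)
}

top_dose_response <- function(results, inhibition = NULL) {
  # max_response at the top tested dose is carried in the results table
  results$max_response
}

#' Primary hit selection
#'
#' A compound is selected when its maximal inhibitory response at the
#' highest tested dose exceeds `min_top_response` (default 50%) and its
#' curve-response class is robust (-1.1, -1.2, -2.1 or -2.2). Compounds
#' carrying the promiscuity flag are then removed before confirmation.
#'
#' @param results Per-compound results from [fit_screen()] on the primary
#'   (4-dose) screen.
#' @param compounds Optional ground-truth/annotation table supplying
#'   `promiscuity_flag` per compound_id.
#' @param rules [triage_rules()].
#' @return Data frame: compound_id, primary_selected, promiscuous_removed,
#'   reasons (character; non-empty for every non-advancing compound).
#' @export
select_primary <- function(results, compounds = NULL,
                           rules = triage_rules()) {
  top <- results$max_response
  cls_ok <- results$crc_class %in% rules$selectable_classes
  sel <- top > rules$min_top_response & cls_ok
  prom <- rep(FALSE, nrow(results))
  if (!is.null(compounds)) {
    prom <- compounds$promiscuity_flag[
      match(results$compound_id, compounds$compound_id)]
    prom[is.na(prom)] <- FALSE
  }
  reasons <- character(nrow(results))
  reasons[!sel & top <= rules$min_top_response] <- "primary:low_response"
  reasons[!sel & !cls_ok] <- paste0(
    reasons[!sel & !cls_ok],
    ifelse(nzchar(reasons[!sel & !cls_ok]), ";", ""), "primary:crc")
  reasons[sel & prom] <- "promiscuous"
  data.frame(compound_id = results$compound_id,
             primary_selected = sel,
             promiscuous_removed = sel & prom,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Confirmation in the 7-dose refit
#'
#' A selected compound is confirmed when its refit retains a selectable
#' curve-response class under the primary class rule.
#'
#' @param results7 Per-compound results from [fit_screen()] on the 7-dose
#'   confirmatory assay.
#' @param rules [triage_rules()].
#' @return Data frame: compound_id, confirmed.
#' @export
confirm <- function(results7, rules = triage_rules()) {
  data.frame(compound_id = results7$compound_id,
             confirmed = results7$crc_class %in% rules$selectable_classes,
             stringsAsFactors = FALSE)
}

#' Counter-screen classification
#'
#' Compares each compound's main-assay and counter-assay curves.
#' `bona_fide`: the counter curve is inactive (class 4 by default, or
#' efficacy below the partial floor under the threshold rule).
#' `differential`: the counter curve is active but much weaker -- the main
#' potency exceeds the counter potency by at least `pic50_gap` log units,
#' or the counter efficacy is below `counter_eff_max` -- so the compound is
#' rescued as a differential hit. Otherwise `counter_active`.
#'
#' @param main,counter Per-compound results ([fit_screen()]) from the main
#'   and counter assays; matched by compound_id.
#' @param rules [triage_rules()].
#' @return Data frame: compound_id, counter_verdict (bona_fide /
#'   differential / counter_active), counter_active, differential_rescued.
#' @export
counter_screen_filter <- function(main, counter, rules = triage_rules()) {
  i <- match(main$compound_id, counter$compound_id)
  if (anyNA(i)) stop_bad("counter results missing for some compounds")
  co <- counter[i, , drop = FALSE]
  inactive <- if (rules$counter_rule == "class") {
    co$crc_class == 4
  } else {
    !is.finite(co$efficacy) | co$efficacy < rules$partial_floor
  }
  gap <- log10(co$ic50) - log10(main$ic50) # pIC50_main - pIC50_counter
  weak <- (!is.na(gap) & gap >= rules$pic50_gap) |
    (is.finite(co$efficacy) & co$efficacy < rules$counter_eff_max)
  verdict <- ifelse(inactive, "bona_fide",
                    ifelse(weak, "differential", "counter_active"))
  data.frame(compound_id = main$compound_id,
             counter_verdict = verdict,
             counter_active = verdict == "counter_active",
             differential_rescued = verdict == "differential",
             stringsAsFactors = FALSE)
}

#' Final potency gate
#'
#' A compound is a final hit when it is confirmed, not counter-active, and
#' its main-assay IC50 is at or below the potency gate (inclusive, default
#' 10 uM).
#'
#' @param verdicts Assembled verdict table (see [triage_screen()]) holding
#'   confirmed, counter_active and main_ic50 columns.
#' @param rules [triage_rules()].
#' @return `verdicts` with final_hit set and reasons extended.
#' @export
finalize <- function(verdicts, rules = triage_rules()) {
  eligible <- verdicts$confirmed & !verdicts$counter_active
  pot_ok <- !is.na(verdicts$main_ic50) &
    verdicts$main_ic50 <= rules$potency_gate
  verdicts$final_hit <- eligible & pot_ok
  add <- eligible & !pot_ok
  verdicts$reasons[add] <- paste0(
    verdicts$reasons[add], ifelse(nzchar(verdicts$reasons[add]), ";", ""),
    "potency_gate")
  verdicts
}

#' Run the full hit-triage cascade
#'
#' Applies, in order: primary selection (top-dose response and CRC),
#' promiscuity removal, 7-dose confirmation, counter-screen elimination
#' with differential rescue, and the final potency gate. Each filter's
#' output set is a subset of its input set except the differential rescue,
#' which only re-admits compounds the counter filter removed.
#'
#' @param primary Per-compound [fit_screen()] results of the 4-dose screen.
#' @param confirmation Results of the 7-dose refit (selected compounds).
#' @param counter Results of the 7-dose counter screen (selected
#'   compounds).
#' @param compounds Optional annotation table with promiscuity flags.
#' @param rules [triage_rules()].
#' @return Verdict data frame, one row per screened compound:
#'   compound_id, primary_selected, promiscuous_removed, confirmed,
#'   counter_active, differential_rescued, final_hit, main_ic50, reasons.
#' @export
triage_screen <- function(primary, confirmation = NULL, counter = NULL,
                          compounds = NULL, rules = triage_rules()) {
  v <- select_primary(primary, compounds, rules)
  v$confirmed <- FALSE
  v$counter_active <- FALSE
  v$differential_rescued <- FALSE
  v$main_ic50 <- NA_real_
  advanced <- v$primary_selected & !v$promiscuous_removed
  v$reasons[!advanced & !nzchar(v$reasons)] <- "primary:not_selected"

  if (!is.null(confirmation) && any(advanced)) {
    cf <- confirm(confirmation, rules)
    i <- match(v$compound_id, cf$compound_id)
    v$confirmed <- advanced & !is.na(i) & cf$confirmed[i] %in% TRUE
    unconf <- advanced & !v$confirmed
    v$reasons[unconf] <- "unconfirmed"
    v$main_ic50 <- confirmation$ic50[
      match(v$compound_id, confirmation$compound_id)]
  }
  if (!is.null(counter) && any(v$confirmed)) {
    conf_ids <- v$compound_id[v$confirmed]
    main_sub <- confirmation[confirmation$compound_id %in% conf_ids, ,
                             drop = FALSE]
    cs <- counter_screen_filter(
      main_sub, counter[counter$compound_id %in% conf_ids, , drop = FALSE],
      rules)
    i <- match(v$compound_id, cs$compound_id)
    hit <- !is.na(i)
    v$counter_active[hit] <- cs$counter_active[i[hit]]
    v$differential_rescued[hit] <- cs$differential_rescued[i[hit]]
    ca <- v$counter_active
    v$reasons[ca] <- paste0(v$reasons[ca],
                            ifelse(nzchar(v$reasons[ca]), ";", ""),
                            "counter_active")
  }
  v <- finalize(v, rules)
  v
}

#' Arithmetic identities of the triage flowchart
#'
#' Derives the stage rates and downstream counts from the four primary
#' stage counts: compounds entering confirmation (`selected`), compounds
#' confirmed in the dose-response refit, counter-screen false positives,
#' and differential rescues. Bona fide inhibitors are confirmed minus
#' counter false positives, and the advanced set is bona fide plus
#' differential.
#'
#' @param selected Number selected for re-testing.
#' @param confirmed Number confirmed in the refit.
#' @param counter_fp Number of counter-screen false positives.
#' @param differential Number of differential rescues.
#' @return Named list: selected, confirmed, confirmation_rate_pct,
#'   counter_fp, counter_fp_rate_pct, bona_fide, differential, advanced.
#' @examples
#' triage_counts(1990, 1782, 1718, 156)$advanced # 220
#' @export
triage_counts <- function(selected, confirmed, counter_fp, differential) {
  for (v in c(selected, confirmed, counter_fp, differential)) {
    assert_number(v, "count", 0)
  }
  if (confirmed > selected) stop_bad("confirmed exceeds selected")
  if (counter_fp > confirmed) stop_bad("counter_fp exceeds confirmed")
  bona <- confirmed - counter_fp
  list(selected = selected, confirmed = confirmed,
       confirmation_rate_pct = 100 * confirmed / selected,
       counter_fp = counter_fp,
       counter_fp_rate_pct = 100 * counter_fp / selected,
       bona_fide = bona, differential = differential,
       advanced = bona + differential)
}

#' Stage-count summary of a triage run (flowchart reproduction)
#'
#' Counts compounds at every stage of the cascade and checks the
#' conservation identities (selected = confirmed + unconfirmed; advanced =
#' bona fide + differential).
#'
#' @param verdicts Verdict table from [triage_screen()].
#' @return Named list of stage counts plus the derived rates from
#'   [triage_counts()].
#' @export
triage_report <- function(verdicts) {
  n <- nrow(verdicts)
  if (n == 0) {
    z <- triage_counts(0, 0, 0, 0)
    z$confirmation_rate_pct <- z$counter_fp_rate_pct <- NaN
    return(c(list(screened = 0, primary_selected = 0,
                  promiscuous_removed = 0, final_hits = 0), z))
  }
  sel <- sum(verdicts$primary_selected & !verdicts$promiscuous_removed)
  conf <- sum(verdicts$confirmed)
  diff_n <- sum(verdicts$differential_rescued)
  # counter false positives in the flowchart sense include the compounds
  # later rescued by the differential rule
  ca <- sum(verdicts$counter_active) + diff_n
  counts <- if (sel > 0) triage_counts(sel, conf, ca, diff_n) else
    list(selected = 0, confirmed = 0, confirmation_rate_pct = NaN,
         counter_fp = 0, counter_fp_rate_pct = NaN, bona_fide = 0,
         differential = 0, advanced = 0)
  c(list(screened = n,
         primary_selected = sum(verdicts$primary_selected),
         promiscuous_removed = sum(verdicts$promiscuous_removed),
         final_hits = sum(verdicts$final_hit)),
    counts)
}
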