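#' Validate a compound ground-truth table
#'
#' A ground-truth table has one row per library compound with its identity,
#' planted class, and the parameters the generators use:
#' \describe{
#'   \item{compound_id}{character, unique}
#'   \item{class_label}{one of "inactive", "true_inhibitor",
#'     "counter_false_positive", "promiscuous"}
#'   \item{true_ic50}{uM; NA for inactive compounds}
#'   \item{true_efficacy}{maximal percent inhibition, 0-100}
#'   \item{counter_ic50}{uM; potency against the detection cascade
#'     (required for counter false positives)}
#'   \item{promiscuity_flag}{logical}
#' }
#'
#' @param x Data frame to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_ground_truth <- function(x) {
  need <- c("compound_id", "class_label", "true_ic50", "true_efficacy",
            "counter_ic50", "promiscuity_flag")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("ground truth lacks columns: %s",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(x$compound_id)) stop_bad("duplicate compound ids")
  ok_class <- c("inactive", "true_inhibitor", "counter_false_positive",
                "promiscuous")
  if (!all(x$class_label %in% ok_class)) stop_bad("unknown class_label")
  act <- x$class_label != "inactive"
  if (any(act & (is.na(x$true_ic50) | x$true_ic50 <= 0) &
          x$class_label != "counter_false_positive")) {
    stop_bad("active compounds need true_ic50 > 0")
  }
  if (any(x$true_efficacy < 0 | x$true_efficacy > 100, na.rm = TRUE)) {
    stop_bad("true_efficacy must be within [0, 100]")
  }
  cfp <- x$class_label == "counter_false_positive"
  if (any(cfp & (is.na(x$counter_ic50) | x$counter_ic50 <= 0))) {
    stop_bad("counter_false_positive compounds need counter_ic50 > 0")
  }
  invisible(x)
}

#' Generate a synthetic compound library with known ground truth
#'
#' Plants four compound classes: inactives, true inhibitors of the target
#' enzyme, counter-screen false positives (compounds that inhibit the
#' coupled detection cascade, not the enzyme, and therefore look active in
#' the primary assay), and promiscuous compounds (flagged nonspecific
#' actives removed by the structural filter upstream of confirmation --
#' modelled here as a boolean flag).
#'
#' True inhibitor potencies are drawn log-uniformly within `ic50_range`
#' (default 0.03-10 uM, the potency window the triage cascade is designed to
#' retain) and counter false-positive potencies log-uniformly within
#' `counter_ic50_range` (default 0.1-50 uM).
#'
#' @param n Library size.
#' @param prop_true,prop_counter_fp,prop_promiscuous Planted class
#'   proportions (the remainder is inactive).
#' @param ic50_range True-inhibitor IC50 range, uM (log-uniform).
#' @param efficacy_range Maximal percent inhibition range (uniform).
#' @param counter_ic50_range Counter false-positive IC50 range, uM.
#' @param seed Integer seed; the table is a pure function of the arguments.
#' @return Ground-truth data frame (see [validate_ground_truth()]).
#' @export
compound_library <- function(n, prop_true = 0.02, prop_counter_fp = 0.05,
                             prop_promiscuous = 0.02,
                             ic50_range = c(0.03, 10),
                             efficacy_range = c(75, 100),
                             counter_ic50_range = c(0.1, 50),
                             seed = 1) {
  if (n < 1) stop_bad("library size must be >= 1")
  if (prop_true + prop_counter_fp + prop_promiscuous > 1) {
    stop_bad("class proportions exceed 1")
  }
  with_seed(derive_seed(seed, 11L), {
    n_true <- round(n * prop_true)
    n_cfp <- round(n * prop_counter_fp)
    n_prom <- round(n * prop_promiscuous)
    labels <- rep("inactive", n)
    idx <- sample.int(n, n_true + n_cfp + n_prom)
    labels[idx[seq_len(n_true)]] <- "true_inhibitor"
    if (n_cfp) labels[idx[n_true + seq_len(n_cfp)]] <- "counter_false_positive"
    if (n_prom) labels[idx[n_true + n_cfp + seq_len(n_prom)]] <- "promiscuous"
    rlunif <- function(k, rng) {
      10^stats::runif(k, log10(rng[1]), log10(rng[2]))
    }
    x <- data.frame(
      compound_id = sprintf("CPD%05d", seq_len(n)),
      class_label = labels,
      true_ic50 = NA_real_,
      true_efficacy = NA_real_,
      counter_ic50 = NA_real_,
      promiscuity_flag = labels == "promiscuous",
      stringsAsFactors = FALSE
    )
    act <- labels %in% c("true_inhibitor", "promiscuous")
    x$true_ic50[act] <- rlunif(sum(act), ic50_range)
    x$true_efficacy[act] <- stats::runif(sum(act), efficacy_range[1],
                                         efficacy_range[2])
    cfp <- labels == "counter_false_positive"
    x$counter_ic50[cfp] <- rlunif(sum(cfp), counter_ic50_range)
    x$true_efficacy[cfp] <- stats::runif(sum(cfp), 90, 100)
    x$true_efficacy[labels == "inactive"] <- 0
    validate_ground_truth(x)
    x
  })
}
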