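#' Delta-delta-Ct fold changes
#'
#' Per sample, dCt = Ct(target) - Ct(reference); per gene and group,
#' ddCt = dCt - mean(dCt of the control group); fold change = 2^(-ddCt).
#' Group fold changes are summarised on the Ct scale (mean ddCt, then
#' exponentiated), which is unbiased for the planted fold under symmetric
#' cycle noise. The result is invariant to adding a constant to both the
#' target and reference Ct of every sample (plate offsets cancel).
#'
#' @param records Data frame: sample_id, group, gene, ct_target,
#'   ct_reference (see [simulate_qpcr()]).
#' @param control_group Name of the control group.
#' @return Data frame: gene, group, n, mean_ddct, sd_ddct, fold, fold_lo,
#'   fold_hi (fold at mean ddCt -+ sd).
#' @export
ddct_fold_change <- function(records, control_group = "control") {
  need <- c("group", "gene", "ct_target", "ct_reference")
  if (!all(need %in% names(records))) {
    stop_bad("records need columns: %s", paste(need, collapse = ", "))
  }
  if (!control_group %in% records$group) {
    stop_bad("control group '%s' absent from records", control_group)
  }
  if (any(records$ct_target < 0 | records$ct_target > 45) ||
      any(records$ct_reference < 0 | records$ct_reference > 45)) {
    stop_bad("Ct values outside the plausible 0-45 cycle range")
  }
  records$dct <- records$ct_target - records$ct_reference
  out <- lapply(split(records, records$gene), function(g) {
    ctrl_mean <- mean(g$dct[g$group == control_group])
    g$ddct <- g$dct - ctrl_mean
    agg <- lapply(split(g, g$group), function(x) {
      data.frame(gene = x$gene[1], group = x$group[1], n = nrow(x),
                 mean_ddct = mean(x$ddct), sd_ddct = stats::sd(x$ddct),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  res <- do.call(rbind, out)
  res$fold <- 2^(-res$mean_ddct)
  res$fold_lo <- 2^(-(res$mean_ddct + res$sd_ddct))
  res$fold_hi <- 2^(-(res$mean_ddct - res$sd_ddct))
  rownames(res) <- NULL
  res
}

#' Percent reduction of a treated group relative to a reference group
#'
#' `100 * (1 - mean(treated)/mean(reference))` with uncertainty by
#' first-order (delta-method) error propagation of the group spreads, or by
#' nonparametric bootstrap. `scale = "sd"` propagates group standard
#' deviations (the spread an individual-animal ratio would show, matching
#' "mean +- SD" reporting); `scale = "sem"` propagates standard errors of
#' the group means (the uncertainty of the reduction estimate itself).
#'
#' @param treated,reference Numeric replicate vectors (n >= 2 each,
#'   values >= 0).
#' @param scale "sd" (default) or "sem".
#' @param method "delta" (default) or "bootstrap".
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return List: estimate (percent), uncertainty (percent), scale, method.
#' @export
percent_reduction <- function(treated, reference, scale = c("sd", "sem"),
                              method = c("delta", "bootstrap"),
                              n_boot = 2000, seed = 1) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (length(treated) < 2 || length(reference) < 2) {
    stop_bad("need >= 2 replicates per group")
  }
  if (any(treated < 0) || any(reference < 0)) {
    stop_bad("counts must be >= 0")
  }
  mt <- mean(treated); mr <- mean(reference)
  if (mr <= 0) stop_bad("reference mean must be > 0")
  est <- 100 * (1 - mt / mr)
  if (method == "delta") {
    st <- stats::sd(treated); sr <- stats::sd(reference)
    if (scale == "sem") {
      st <- st / sqrt(length(treated)); sr <- sr / sqrt(length(reference))
    }
    unc <- 100 * sqrt((st / mr)^2 + (mt * sr / mr^2)^2)
  } else {
    boots <- with_seed(derive_seed(seed, 61L), {
      vapply(seq_len(n_boot), function(b) {
        100 * (1 - mean(sample(treated, replace = TRUE)) /
                 mean(sample(reference, replace = TRUE)))
      }, numeric(1))
    })
    unc <- stats::sd(boots)
  }
  list(estimate = est, uncertainty = unc, scale = scale, method = method)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical one-way decomposition (via [stats::aov()]) followed by Tukey's
#' honestly-significant-difference comparisons using studentized-range
#' quantiles ([stats::TukeyHSD()]).
#'
#' @param values Numeric response vector.
#' @param group Group labels (>= 2 groups, >= 2 values each).
#' @param conf_level Confidence level of the Tukey intervals.
#' @return List: f_statistic, df_between, df_within, p_value, tukey (data
#'   frame: comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, group, conf_level = 0.95) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop_bad("need >= 2 groups")
  if (any(table(group) < 2)) stop_bad("need >= 2 values per group")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(f_statistic = s[["F value"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2],
       p_value = s[["Pr(>F)"]][1], tukey = tukey)
}

#' Emax dose-response fit of EV counts
#'
#' Converts group mean particle counts to percent inhibition relative to
#' the vehicle (dose 0) mean and fits the shared four-parameter logistic
#' machinery ([fit_4pl()]); the fitted midpoint is the cellular EC50 and
#' the fitted top the Emax.
#'
#' @param counts Data frame with columns dose_um and a value column
#'   (default `ev_per_ml`) of replicate counts, vehicle included as dose 0.
#' @param value_col Name of the value column.
#' @return A `dr_fit` (see [fit_4pl()]) on percent reduction vs dose, with
#'   `ec50` and `emax` aliases attached.
#' @export
ev_dose_response <- function(counts, value_col = "ev_per_ml") {
  if (!all(c("dose_um", value_col) %in% names(counts))) {
    stop_bad("counts need columns dose_um and %s", value_col)
  }
  doses <- sort(unique(counts$dose_um))
  if (!0 %in% doses) stop_bad("vehicle (dose 0) group required")
  test_doses <- setdiff(doses, 0)
  if (length(test_doses) < 2) {
    stop_bad("need >= 2 nonzero doses for a dose-response fit")
  }
  v0 <- mean(counts[[value_col]][counts$dose_um == 0])
  if (v0 <= 0) stop_bad("vehicle mean must be > 0")
  means <- vapply(test_doses, function(d) {
    mean(counts[[value_col]][counts$dose_um == d])
  }, numeric(1))
  pct <- 100 * (1 - means / v0)
  fit <- fit_4pl(test_doses, pct)
  fit$ec50 <- fit$ic50
  fit$emax <- fit$top
  fit
}
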