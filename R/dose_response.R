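#' Percent inhibition from paired rates
#'
#' 100 x (1 - rate_with_inhibitor / rate_without), i.e. the complement of
#' the activity ratio, so that inhibition increases with effect. Values are
#' clipped to \[-10, 110\] for reporting (mild activation and overshoot are
#' retained, gross outliers are not).
#'
#' @param rate_inhibited Rate (RFU/h or uM/h) in the presence of inhibitor.
#' @param rate_control Rate in the absence of inhibitor (> 0).
#' @param clip Clip to \[-10, 110\]? Default TRUE.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(rate_inhibited, rate_control, clip = TRUE) {
  if (any(!is.finite(rate_control)) || any(rate_control <= 0)) {
    stop_bad("control rate must be positive and finite")
  }
  p <- 100 * (1 - rate_inhibited / rate_control)
  if (clip) p <- pmin(pmax(p, -10), 110)
  p
}

#' Per-well percent inhibition from plate data
#'
#' Normalises compound-well fluorescence to the per-plate controls: the
#' saturating positive-control column defines 0% inhibition and the
#' no-enzyme column 100%.
#'
#' @param wells Well table ([simulate_plate()] schema).
#' @param clip Clip reported inhibition to \[-10, 110\]?
#' @return Data frame: plate_id, compound_id, conc_um, pct_inhibition.
#' @export
plate_inhibition <- function(wells, clip = TRUE) {
  out <- lapply(split(wells, wells$plate_id), function(p) {
    pos <- mean(p$rfu[p$role == "pos_control"])
    neg <- mean(p$rfu[p$role == "neg_control"])
    if (!is.finite(pos - neg) || pos <= neg) {
      stop_bad("plate %s: positive-control mean not above background",
               p$plate_id[1])
    }
    cw <- p[p$role == "compound" & !is.na(p$compound_id), , drop = FALSE]
    pct <- 100 * (1 - (cw$rfu - neg) / (pos - neg))
    if (clip) pct <- pmin(pmax(pct, -10), 110)
    data.frame(plate_id = cw$plate_id, compound_id = cw$compound_id,
               conc_um = cw$conc_um, pct_inhibition = pct,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent inhibition of the column-1 control dose series
#'
#' @inheritParams plate_inhibition
#' @return Data frame: plate_id, conc_um, pct_inhibition (one row per
#'   control-series well).
#' @export
control_series_inhibition <- function(wells, clip = TRUE) {
  out <- lapply(split(wells, wells$plate_id), function(p) {
    pos <- mean(p$rfu[p$role == "pos_control"])
    neg <- mean(p$rfu[p$role == "neg_control"])
    sw <- p[p$role == "pos_series", , drop = FALSE]
    pct <- 100 * (1 - (sw$rfu - neg) / (pos - neg))
    if (clip) pct <- pmin(pmax(pct, -10), 110)
    data.frame(plate_id = sw$plate_id, conc_um = sw$conc_um,
               pct_inhibition = pct, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Curve-response-class thresholds
#'
#' All tunables of the CRC scheme in one place. `high_efficacy` separates
#' subclass .1 from .2; curves with fitted efficacy below `partial_floor`
#' are inactive (class 4); `r2_min` is the fit-quality gate below which a
#' curve can only be class 3 (single-dose activity) or 4; an asymptote
#' counts as present when the fitted curve comes within `asym_frac` of the
#' corresponding plateau inside the tested dose range; IC50s more than
#' `extrapolation_logs` outside the tested range demote subclass .1 to .2.
#'
#' @param high_efficacy Percent; subclass .1 requires efficacy >= this.
#' @param partial_floor Percent; minimal efficacy for an active class.
#' @param r2_min Minimal r-squared for classes 1 and 2.
#' @param asym_frac Fraction of the fitted span for plateau detection.
#' @param extrapolation_logs Log10 units the IC50 may sit outside the
#'   tested range before the curve is flagged extrapolated.
#' @param single_dose_activity Percent response qualifying a poorly fit
#'   curve as class 3 rather than 4.
#' @return Named list of thresholds.
#' @export
crc_thresholds <- function(high_efficacy = 80, partial_floor = 30,
                           r2_min = 0.9, asym_frac = 0.05,
                           extrapolation_logs = 1,
                           single_dose_activity = 50) {
  list(high_efficacy = high_efficacy, partial_floor = partial_floor,
       r2_min = r2_min, asym_frac = asym_frac,
       extrapolation_logs = extrapolation_logs,
       single_dose_activity = single_dose_activity)
}

pred_4pl <- function(d, bottom, top, lic50, h) {
  bottom + (top - bottom) / (1 + 10^(h * (lic50 - log10(d))))
}

#' Fit a four-parameter logistic (Hill) dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ic50) - log10(d))))`
#' on log10 dose, with soft box bounds (Levenberg-Marquardt). Responses are
#' percent inhibition, so `top` is the upper plateau and `hill > 0` for an
#' inhibitor. Designs with four or fewer distinct doses are fitted with
#' `bottom` fixed at 0 and the Hill slope restricted to \[0.5, 3\] to avoid
#' overfitting; richer designs are unconstrained (hill in \[0.2, 5\]).
#'
#' @param doses Doses, uM (> 0).
#' @param response Percent inhibition at each dose.
#' @param weights Optional fit weights.
#' @param constrain Force the constrained (4-dose) parameterisation;
#'   default NULL decides from the number of distinct doses.
#' @param thresholds [crc_thresholds()], used for asymptote counting and
#'   the extrapolation flag.
#' @return A `dr_fit` object: fitted bottom/top/ic50/hill, r2, efficacy
#'   (top - bottom), n_asymptotes, extrapolated and converged flags, plus
#'   the data and fitted values.
#' @examples
#' d <- 10^seq(-3, 2, length.out = 11)
#' y <- 100 / (1 + (1 / d))
#' fit_4pl(d, y)$ic50 # 1 uM
#' @export
fit_4pl <- function(doses, response, weights = NULL, constrain = NULL,
                    thresholds = crc_thresholds()) {
  if (length(doses) != length(response)) {
    stop_bad("`doses` and `response` lengths differ")
  }
  if (any(doses <= 0)) stop_bad("doses must be positive")
  nd <- length(unique(doses))
  if (nd < 2) stop_bad("need at least 2 distinct doses")
  constrain <- constrain %||% (nd <= 4)
  w <- weights %||% rep(1, length(response))
  ld <- log10(doses)
  rng <- range(ld)

  fit <- list(doses = doses, response = response, weights = w,
              constrained = constrain, thresholds = thresholds,
              bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
              hill = NA_real_, r2 = NA_real_, efficacy = NA_real_,
              n_asymptotes = 0L, extrapolated = FALSE, converged = FALSE,
              fitted = rep(NA_real_, length(response)),
              max_response = max(response))
  class(fit) <- "dr_fit"

  span <- diff(range(response))
  if (span < 1e-9) {
    # flat data: no curve to fit
    fit$bottom <- fit$top <- mean(response)
    fit$efficacy <- 0
    fit$fitted <- rep(mean(response), length(response))
    fit$r2 <- 0
    return(fit)
  }

  # starting values: plateaus from data, midpoint by interpolation
  top0 <- max(response)
  bot0 <- if (constrain) 0 else min(response)
  half <- (top0 + bot0) / 2
  ord <- order(ld)
  above <- which(response[ord] >= half)
  lic0 <- if (length(above)) ld[ord][above[1]] else mean(rng)
  hill_lim <- if (constrain) c(0.5, 3) else c(0.2, 5)
  starts <- expand.grid(lic = unique(c(lic0, mean(rng), rng[1], rng[2])),
                        h = c(1, 2))
  # Levenberg-Marquardt on the raw residual function (nls.lm): robust to
  # machine-perfect fits on noise-free data, where building a full nls
  # object can fail on a rank test of the gradient at the solution.
  sw <- sqrt(w)
  resid_fn <- if (constrain) {
    function(p) sw * (response - pred_4pl(doses, 0, p[1], p[2], p[3]))
  } else {
    function(p) sw * (response - pred_4pl(doses, p[1], p[2], p[3], p[4]))
  }
  lower <- if (constrain) c(-10, rng[1] - 3, hill_lim[1]) else
    c(-30, -10, rng[1] - 3, hill_lim[1])
  upper <- if (constrain) c(120, rng[2] + 3, hill_lim[2]) else
    c(30, 120, rng[2] + 3, hill_lim[2])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- if (constrain) c(top0, starts$lic[i], starts$h[i]) else
      c(bot0, top0, starts$lic[i], starts$h[i])
    res <- try(minpack.lm::nls.lm(
      par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(res, "try-error") && res$info %in% 1:4) {
      rss <- res$deviance
      if (is.null(best) || rss < best$rss) {
        best <- list(par = res$par, rss = rss)
      }
    }
  }
  if (is.null(best)) return(fit)

  cf <- best$par
  if (constrain) cf <- c(0, cf)
  fit$bottom <- cf[1]
  fit$top <- cf[2]
  fit$ic50 <- 10^cf[3]
  fit$hill <- cf[4]
  fit$fitted <- pred_4pl(doses, fit$bottom, fit$top, log10(fit$ic50),
                         fit$hill)
  tss <- sum(w * (response - stats::weighted.mean(response, w))^2)
  fit$r2 <- if (tss > 0) max(0, min(1, 1 - best$rss / tss)) else 0
  fit$efficacy <- fit$top - fit$bottom
  fit$converged <- TRUE
  fit$n_asymptotes <- count_asymptotes(fit, thresholds$asym_frac)
  fit$extrapolated <-
    log10(fit$ic50) < rng[1] - thresholds$extrapolation_logs ||
    log10(fit$ic50) > rng[2] + thresholds$extrapolation_logs
  fit
}

# Plateau detection: an asymptote is present when the fitted curve comes
# within `frac` of it at the corresponding end of the tested range.
count_asymptotes <- function(fit, frac = 0.05) {
  eff <- abs(fit$top - fit$bottom)
  if (!is.finite(eff) || eff == 0) return(0L)
  dmin <- min(fit$doses); dmax <- max(fit$doses)
  lo <- pred_4pl(dmin, fit$bottom, fit$top, log10(fit$ic50), fit$hill)
  hi <- pred_4pl(dmax, fit$bottom, fit$top, log10(fit$ic50), fit$hill)
  sum(abs(lo - fit$bottom) <= frac * eff, abs(fit$top - hi) <= frac * eff)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit>")
  if (!x$converged) cat(" (not converged)")
  cat(sprintf("\n  IC50 %.4g uM, hill %.3g, efficacy %.1f%%, r2 %.3f\n",
              x$ic50, x$hill, x$efficacy, x$r2))
  cat(sprintf("  asymptotes: %d, extrapolated: %s\n", x$n_asymptotes,
              x$extrapolated))
  invisible(x)
}

#' Assign a curve-response class (CRC)
#'
#' Discrete summary of a dose-response curve's completeness, efficacy and
#' fit quality. Class 1: complete curve (both plateaus inside the tested
#' range); class 2: well-fit but incomplete curve (fewer than two
#' plateaus); class 3: activity without an interpretable curve (poor fit or
#' non-convergence with at least one response above the single-dose
#' activity threshold); class 4: inactive. Subclass .1 denotes high
#' efficacy, .2 partial efficacy; the sign is negative for inhibition.
#' Curves whose IC50 extrapolates beyond the tested range (plus the allowed
#' margin) are demoted from .1 to .2.
#'
#' @param fit A `dr_fit` from [fit_4pl()].
#' @param thresholds [crc_thresholds()].
#' @return One of -1.1, -1.2, -2.1, -2.2, -3, 4.
#' @export
crc_classify <- function(fit, thresholds = crc_thresholds()) {
  t <- thresholds
  single <- max(fit$response) >= t$single_dose_activity
  if (!fit$converged || !is.finite(fit$ic50)) {
    return(if (single) -3 else 4)
  }
  eff <- fit$top - fit$bottom
  if (eff < t$partial_floor) return(4)
  if (fit$r2 < t$r2_min) return(if (single) -3 else 4)
  # a curve needs at least two doses with appreciable response; a lone
  # top-dose spike is single-dose activity (class 3), not a curve
  if (sum(fit$response >= t$partial_floor) < 2) {
    return(if (single) -3 else 4)
  }
  n_asym <- count_asymptotes(fit, t$asym_frac)
  cls <- if (n_asym == 2L) 1 else 2
  sub <- if (eff >= t$high_efficacy && !fit$extrapolated) 0.1 else 0.2
  -(cls + sub)
}

#' IC50 with a residual-bootstrap confidence interval
#'
#' Resamples residuals around the fitted curve, refits, and reports the
#' percentile interval of the bootstrapped IC50s. With `n_boot = 0` only
#' the point estimate is returned; noise-free data yield a zero-width
#' interval.
#'
#' @param fit A converged `dr_fit`.
#' @param n_boot Number of bootstrap refits.
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @return List: ic50, lower, upper, level, n_boot.
#' @export
ic50_with_ci <- function(fit, n_boot = 500, seed = 1, level = 0.95) {
  if (!fit$converged) stop_bad("cannot bootstrap a non-converged fit")
  if (n_boot == 0) {
    return(list(ic50 = fit$ic50, lower = NA_real_, upper = NA_real_,
                level = level, n_boot = 0L))
  }
  resid <- fit$response - fit$fitted
  boots <- with_seed(derive_seed(seed, 23L), {
    vapply(seq_len(n_boot), function(b) {
      yb <- fit$fitted + sample(resid, length(resid), replace = TRUE)
      fb <- fit_4pl(fit$doses, yb, weights = fit$weights,
                    constrain = fit$constrained,
                    thresholds = fit$thresholds)
      if (fb$converged) fb$ic50 else NA_real_
    }, numeric(1))
  })
  q <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  list(ic50 = fit$ic50, lower = q[1], upper = q[2], level = level,
       n_boot = as.integer(n_boot))
}

#' Fit and classify every compound in an inhibition table
#'
#' @param inhibition Data frame from [plate_inhibition()] (compound_id,
#'   conc_um, pct_inhibition; rows across plates/doses).
#' @param assay_id Label recorded in the output.
#' @param thresholds [crc_thresholds()].
#' @return Data frame with one row per compound: compound_id, assay_id,
#'   n_doses, max_response, bottom, top, ic50, hill, r2, efficacy,
#'   n_asymptotes, converged, extrapolated, crc_class.
#' @export
fit_screen <- function(inhibition, assay_id = "main",
                       thresholds = crc_thresholds()) {
  out <- lapply(split(inhibition, inhibition$compound_id), function(x) {
    f <- fit_4pl(x$conc_um, x$pct_inhibition, thresholds = thresholds)
    data.frame(
      compound_id = x$compound_id[1], assay_id = assay_id,
      n_doses = length(unique(x$conc_um)), max_response = f$max_response,
      bottom = f$bottom, top = f$top, ic50 = f$ic50, hill = f$hill,
      r2 = f$r2, efficacy = f$efficacy, n_asymptotes = f$n_asymptotes,
      converged = f$converged, extrapolated = f$extrapolated,
      crc_class = crc_classify(f, thresholds),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
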