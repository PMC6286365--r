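#' Fit Michaelis-Menten kinetics
#'
#' Least squares on v = Vmax * S / (Km + S). Warns when fewer than four
#' substrate levels are supplied or the levels do not span the fitted Km;
#' duplicate substrate levels are used as replicates.
#'
#' @param substrate Substrate concentrations, uM.
#' @param rate Rates (uM/h or RFU/h; units carried through to Vmax).
#' @return List: Vmax, Km, se_Vmax, se_Km, ill_determined (Km SE exceeds
#'   the estimate), fitted, converged.
#' @export
fit_mm <- function(substrate, rate) {
  if (length(substrate) != length(rate)) stop_bad("length mismatch")
  if (any(substrate <= 0)) stop_bad("substrate must be positive")
  if (length(unique(substrate)) < 4) {
    warning("fewer than 4 substrate levels; Km may be poorly determined",
            call. = FALSE)
  }
  vmax0 <- max(rate) * 1.2
  km0 <- stats::median(substrate)
  mm_try <- function(v0, k0) {
    try(minpack.lm::nlsLM(rate ~ Vmax * substrate / (Km + substrate),
                          start = list(Vmax = v0, Km = k0),
                          lower = c(Vmax = 1e-12, Km = 1e-12),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200)),
        silent = TRUE)
  }
  f <- mm_try(vmax0, km0)
  # a machine-perfect fit can fail the gradient rank test when the nls
  # object is built; a minute start perturbation resolves it
  if (inherits(f, "try-error")) f <- mm_try(vmax0 * 1.013, km0 * 0.991)
  if (inherits(f, "try-error")) {
    return(list(Vmax = NA_real_, Km = NA_real_, se_Vmax = NA_real_,
                se_Km = NA_real_, ill_determined = TRUE,
                fitted = rep(NA_real_, length(rate)), converged = FALSE))
  }
  cf <- stats::coef(f)
  se <- tryCatch(sqrt(diag(stats::vcov(f))),
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  km <- unname(cf["Km"]); se_km <- unname(se["Km"])
  ill <- is.na(se_km) || se_km > abs(km)
  if (km > max(substrate)) {
    warning("substrate levels do not span the fitted Km", call. = FALSE)
  }
  list(Vmax = unname(cf["Vmax"]), Km = km,
       se_Vmax = unname(se["Vmax"]), se_Km = se_km,
       ill_determined = ill, fitted = stats::fitted(f), converged = TRUE)
}

aicc <- function(rss, n, k, scale = 1) {
  # floor the RSS relative to the data scale: below numerical precision all
  # models fit "exactly" and the parameter-count penalty must decide
  rss <- max(rss, scale * 1e-12, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

inhibition_models <- function() {
  list(
    competitive = function(S, I, Vmax, Km, Ki, alpha = NA) {
      Vmax * S / (Km * (1 + I / Ki) + S)
    },
    noncompetitive = function(S, I, Vmax, Km, Ki, alpha = NA) {
      Vmax * S / ((Km + S) * (1 + I / Ki))
    },
    uncompetitive = function(S, I, Vmax, Km, Ki, alpha = NA) {
      Vmax * S / (Km + S * (1 + I / Ki))
    },
    mixed = function(S, I, Vmax, Km, Ki, alpha) {
      Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki)))
    }
  )
}

#' Global inhibition-mode fit and model selection
#'
#' Fits the classical competitive, noncompetitive, uncompetitive and mixed
#' rate laws globally across all inhibitor levels and selects the mode by
#' small-sample-corrected AIC (AICc). When the best and runner-up modes are
#' within `delta_ambiguous` AICc units the call is flagged ambiguous.
#' Independent per-level Michaelis-Menten fits are reported alongside so
#' the apparent Vmax(I)/Km(I) trends (the diagnostic signature: a
#' noncompetitive inhibitor lowers Vmax and leaves Km unchanged) can be
#' inspected.
#'
#' @param data Data frame with columns substrate, inhibitor, rate (a
#'   complete substrate x inhibitor grid; replicates allowed).
#' @param delta_ambiguous AICc separation below which the top modes are
#'   reported as ambiguous.
#' @return A `kinetic_fit` list: mode, ambiguous, Ki, Vmax, Km, alpha (for
#'   mixed), mode_scores (named AICc vector), per_level (data frame of
#'   per-inhibitor-level Vmax/Km fits), fits.
#' @export
fit_inhibition_global <- function(data, delta_ambiguous = 2) {
  need <- c("substrate", "inhibitor", "rate")
  if (!all(need %in% names(data))) {
    stop_bad("data needs columns: %s", paste(need, collapse = ", "))
  }
  levels_i <- sort(unique(data$inhibitor))
  if (length(levels_i) < 2) {
    stop_bad("need >= 2 inhibitor levels to diagnose the inhibition mode")
  }
  # per-level Michaelis-Menten fits
  per_level <- do.call(rbind, lapply(levels_i, function(I) {
    d <- data[data$inhibitor == I, , drop = FALSE]
    f <- suppressWarnings(fit_mm(d$substrate, d$rate))
    data.frame(inhibitor = I, Vmax = f$Vmax, Km = f$Km,
               se_Vmax = f$se_Vmax, se_Km = f$se_Km)
  }))
  S <- data$substrate; I <- data$inhibitor; v <- data$rate
  n <- length(v)
  vmax0 <- max(v) * 1.1
  km0 <- stats::median(S)
  ki0 <- stats::median(I[I > 0])
  mods <- inhibition_models()
  fits <- list(); scores <- c()
  for (m in names(mods)) {
    fn <- mods[[m]]
    k <- if (m == "mixed") 4 else 3
    # raw Levenberg-Marquardt (nls.lm): only parameters and deviance are
    # needed, and it is robust to exact fits on noise-free grids
    p0 <- c(Vmax = vmax0, Km = km0, Ki = ki0)
    lo <- rep(1e-12, 3); up <- rep(Inf, 3)
    if (m == "mixed") {
      p0 <- c(p0, alpha = 1)
      lo <- c(lo, 1e-3); up <- c(up, 1e3)
    }
    resid_fn <- function(p) {
      v - fn(S, I, p[1], p[2], p[3], if (k == 4) p[4] else NA)
    }
    f <- try(suppressWarnings(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = up, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300))), silent = TRUE)
    if (!inherits(f, "try-error") && f$info %in% 1:4) {
      fits[[m]] <- f
      scores[m] <- aicc(f$deviance, n, k, scale = sum(v^2))
    }
  }
  if (!length(scores)) stop_bad("no inhibition model converged")
  ord <- order(scores)
  best <- names(scores)[ord[1]]
  ambiguous <- length(scores) > 1 &&
    (scores[ord[2]] - scores[ord[1]]) < delta_ambiguous
  cf <- fits[[best]]$par
  structure(list(
    mode = best, ambiguous = ambiguous,
    Ki = unname(cf["Ki"]), Vmax = unname(cf["Vmax"]),
    Km = unname(cf["Km"]),
    alpha = if (best == "mixed") unname(cf["alpha"]) else NA_real_,
    mode_scores = scores, per_level = per_level, fits = fits
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> mode: %s%s\n", x$mode,
              if (x$ambiguous) " (ambiguous)" else ""))
  cat(sprintf("  Ki %.4g uM, Vmax %.4g, Km %.4g uM\n", x$Ki, x$Vmax, x$Km))
  cat("  AICc: ", paste(sprintf("%s=%.1f", names(x$mode_scores),
                                x$mode_scores), collapse = ", "), "\n")
  invisible(x)
}

#' Selectivity summary against off-target enzymes
#'
#' Classifies each off-target as inactive (IC50 above the inactivity
#' threshold) or active, and reports fold-selectivity relative to the
#' primary target. Censored potencies (IC50 recorded at or above the
#' threshold, or infinite) yield a lower bound on the fold.
#'
#' @param ic50_by_target Named numeric vector of IC50s, uM (use `Inf` or a
#'   value above the threshold for inactive enzymes).
#' @param primary Name of the primary target in `ic50_by_target`.
#' @param inactivity_threshold IC50 above which a target counts inactive,
#'   uM (default 100).
#' @return Data frame: target, ic50_um, status, fold_selectivity,
#'   fold_label (">n" for censored entries).
#' @export
selectivity_summary <- function(ic50_by_target, primary,
                                inactivity_threshold = 100) {
  if (length(ic50_by_target) == 0) stop_bad("empty target mapping")
  if (is.null(names(ic50_by_target)) || !primary %in%
      names(ic50_by_target)) {
    stop_bad("`primary` must name an entry of `ic50_by_target`")
  }
  p <- ic50_by_target[[primary]]
  if (!is.finite(p) || p <= 0) stop_bad("primary IC50 must be finite and > 0")
  ic <- ic50_by_target
  censored <- !is.finite(ic) | ic >= inactivity_threshold
  fold <- ifelse(censored, inactivity_threshold / p, ic / p)
  data.frame(
    target = names(ic),
    ic50_um = unname(ic),
    status = ifelse(names(ic) == primary, "primary",
                    ifelse(censored, "inactive", "active")),
    fold_selectivity = unname(fold),
    fold_label = ifelse(names(ic) == primary, "1",
                        ifelse(censored, sprintf(">%g", floor(fold)),
                               sprintf("%g", signif(fold, 3)))),
    stringsAsFactors = FALSE
  )
}

#' Weak-activity rate across a bioassay panel
#'
#' Percentage of panel assays in which a compound showed (weak) activity.
#'
#' @param n_active Number of assays with activity.
#' @param n_total Panel size.
#' @return Percent (0-100).
#' @examples
#' panel_activity_rate(19, 759) # 2.5%
#' @export
panel_activity_rate <- function(n_active, n_total) {
  assert_number(n_active, "n_active", 0)
  assert_number(n_total, "n_total", 1)
  if (n_active > n_total) stop_bad("n_active exceeds n_total")
  100 * n_active / n_total
}
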