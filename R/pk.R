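#' Non-compartmental pharmacokinetic analysis
#'
#' Model-free summary of a concentration-time profile. With destructive
#' (composite) sampling each animal contributes a single time point, so the
#' profile is naively pooled: per-time means over available animals. Cmax
#' and Tmax come from the pooled mean profile; the terminal rate constant
#' lambda_z from a log-linear regression over the last `lambda_n`
#' quantifiable points; AUC0-t by the chosen trapezoid dialect
#' (lin-up/log-down by default, WinNonlin's common rule; plain linear
#' available); and AUC0-inf = AUC0-t + Clast / lambda_z. For extravascular
#' dosing a zero concentration at t = 0 is prepended unless the profile
#' already starts at 0 (`add_t0`).
#'
#' @param profile Data frame with columns time_h and conc (uM), optionally
#'   animal_id (pooled by mean per time point).
#' @param method Trapezoid dialect: "linuplogdown" or "linear".
#' @param lambda_n Number of terminal points for the lambda_z regression.
#' @param add_t0 Prepend C = 0 at t = 0 (extravascular dose)?
#' @return An `nca_result` list: cmax, tmax, lambda_z, auc_0t, auc_inf,
#'   clast, tlast, n_lambda, method, times, conc.
#' @export
nca <- function(profile, method = c("linuplogdown", "linear"),
                lambda_n = 3, add_t0 = TRUE) {
  method <- match.arg(method)
  if (!all(c("time_h", "conc") %in% names(profile))) {
    stop_bad("profile needs columns time_h and conc")
  }
  agg <- stats::aggregate(conc ~ time_h, data = profile, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  t <- agg$time_h; c_ <- agg$conc
  if (any(c_ < 0)) stop_bad("concentrations must be >= 0")
  if (length(t) < 3) stop_bad("need >= 3 time points")
  if (any(diff(t) <= 0)) stop_bad("times must be strictly increasing")
  if (add_t0 && t[1] > 0) {
    t <- c(0, t); c_ <- c(0, c_)
  }
  cmax <- max(c_)
  tmax <- t[which.max(c_)]
  auc_0t <- auc_trapezoid(t, c_, method)
  pos <- which(c_ > 0)
  tlast <- t[max(pos)]; clast <- c_[max(pos)]
  lambda_z <- NA_real_; auc_inf <- NA_real_; n_lam <- 0L
  term <- utils::tail(pos, lambda_n)
  if (length(term) >= 3) {
    lmfit <- stats::lm(log(c_[term]) ~ t[term])
    slope <- unname(stats::coef(lmfit)[2])
    if (is.finite(slope) && slope < 0) {
      lambda_z <- -slope
      auc_inf <- auc_0t + clast / lambda_z
      n_lam <- length(term)
    } else {
      warning("terminal slope not negative; AUC0-inf omitted",
              call. = FALSE)
    }
  } else {
    warning("fewer than 3 quantifiable terminal points; lambda_z ",
            "unavailable and AUC0-inf omitted", call. = FALSE)
  }
  structure(list(cmax = cmax, tmax = tmax, lambda_z = lambda_z,
                 auc_0t = auc_0t, auc_inf = auc_inf, clast = clast,
                 tlast = tlast, n_lambda = n_lam, method = method,
                 times = t, conc = c_),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> Cmax %.4g uM at Tmax %g h; AUC0-t %.4g, AUC0-inf %.4g uM*h; lambda_z %.4g /h\n",
    x$cmax, x$tmax, x$auc_0t, x$auc_inf, x$lambda_z))
  invisible(x)
}

#' Trapezoidal area under sampled concentrations
#'
#' The raw trapezoid primitive used by [nca()]. "linuplogdown" applies the
#' linear trapezoid on rising or zero-touching segments and the logarithmic
#' trapezoid on declining positive segments (exact for exponential decay);
#' "linear" applies the linear rule throughout.
#'
#' @param time_h Strictly increasing sampling times, h.
#' @param conc Concentrations (>= 0), uM.
#' @param method "linuplogdown" or "linear".
#' @return AUC, uM*h.
#' @examples
#' auc_points(c(0, 1), c(10, 10), "linear") # 10
#' @export
auc_points <- function(time_h, conc, method = c("linuplogdown",
                                                "linear")) {
  method <- match.arg(method)
  if (length(time_h) != length(conc) || length(time_h) < 2) {
    stop_bad("need >= 2 (time, conc) pairs")
  }
  if (any(diff(time_h) <= 0)) stop_bad("times must be strictly increasing")
  auc_trapezoid(time_h, conc, method)
}

# lin-up/log-down: linear trapezoid on rising
# or zero-touching segments, log trapezoid on declining positive segments.
auc_trapezoid <- function(t, c_, method) {
  dt <- diff(t)
  c1 <- c_[-length(c_)]; c2 <- c_[-1]
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(sum(lin))
  use_log <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- lin
  seg[use_log] <- (c1[use_log] - c2[use_log]) /
    log(c1[use_log] / c2[use_log]) * dt[use_log]
  sum(seg)
}

#' Brain-to-plasma exposure ratio
#'
#' AUC0-inf(brain) / AUC0-inf(plasma). Accepts two [nca()] results or two
#' bare AUC values.
#'
#' @param brain,plasma `nca_result` objects or numeric AUCs (uM*h).
#' @return Dimensionless ratio.
#' @examples
#' auc_ratio(2.6, 10) # 0.26
#' @export
auc_ratio <- function(brain, plasma) {
  val <- function(x) {
    if (inherits(x, "nca_result")) x$auc_inf else x
  }
  b <- val(brain); p <- val(plasma)
  assert_number(p, "plasma AUC", 0, strict_lower = TRUE)
  assert_number(b, "brain AUC", 0)
  b / p
}

#' Time above a concentration threshold
#'
#' Last downward crossing time of the linearly interpolated mean profile
#' above `threshold`, measured from the dose time. Returns 0 when the
#' profile never exceeds the threshold and the last sampling time when it
#' is still above at the end of sampling (no extrapolation).
#'
#' @inheritParams nca
#' @param threshold Concentration threshold, uM.
#' @return Time in hours.
#' @export
time_above <- function(profile, threshold, add_t0 = TRUE) {
  agg <- stats::aggregate(conc ~ time_h, data = profile, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  t <- agg$time_h; c_ <- agg$conc
  if (add_t0 && t[1] > 0) { t <- c(0, t); c_ <- c(0, c_) }
  above <- c_ >= threshold
  if (!any(above)) return(0)
  last <- max(which(above))
  if (last == length(t)) return(t[length(t)])
  # linear interpolation of the downward crossing
  t1 <- t[last]; t2 <- t[last + 1]
  y1 <- c_[last]; y2 <- c_[last + 1]
  t1 + (y1 - threshold) / (y1 - y2) * (t2 - t1)
}

#' Microsomal stability summary
#'
#' First-order decay fit of percent compound remaining vs incubation time.
#' Percentages are renormalised so that the t = 0 point is 100. When the
#' fitted elimination constant is not distinguishable from zero (one-sided
#' p > 0.05) or is negative ("remaining" increases, which is flagged), the
#' compound is reported stable with infinite half-life.
#'
#' @param times_min Incubation times, minutes (must include 0).
#' @param percent_remaining Percent of compound remaining at each time.
#' @param species Label ("mouse", "human", ...).
#' @return A `microsome_stability` list: species, times_min,
#'   percent_remaining (normalised), k_per_min, half_life_min (Inf when
#'   stable), stable, increasing_flag.
#' @export
microsome_summary <- function(times_min, percent_remaining,
                              species = "mouse") {
  if (length(times_min) != length(percent_remaining)) {
    stop_bad("length mismatch")
  }
  if (!any(times_min == 0)) stop_bad("times must include 0")
  p0 <- mean(percent_remaining[times_min == 0])
  pr <- 100 * percent_remaining / p0
  if (any(pr <= 0)) stop_bad("percent remaining must be positive")
  fitdat <- data.frame(t = times_min, lp = log(pr))
  lmfit <- stats::lm(lp ~ t, data = fitdat)
  slope <- unname(stats::coef(lmfit)[2])
  se <- tryCatch(
    suppressWarnings(summary(lmfit)$coefficients["t", "Std. Error"]),
    error = function(e) NA_real_)
  increasing <- is.finite(slope) && slope > 0
  if (increasing) {
    warning("percent remaining increases with time; clipping decay ",
            "constant to 0 (reported stable)", call. = FALSE)
  }
  k <- max(-slope, 0)
  if (k < 1e-9) k <- 0 # numerically flat time course
  # one-sided test of decay (slope < 0); a perfect fit (se ~ 0) counts as
  # significant whenever there is any decay at all
  pval <- if (is.finite(se) && se > 1e-12) {
    stats::pt(slope / se, df = stats::df.residual(lmfit))
  } else if (k > 0) 0 else 1
  stable <- increasing || pval > 0.05 || k == 0
  structure(list(species = species, times_min = times_min,
                 percent_remaining = pr, k_per_min = k,
                 half_life_min = if (stable) Inf else log(2) / k,
                 stable = stable, increasing_flag = increasing),
            class = "microsome_stability")
}

#' @export
print.microsome_stability <- function(x, ...) {
  cat(sprintf("<microsome_stability> %s: %s\n", x$species,
              if (x$stable) "stable (t1/2 = Inf)" else
                sprintf("t1/2 = %.3g min", x$half_life_min)))
  invisible(x)
}
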