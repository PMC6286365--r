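#' Simulate a plasma/brain pharmacokinetic study
#'
#' One-compartment model with first-order absorption:
#' `C(t) = A * (exp(-ke * t) - exp(-ka * t))`. The brain profile is the
#' plasma profile scaled by `brain_partition`. Sampling is destructive
#' (composite design): each animal contributes the plasma and brain sample
#' at a single time point, with independent lognormal noise per matrix.
#'
#' Defaults emulate a 10 mg/kg intraperitoneal dose sampled at 0.25, 0.5,
#' 1, 2, 4 and 6 h with n = 3 animals per time point: ka = 3.1 /h and
#' ke = 1.2 /h put Tmax at 0.5 h, A = 34.5 uM puts plasma Cmax near
#' 11.6 uM, and brain_partition = 0.26 fixes the brain/plasma AUC ratio.
#'
#' @param A Profile coefficient, uM.
#' @param ka Absorption rate constant, 1/h.
#' @param ke Elimination rate constant, 1/h (ka > ke).
#' @param brain_partition Brain-to-plasma concentration fraction.
#' @param times Sampling times, h.
#' @param n_per_time Animals per time point.
#' @param noise_cv Lognormal CV of individual concentrations.
#' @param seed Integer seed.
#' @return Data frame: matrix ("plasma"/"brain"), time_h, conc (uM),
#'   animal_id. Attribute `truth` carries the generating parameters and the
#'   analytic AUC0-inf, `A * (1/ke - 1/ka)`.
#' @export
simulate_pk <- function(A = 34.5, ka = 3.1, ke = 1.2,
                        brain_partition = 0.26,
                        times = c(0.25, 0.5, 1, 2, 4, 6),
                        n_per_time = 3, noise_cv = 0.1, seed = 1) {
  assert_number(A, "A", 0, strict_lower = TRUE)
  assert_number(ka, "ka", 0, strict_lower = TRUE)
  assert_number(ke, "ke", 0, strict_lower = TRUE)
  if (ka <= ke) stop_bad("ka must exceed ke (flip-flop not modelled)")
  assert_number(brain_partition, "brain_partition", 0)
  if (length(times) < 1 || any(times <= 0)) stop_bad("invalid times")
  conc_fun <- function(t) A * (exp(-ke * t) - exp(-ka * t))
  grid <- expand.grid(time_h = times, repl = seq_len(n_per_time),
                      KEEP.OUT.ATTRS = FALSE)
  grid$animal_id <- sprintf("M%03d", seq_len(nrow(grid)))
  mu_p <- conc_fun(grid$time_h)
  out <- with_seed(derive_seed(seed, 31L), {
    plasma <- data.frame(matrix = "plasma", time_h = grid$time_h,
                         conc = rlnorm_cv(nrow(grid), mu_p, noise_cv),
                         animal_id = grid$animal_id,
                         stringsAsFactors = FALSE)
    brain <- data.frame(matrix = "brain", time_h = grid$time_h,
                        conc = rlnorm_cv(nrow(grid),
                                         mu_p * brain_partition, noise_cv),
                        animal_id = grid$animal_id,
                        stringsAsFactors = FALSE)
    rbind(plasma, brain)
  })
  attr(out, "truth") <- list(A = A, ka = ka, ke = ke,
                             brain_partition = brain_partition,
                             auc_inf_plasma = A * (1 / ke - 1 / ka),
                             auc_inf_brain = brain_partition *
                               A * (1 / ke - 1 / ka),
                             tmax_h = log(ka / ke) / (ka - ke),
                             cmax = conc_fun(log(ka / ke) / (ka - ke)))
  out
}

#' Simulate an in vitro EV-release dose-response study
#'
#' Extracellular vesicle (particle) concentrations per replicate are drawn
#' lognormally around an Emax-type inhibition of the vehicle baseline:
#' `mean(d) = floor + (baseline - floor) * (1 - (emax/100) * d / (d + ec50))`.
#' An inactive-analog arm is generated with zero effect at the same doses.
#'
#' @param doses Treatment concentrations, uM (0 = vehicle).
#' @param baseline Vehicle mean particle concentration, EVs/mL.
#' @param emax Maximal percent reduction of the releasable pool.
#' @param ec50 Half-maximal concentration, uM.
#' @param floor Residual (release-independent) particle background, EVs/mL.
#' @param n_replicates Replicate experiments per dose.
#' @param dispersion_cv Lognormal CV of replicate values.
#' @param include_inactive_analog Add the zero-effect comparator arm?
#' @param seed Integer seed.
#' @return Data frame: arm, dose_um, replicate, ev_per_ml.
#' @export
simulate_ev_study <- function(doses = c(0, 0.03, 0.1, 0.3, 1, 3, 10),
                              baseline = 1e9, emax = 90, ec50 = 0.3,
                              floor = 0, n_replicates = 4,
                              dispersion_cv = 0.15,
                              include_inactive_analog = TRUE, seed = 1) {
  assert_number(emax, "emax", 0, 100)
  assert_number(ec50, "ec50", 0, strict_lower = TRUE)
  if (n_replicates < 2) stop_bad("need >= 2 replicates per group")
  arms <- if (include_inactive_analog) c("active", "inactive_analog")
          else "active"
  with_seed(derive_seed(seed, 41L), {
    out <- lapply(arms, function(a) {
      e <- if (a == "active") emax else 0
      mu <- floor + (baseline - floor) *
        (1 - (e / 100) * doses / (doses + ec50))
      data.frame(arm = a,
                 dose_um = rep(doses, each = n_replicates),
                 replicate = rep(seq_len(n_replicates), length(doses)),
                 ev_per_ml = rlnorm_cv(length(doses) * n_replicates,
                                       rep(mu, each = n_replicates),
                                       dispersion_cv),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate grouped replicate counts (in vivo endpoints)
#'
#' Lognormal replicate values around per-group means with per-group CVs.
#' Used for the in vivo endpoints: circulating astrocyte-derived EV counts
#' and brain neutrophil counts under saline / stimulus / stimulus+drug /
#' stimulus+inactive-analog conditions.
#'
#' @param group_means Named numeric vector of group means.
#' @param cv Per-group CV (recycled).
#' @param n Replicates (animals) per group.
#' @param seed Integer seed.
#' @return Data frame: group, replicate, value.
#' @export
simulate_group_counts <- function(group_means, cv = 0.2, n = 5, seed = 1) {
  if (is.null(names(group_means))) stop_bad("group_means must be named")
  if (n < 2) stop_bad("need n >= 2 per group")
  cv <- rep_len(cv, length(group_means))
  with_seed(derive_seed(seed, 43L), {
    out <- mapply(function(g, m, v) {
      data.frame(group = g, replicate = seq_len(n),
                 value = rlnorm_cv(n, m, v), stringsAsFactors = FALSE)
    }, names(group_means), group_means, cv, SIMPLIFY = FALSE)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate qPCR Ct values for a treatment-vs-control design
#'
#' Target-gene Ct values shift by -log2(fold) in the treatment group
#' relative to control; the reference gene is unaffected. Gaussian cycle
#' noise is added independently to target and reference Cts.
#'
#' @param fold_changes Named vector: planted treatment/control fold change
#'   per target gene.
#' @param reference_ct Reference-gene Ct (cycles).
#' @param target_ct_control Control-group target Ct (cycles; recycled).
#' @param n Samples per group.
#' @param noise_sd Ct noise, cycles.
#' @param seed Integer seed.
#' @return Data frame: sample_id, group ("control"/"treatment"), gene,
#'   ct_target, ct_reference.
#' @export
simulate_qpcr <- function(fold_changes, reference_ct = 18,
                          target_ct_control = 25, n = 5, noise_sd = 0.1,
                          seed = 1) {
  if (is.null(names(fold_changes))) stop_bad("fold_changes must be named")
  if (any(fold_changes <= 0)) stop_bad("fold changes must be positive")
  tcc <- rep_len(target_ct_control, length(fold_changes))
  with_seed(derive_seed(seed, 47L), {
    out <- list()
    for (gi in seq_along(fold_changes)) {
      gene <- names(fold_changes)[gi]
      for (grp in c("control", "treatment")) {
        ct_t <- tcc[gi] - if (grp == "treatment")
          log2(fold_changes[[gi]]) else 0
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%02d", gene, grp, seq_len(n)),
          group = grp, gene = gene,
          ct_target = ct_t + stats::rnorm(n, 0, noise_sd),
          ct_reference = reference_ct + stats::rnorm(n, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a substrate x inhibitor kinetic rate grid
#'
#' Rates from [simulate_rate()] over a grid of substrate and inhibitor
#' concentrations with optional lognormal noise; the input for
#' [fit_mm()] / [fit_inhibition_global()].
#'
#' @inheritParams simulate_rate
#' @param substrate_levels Substrate concentrations, uM.
#' @param inhibitor_levels Inhibitor concentrations, uM (include 0).
#' @param noise_cv Lognormal CV on rates.
#' @param replicates Replicates per grid point.
#' @param seed Integer seed.
#' @return Data frame: substrate, inhibitor, rate, replicate.
#' @export
simulate_kinetic_series <- function(assay, true_ic50,
                                    substrate_levels = c(5, 10, 20, 40),
                                    inhibitor_levels = c(0, 0.01, 0.03,
                                                         0.1),
                                    mode = "noncompetitive",
                                    efficacy = 100, noise_cv = 0,
                                    replicates = 1, seed = 1) {
  grid <- expand.grid(substrate = substrate_levels,
                      inhibitor = inhibitor_levels,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- simulate_rate(assay, grid$substrate, grid$inhibitor,
                      true_ic50 = true_ic50, efficacy = efficacy,
                      mode = mode)
  grid$rate <- with_seed(derive_seed(seed, 53L),
                         rlnorm_cv(nrow(grid), mu, noise_cv))
  grid[, c("substrate", "inhibitor", "rate", "replicate")]
}

#' Simulate a microsomal stability time course
#'
#' Percent compound remaining under first-order decay with lognormal noise.
#'
#' @param times_min Sampling times, minutes (include 0).
#' @param half_life_min True half-life (Inf = stable).
#' @param noise_cv Lognormal CV on percent remaining.
#' @param species Label.
#' @param seed Integer seed.
#' @return Data frame: species, time_min, percent_remaining.
#' @export
simulate_microsome <- function(times_min = c(0, 10, 20, 30, 60),
                               half_life_min = Inf, noise_cv = 0,
                               species = "mouse", seed = 1) {
  mu <- if (is.finite(half_life_min)) {
    100 * exp(-log(2) / half_life_min * times_min)
  } else rep(100, length(times_min))
  data.frame(species = species, time_min = times_min,
             percent_remaining = with_seed(derive_seed(seed, 59L),
                                           rlnorm_cv(length(mu), mu,
                                                     noise_cv)),
             stringsAsFactors = FALSE)
}

#' Simulate the in vivo astrocyte-EV and neutrophil endpoint studies
#'
#' Grouped replicate counts for the two in vivo endpoints of an
#' IL-1beta-driven brain-inflammation model, with planted drug effects:
#'
#' * `simulate_adev_study()`: GFP-labelled astrocyte-derived EV counts in
#'   plasma 2 h after IL-1beta. The stimulus raises counts above saline;
#'   drug treatment reduces the stimulated counts by `reduction_pct`
#'   (default 51%); the inactive analog has no effect. Group CV 0.19,
#'   calibrated so the delta-method spread of the reduction estimate is
#'   about +-13 percentage points at n = 5.
#' * `simulate_neutrophil_study()`: brain neutrophil counts 24 h after
#'   IL-1beta, planted `reduction_pct` 80%. Treated-group CV 1.0 and
#'   stimulated-group CV 0.57 give a reduction spread of about +-23 points.
#'
#' @param stimulated_mean Mean of the IL-1beta group (EVs/mL or cells).
#' @param saline_frac Saline-group mean as a fraction of the stimulated
#'   mean.
#' @param reduction_pct Planted percent reduction under drug.
#' @param n Animals per group.
#' @param cv Group CV(s), recycled over groups (saline, il1b, il1b_drug,
#'   il1b_analog).
#' @param seed Integer seed.
#' @return Data frame: group, replicate, value (see
#'   [simulate_group_counts()]).
#' @export
simulate_adev_study <- function(stimulated_mean = 5e8, saline_frac = 0.3,
                                reduction_pct = 51, n = 5, cv = 0.19,
                                seed = 1) {
  simulate_group_counts(
    c(saline = stimulated_mean * saline_frac,
      il1b = stimulated_mean,
      il1b_drug = stimulated_mean * (1 - reduction_pct / 100),
      il1b_analog = stimulated_mean),
    cv = cv, n = n, seed = seed)
}

#' @rdname simulate_adev_study
#' @export
simulate_neutrophil_study <- function(stimulated_mean = 100,
                                      saline_frac = 0.05,
                                      reduction_pct = 80, n = 5,
                                      cv = c(0.3, 0.57, 1.0, 0.57),
                                      seed = 1) {
  simulate_group_counts(
    c(saline = stimulated_mean * saline_frac,
      il1b = stimulated_mean,
      il1b_drug = stimulated_mean * (1 - reduction_pct / 100),
      il1b_analog = stimulated_mean),
    cv = cv, n = n, seed = seed)
}
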