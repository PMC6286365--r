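#' Simulate a set of 1536-well screening plates
#'
#' Generates well-level fluorescence for the primary (main) assay: one plate
#' per dose in `dose_scheme`, with the layout's control columns populated
#' (cambinol dose series at IC50 27 uM in column 1, no-enzyme background in
#' column 2, saturating positive control in column 3) and library compounds
#' filling columns 4 onward row-major. Libraries larger than the compound
#' field are split across plate series. Unassigned compound wells are
#' vehicle-only (full signal, `compound_id` NA).
#'
#' Well RFU = background + gain x product, attenuated by each compound's
#' fractional inhibition at the plated dose, with multiplicative lognormal
#' noise (`assay$noise_cv`) and additive read noise (`assay$read_noise_sd`).
#' Counter-screen false positives suppress signal here too (they inhibit
#' the detection cascade, which is part of the readout), with their
#' `counter_ic50` as the apparent potency.
#'
#' @param layout A [plate_layout()].
#' @param assay An [assay_model()].
#' @param compounds Ground-truth table from [compound_library()].
#' @param doses Dose scheme, uM (default [dose_scheme()]: 4 doses, 57 uM
#'   top, 5-fold dilutions).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param pos_series_ic50 IC50 of the column-1 control inhibitor, uM
#'   (cambinol, 27 uM).
#' @param plate_prefix Prefix for plate ids.
#' @return Data frame of well measurements: plate_id, row, col, role,
#'   compound_id, conc_um, rfu.
#' @export
simulate_plate <- function(layout, assay, compounds,
                           doses = dose_scheme(), seed = 1,
                           pos_series_ic50 = 27,
                           plate_prefix = "main") {
  simulate_plate_impl(layout, assay, compounds, doses, seed,
                      pos_series_ic50, plate_prefix, counter = FALSE)
}

#' Simulate counter-screen plates (detection cascade only)
#'
#' Same geometry and noise model as [simulate_plate()], but the signal is
#' generated by the coupling cascade alone (no target enzyme; the cascade is
#' driven by spiked phosphorylcholine). True inhibitors of the target enzyme
#' therefore produce no inhibition here; counter false positives inhibit
#' with their `counter_ic50`. The column-1 control series is inactive in
#' this assay.
#'
#' @inheritParams simulate_plate
#' @return Data frame of well measurements (same schema as
#'   [simulate_plate()]).
#' @export
simulate_counter_plate <- function(layout, assay, compounds,
                                   doses = dose_scheme(), seed = 1,
                                   plate_prefix = "counter") {
  simulate_plate_impl(layout, assay, compounds, doses, seed,
                      pos_series_ic50 = NA, plate_prefix, counter = TRUE)
}

simulate_plate_impl <- function(layout, assay, compounds, doses, seed,
                                pos_series_ic50, plate_prefix, counter) {
  if (length(doses) == 0) stop_bad("`doses` must contain at least one dose")
  if (any(doses <= 0)) stop_bad("doses must be positive (uM)")
  validate_ground_truth(compounds)
  field <- n_compound_wells(layout)
  chunks <- split(seq_len(nrow(compounds)),
                  ceiling(seq_len(nrow(compounds)) / field))
  neutral <- expected_rfu(assay)
  window <- neutral - assay$background_rfu
  out <- vector("list", length(chunks) * length(doses))
  k <- 0L
  for (ci in seq_along(chunks)) {
    cmp <- compounds[chunks[[ci]], , drop = FALSE]
    for (di in seq_along(doses)) {
      k <- k + 1L
      d <- doses[di]
      w <- layout$wells
      w$plate_id <- sprintf("%s_c%02d_d%02d", plate_prefix, ci, di)
      w$compound_id <- NA_character_
      w$conc_um <- 0
      is_cmp <- w$role == "compound"
      idx <- which(is_cmp)[seq_len(nrow(cmp))]
      w$compound_id[idx] <- cmp$compound_id
      w$conc_um[idx] <- d
      w$conc_um[w$role == "pos_series"] <-
        w$series_conc_um[w$role == "pos_series"]
      # fractional enzyme (or cascade) activity per well
      frac <- rep(1, nrow(w))
      fr <- compound_activity_fraction(cmp, d, counter)
      frac[idx] <- fr
      if (!counter) {
        ps <- w$role == "pos_series"
        frac[ps] <- 1 - w$conc_um[ps] / (w$conc_um[ps] + pos_series_ic50)
      }
      mu <- assay$background_rfu + window * frac
      mu[w$role == "neg_control"] <- assay$background_rfu
      sub_seed <- derive_seed(seed, 97L * k + if (counter) 50000L else 0L)
      w$rfu <- with_seed(sub_seed, {
        r <- rlnorm_cv(nrow(w), mu, assay$noise_cv)
        if (assay$read_noise_sd > 0) {
          r <- r + stats::rnorm(nrow(w), 0, assay$read_noise_sd)
        }
        r
      })
      out[[k]] <- w[, c("plate_id", "row", "col", "role", "compound_id",
                        "conc_um", "rfu")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fraction of uninhibited signal for each compound at dose d (uM).
compound_activity_fraction <- function(cmp, d, counter) {
  frac <- rep(1, nrow(cmp))
  if (counter) {
    hit <- cmp$class_label == "counter_false_positive"
    frac[hit] <- 1 - (cmp$true_efficacy[hit] / 100) *
      d / (d + cmp$counter_ic50[hit])
  } else {
    inh <- cmp$class_label %in% c("true_inhibitor", "promiscuous")
    frac[inh] <- 1 - (cmp$true_efficacy[inh] / 100) *
      d / (d + cmp$true_ic50[inh])
    cfp <- cmp$class_label == "counter_false_positive"
    frac[cfp] <- 1 - (cmp$true_efficacy[cfp] / 100) *
      d / (d + cmp$counter_ic50[cfp])
  }
  frac
}
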