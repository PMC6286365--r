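#' Forward model of the coupled-fluorescence sphingomyelinase assay
#'
#' Describes the enzyme-coupled Amplex Red readout used for the screen: the
#' enzyme hydrolyses sphingomyelin (SM) to ceramide and phosphorylcholine,
#' and phosphorylcholine is converted stoichiometrically through a coupling
#' cascade to fluorescent resorufin, so fluorescence is proportional to
#' accumulated product. Product formation is linearised over the incubation
#' (the reaction is run in its linear range) and a guard checks that
#' accumulated product stays below 10% of substrate so depletion can be
#' ignored.
#'
#' Default values reproduce the screening conditions: 0.1 ug protein/uL
#' lysate, 20 uM SM, 2 h incubation, and a neutral (uninhibited) signal of
#' about 2500 RFU over a background of about 119 RFU, i.e.
#' signal/background = 21. The noise model is multiplicative lognormal with
#' coefficient of variation `noise_cv` plus additive Gaussian read noise
#' (`read_noise_sd`, RFU); the defaults give an analytic Z' of 0.80 for the
#' control columns.
#'
#' @param enzyme_conc Enzyme preparation concentration, ug protein/uL.
#' @param substrate_conc SM concentration, uM.
#' @param incubation_time Incubation, minutes.
#' @param gain Fluorescence yield, RFU per uM product.
#' @param background_rfu Background fluorescence (no-enzyme wells), RFU.
#' @param noise_cv Multiplicative well-to-well noise (lognormal CV, fraction).
#' @param read_noise_sd Additive detector noise, RFU.
#' @param Km_SM Michaelis constant for SM, uM.
#' @param Vmax Maximal product formation rate at the reference enzyme
#'   concentration (0.1 ug/uL), uM product per hour.
#' @return An object of class `assay_model`.
#' @examples
#' am <- assay_model()
#' expected_rfu(am) # ~2500 RFU
#' @export
assay_model <- function(enzyme_conc = 0.1, substrate_conc = 20,
                        incubation_time = 120, gain = 1253,
                        background_rfu = 119, noise_cv = 0.05,
                        read_noise_sd = 27, Km_SM = 20, Vmax = 1.9) {
  assert_number(gain, "gain", 0, strict_lower = TRUE)
  assert_number(noise_cv, "noise_cv", 0)
  assert_number(read_noise_sd, "read_noise_sd", 0)
  assert_number(Km_SM, "Km_SM", 0, strict_lower = TRUE)
  assert_number(Vmax, "Vmax", 0, strict_lower = TRUE)
  assert_number(enzyme_conc, "enzyme_conc", 0)
  assert_number(substrate_conc, "substrate_conc", 0, strict_lower = TRUE)
  assert_number(incubation_time, "incubation_time", 0)
  assert_number(background_rfu, "background_rfu", 0)
  structure(list(
    enzyme_conc = enzyme_conc, substrate_conc = substrate_conc,
    incubation_time = incubation_time, gain = gain,
    background_rfu = background_rfu, noise_cv = noise_cv,
    read_noise_sd = read_noise_sd, Km_SM = Km_SM, Vmax = Vmax,
    reference_enzyme_conc = 0.1
  ), class = "assay_model")
}

#' @export
print.assay_model <- function(x, ...) {
  cat("<assay_model>\n")
  cat(sprintf("  enzyme %g ug/uL, SM %g uM, %g min incubation\n",
              x$enzyme_conc, x$substrate_conc, x$incubation_time))
  cat(sprintf("  Vmax %g uM/h (ref conc), Km(SM) %g uM\n", x$Vmax, x$Km_SM))
  cat(sprintf("  gain %g RFU/uM, background %g RFU, noise CV %g, read sd %g\n",
              x$gain, x$background_rfu, x$noise_cv, x$read_noise_sd))
  cat(sprintf("  expected neutral signal %0.1f RFU\n", expected_rfu(x)))
  invisible(x)
}

#' Uninhibited product formation rate (uM/h) under an assay model
#'
#' Michaelis-Menten rate scaled linearly by enzyme concentration relative to
#' the reference preparation.
#'
#' @param assay An [assay_model()].
#' @param substrate SM concentration, uM (default: the model's).
#' @param enzyme Enzyme concentration, ug/uL (default: the model's).
#' @return Rate in uM product per hour.
#' @export
neutral_rate <- function(assay, substrate = assay$substrate_conc,
                         enzyme = assay$enzyme_conc) {
  (enzyme / assay$reference_enzyme_conc) *
    assay$Vmax * substrate / (assay$Km_SM + substrate)
}

#' Expected fluorescence (RFU) of a well
#'
#' Background plus gain times accumulated product over the incubation.
#' Expected signal is nondecreasing in incubation time, enzyme concentration
#' and substrate concentration. Warns if accumulated product exceeds 10% of
#' substrate (the linearisation guard).
#'
#' @inheritParams neutral_rate
#' @param time Incubation time, minutes.
#' @param activity_fraction Fraction of uninhibited enzyme activity in the
#'   well (1 = neutral, 0 = fully inhibited).
#' @return Expected RFU (no noise).
#' @export
expected_rfu <- function(assay, substrate = assay$substrate_conc,
                         enzyme = assay$enzyme_conc,
                         time = assay$incubation_time,
                         activity_fraction = 1) {
  product <- neutral_rate(assay, substrate, enzyme) * (time / 60) *
    activity_fraction
  if (any(product > 0.1 * substrate)) {
    warning("accumulated product exceeds 10% of substrate; ",
            "linear-rate approximation is strained", call. = FALSE)
  }
  assay$background_rfu + assay$gain * product
}

#' Simulate an enzymatic rate under an inhibitor
#'
#' Generates the true (noise-free) product-formation rate at a given
#' substrate and inhibitor concentration. For `mode = "noncompetitive"` the
#' inhibitor lowers the apparent Vmax without changing Km, so that at
#' `inhibitor == true_ic50` the rate is halved at any substrate
#' concentration (for full efficacy); the IC50 then equals the inhibition
#' constant Ki independent of substrate. Partial inhibitors scale the
#' inhibited fraction by `efficacy`/100. `mode = "competitive"` and
#' `"uncompetitive"` interpret `true_ic50` as Ki in the corresponding
#' classical rate law; `mode = "none"` ignores the inhibitor.
#'
#' @inheritParams neutral_rate
#' @param inhibitor Inhibitor concentration, uM (>= 0).
#' @param true_ic50 Inhibitor potency, uM (equals Ki for noncompetitive).
#' @param efficacy Maximal percent inhibition (0-100); only meaningful for
#'   the noncompetitive mode.
#' @param mode One of "noncompetitive", "competitive", "uncompetitive",
#'   "none".
#' @return Rate, uM product per hour.
#' @examples
#' am <- assay_model()
#' simulate_rate(am, substrate = am$Km_SM, inhibitor = 0) # Vmax/2
#' @export
simulate_rate <- function(assay, substrate, inhibitor = 0, true_ic50 = NA,
                          efficacy = 100,
                          mode = c("noncompetitive", "competitive",
                                   "uncompetitive", "none")) {
  mode <- match.arg(mode)
  if (any(substrate <= 0)) stop_bad("`substrate` must be > 0")
  if (any(inhibitor < 0)) stop_bad("`inhibitor` must be >= 0")
  if (mode != "none") {
    if (any(is.na(true_ic50)) || any(true_ic50 <= 0)) {
      stop_bad("`true_ic50` must be a positive number for mode '%s'", mode)
    }
    assert_number(efficacy, "efficacy", 0, 100)
  }
  scale <- assay$enzyme_conc / assay$reference_enzyme_conc
  Vm <- assay$Vmax * scale
  Km <- assay$Km_SM
  switch(mode,
    none = Vm * substrate / (Km + substrate),
    noncompetitive = Vm * substrate / (Km + substrate) *
      (1 - (efficacy / 100) * inhibitor / (inhibitor + true_ic50)),
    competitive = Vm * substrate /
      (Km * (1 + inhibitor / true_ic50) + substrate),
    uncompetitive = Vm * substrate /
      (Km + substrate * (1 + inhibitor / true_ic50))
  )
}
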