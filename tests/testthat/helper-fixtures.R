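# Shared fixtures: assay models and small screens built in code.

noise_free_assay <- function() {
  assay_model(noise_cv = 0, read_noise_sd = 0)
}

# vector with exact mean m and exact sample sd s
vec_with_moments <- function(n, m, s, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  m + (z - mean(z)) / stats::sd(z) * s
}

# percent-inhibition responses from a 4PL truth with rate-ratio noise
make_curve <- function(doses, top, ic50, hill = 1, bottom = 0, cv = 0) {
  y <- bottom + (top - bottom) /
    (1 + 10^(hill * (log10(ic50) - log10(doses))))
  if (cv > 0) {
    act <- 1 - y / 100
    sdlog <- sqrt(log(1 + cv^2))
    act <- act * stats::rlnorm(length(act), -sdlog^2 / 2, sdlog)
    y <- 100 * (1 - act)
  }
  y
}

small_screen <- function(n = 120, noise = FALSE, seed = 5) {
  am <- if (noise) assay_model() else noise_free_assay()
  cmp <- compound_library(n, seed = seed)
  plates <- simulate_plate(plate_layout(), am, cmp, seed = seed)
  list(assay = am, compounds = cmp, plates = plates)
}
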