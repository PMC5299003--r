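# Closed-form OLS oracle (textbook formulas), kept independent of the
# lm()-based implementation paths.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  list(slope = slope, se = se)
}

# Build a porewater profile directly from depth/concentration vectors.
profile_from_vectors <- function(depth_mm, conc_uM, analyte = "H2S",
                                 porosity = 0.9, censored = "ok", ...) {
  porewater_profile(
    station = "test", water_depth_m = 100,
    data = data.frame(depth_mm = depth_mm, analyte = analyte,
                      conc_uM = conc_uM, censored = censored),
    porosity_surface = porosity, ...)
}

# Random sulfide-recovery scenario: the target flux is drawn log-uniformly,
# and the gradient-zone thickness follows from a measurable concentration
# span (150-400 uM), mirroring how fit windows track the linear region of
# real profiles (5 mm windows for steep mat gradients, tens of mm for weak
# deep gradients).
random_recovery_scenario <- function(seed) {
  set.seed(seed)
  flux <- 10^stats::runif(1, log10(0.1), log10(10))
  porosity <- 0.9
  Ds <- sediment_diffusivity(
    diffusion_coefficient("H2S", 12, 10)$D_free, porosity)
  slope <- flux / (porosity * Ds * 1000) # uM/mm
  span <- stats::runif(1, 150, 400)
  width <- min(max(span / slope, 3), 80)
  with_mat <- stats::runif(1) < 0.5
  top <- if (with_mat) 1 else 0
  thick <- stats::runif(1, 10, 30)
  rate <- flux / (porosity * thick * 1e-3)
  scenario(
    station_label = sprintf("syn%03d", seed),
    bottom_water_conc = c(H2S = if (with_mat) 0 else stats::runif(1, 0, 100)),
    production_zone = c(top + width, top + width + thick, rate),
    mat_layer = if (with_mat) c(0, 1) else NULL,
    porosity = porosity, noise_sd = 2, seed = seed)
}

# Recover the interface flux from a generated profile the way the flux
# module consumes it.
recover_flux <- function(gp) {
  g <- fit_gradient(gp$profile, "H2S", gp$truth$fit_window)
  Ds <- sediment_diffusivity(
    diffusion_coefficient("H2S", 12, 10)$D_free,
    gp$profile$porosity_surface)
  diffusive_flux(g$slope, g$se_slope, gp$profile$porosity_surface, Ds)$flux
}

# Four replicate scans (first biased, as in the field protocol) for a given
# concentration map.
replicate_scans <- function(true_conc, calib = calibration_model(),
                            noise_sd_nA = 0.1, seed = 1, depth_mm = 0) {
  lapply(1:4, function(r)
    generate_voltammogram(true_conc, calib, noise_sd_nA = noise_sd_nA,
                          seed = seed + r, depth_mm = depth_mm,
                          replicate = r))
}
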