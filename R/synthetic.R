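# Ground-truth scenario generator. A steady-state 1-D reaction-diffusion
# model produces porewater profiles with an analytically known interface
# flux; matching voltammograms and chamber time series exercise the full
# measurement chain.
#
# Depth convention (package-wide): z in mm, positive downward, 0 at the
# sediment-water interface; overlying-water points carry negative depths.

#' Define a synthetic station scenario
#'
#' Describes a station for the steady-state generator: a constant volumetric
#' sulfide source over a depth interval, an optional surface mat that
#' consumes sulfide completely (modelled as a strong first-order sink), and
#' an optional deep Fe(II) source below which FeS precipitation removes both
#' species where they would overlap.
#'
#' @param station_label station name.
#' @param water_depth_m water depth (m), metadata.
#' @param bottom_water_conc named vector of bottom-water concentrations (uM),
#'   e.g. `c(H2S = 0)`.
#' @param production_zone `c(top_mm, bottom_mm, rate_uM_day)` for the sulfide
#'   source (rate per porewater volume, >= 0).
#' @param mat_layer optional `c(top_mm, bottom_mm)` total-consumption zone.
#' @param fe_source optional `c(depth_mm, flux_mmol_m2_day)` deep Fe(II)
#'   source.
#' @param porosity surface porosity phi(0), in (0, 1]. No field value is
#'   available for the study sediments; 0.9 is assumed for organic-rich mud.
#' @param depth_step grid step (mm), >= 0.25 (the profiling step).
#' @param max_depth_mm bottom of the model domain (mm).
#' @param noise_sd additive Gaussian noise on sampled concentrations (uM),
#'   truncated at zero at sampling time.
#' @param salinity,temperature ambient conditions for diffusion coefficients.
#' @param seed integer seed for the sampling noise.
#' @return an object of class `scenario`.
#' @export
scenario <- function(station_label = "synthetic",
                     water_depth_m = 110,
                     bottom_water_conc = c(H2S = 0),
                     production_zone = c(5, 40, 75),
                     mat_layer = c(0, 1),
                     fe_source = NULL,
                     porosity = 0.9,
                     depth_step = 0.25,
                     max_depth_mm = NULL,
                     noise_sd = 2,
                     salinity = 12, temperature = 10,
                     seed = 1L) {
  if (depth_step < 0.25) stop("depth_step must be >= 0.25 mm")
  if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]")
  if (length(production_zone) != 3 || production_zone[3] < 0)
    stop("production_zone must be c(top_mm, bottom_mm, rate >= 0)")
  if (production_zone[2] <= production_zone[1])
    stop("production zone bottom must lie below its top")
  if (!is.null(mat_layer) && mat_layer[2] <= mat_layer[1])
    stop("mat layer bottom must lie below its top")
  if (!is.null(fe_source) && (length(fe_source) != 2 || fe_source[2] < 0))
    stop("fe_source must be c(depth_mm, flux >= 0)")
  if (is.null(max_depth_mm))
    max_depth_mm <- max(production_zone[2],
                        if (is.null(fe_source)) 0 else fe_source[1]) + 20
  structure(
    list(station_label = station_label, water_depth_m = water_depth_m,
         bottom_water_conc = bottom_water_conc,
         production_zone = production_zone, mat_layer = mat_layer,
         fe_source = fe_source, porosity = porosity,
         depth_step = depth_step, max_depth_mm = max_depth_mm,
         noise_sd = noise_sd, salinity = salinity, temperature = temperature,
         seed = as.integer(seed)),
    class = "scenario"
  )
}

# Solve -Ds C'' + k(z) C = R(z) on a uniform grid with Dirichlet top
# (bottom-water concentration) and zero-gradient bottom, by a tridiagonal
# (Thomas) solve. Ds in m2/day, z in mm, k in 1/day, R in uM/day.
.solve_steady_state <- function(z_mm, Ds, k, R, c_top) {
  n <- length(z_mm)
  h <- (z_mm[2] - z_mm[1]) * 1e-3 # m
  a <- rep(-Ds / h^2, n) # sub-diagonal
  b <- rep(2 * Ds / h^2, n) + k
  cc <- rep(-Ds / h^2, n) # super-diagonal
  d <- R
  # top Dirichlet
  b[1] <- 1; cc[1] <- 0; d[1] <- c_top
  # bottom zero-gradient: C[n] = C[n-1]
  a[n] <- -1; b[n] <- 1; d[n] <- 0
  # Thomas algorithm
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  x <- numeric(n)
  x[n] <- d[n] / b[n]
  for (i in (n - 1):1) x[i] <- (d[i] - cc[i] * x[i + 1]) / b[i]
  x
}

#' Generate a synthetic porewater profile with known truth
#'
#' Solves the steady-state 1-D diffusion-reaction model on the scenario grid
#' (second-order finite differences, Dirichlet top boundary at the
#' bottom-water concentration, zero-gradient bottom) and samples it with
#' additive Gaussian noise truncated at zero. The mat layer is a first-order
#' sink strong enough (`k_mat`) to force the concentration at the mat top
#' below 0.1 uM. An Fe(II) source injects iron below `fe_source` depth; FeS
#' precipitation (first-order in each species where the other is present)
#' keeps the Fe(II) and sulfide fields from overlapping substantially.
#'
#' The true sulfide flux is the analytic steady-state flux through the top
#' of the source-free diffusive zone (the mat base when a mat is present,
#' otherwise the interface): `phi * rate * thickness` of the production
#' zone, positive out of the sediment. When a deep FeS sink intercepts part
#' of the production this analytic value is replaced by the numerically
#' evaluated gradient flux at the same level.
#'
#' @param scen a [scenario()].
#' @param k_mat first-order mat consumption rate (1/day). The default 1e5
#'   gives a consumption length scale of ~0.03 mm, far thinner than any mat.
#' @param k_feS first-order FeS precipitation rate (1/day).
#' @return list with `profile` (a [porewater_profile()] carrying the noisy
#'   samples) and `truth` (list: `scenario`, `true_flux` per analyte in
#'   mmol m-2 day-1, `field` data frame of noiseless concentrations,
#'   `fit_window` recommended gradient window in mm).
#' @export
generate_profile <- function(scen, k_mat = 1e5, k_feS = 5e3) {
  stopifnot(inherits(scen, "scenario"))
  z <- seq(0, scen$max_depth_mm, by = scen$depth_step)
  n <- length(z)
  pz <- scen$production_zone
  phi <- scen$porosity

  Ds_h2s <- sediment_diffusivity(
    diffusion_coefficient("H2S", scen$salinity, scen$temperature)$D_free, phi)

  R <- ifelse(z >= pz[1] & z <= pz[2], pz[3], 0)
  k <- numeric(n)
  if (!is.null(scen$mat_layer))
    k[z >= scen$mat_layer[1] & z < scen$mat_layer[2]] <- k_mat
  if (!is.null(scen$fe_source))
    k[z >= scen$fe_source[1]] <- k[z >= scen$fe_source[1]] + k_feS

  c_bw <- if ("H2S" %in% names(scen$bottom_water_conc))
    scen$bottom_water_conc[["H2S"]] else 0
  h2s <- .solve_steady_state(z, Ds_h2s, k, R, c_bw)
  if (any(h2s < -1e-6))
    stop("solver produced negative concentrations in the noiseless field")
  h2s[h2s < 0] <- 0

  fit_top <- if (is.null(scen$mat_layer)) 0 else scen$mat_layer[2]
  fit_window <- c(fit_top, pz[1])

  # analytic flux through the top of the source-free zone; with a deep FeS
  # sink part of the production is diverted downward, so fall back to the
  # numerical gradient at that level
  true_flux_h2s <- phi * pz[3] * (pz[2] - pz[1]) * 1e-3
  if (!is.null(scen$fe_source)) {
    i <- max(which(z <= fit_top), 1)
    grad <- (h2s[i + 1] - h2s[i]) / (scen$depth_step * 1e-3) # mmol/m4
    true_flux_h2s <- phi * Ds_h2s * grad
  }

  field <- data.frame(depth_mm = z, analyte = "H2S", conc_uM = h2s,
                      stringsAsFactors = FALSE)
  true_flux <- c(H2S = true_flux_h2s)

  fe <- NULL
  if (!is.null(scen$fe_source)) {
    Ds_fe <- sediment_diffusivity(
      diffusion_coefficient("Fe", scen$salinity, scen$temperature)$D_free, phi)
    # spread the Fe source over 5 mm below its nominal depth
    src <- scen$fe_source
    in_src <- z >= src[1] & z <= src[1] + 5
    R_fe <- numeric(n)
    R_fe[in_src] <- src[2] / (phi * 5e-3) # uM/day so that phi*int(R) = flux
    # precipitation wherever sulfide persists in the noiseless field
    k_fe <- ifelse(h2s > 1, k_feS, 0)
    fe_bw <- if ("Fe" %in% names(scen$bottom_water_conc))
      scen$bottom_water_conc[["Fe"]] else 0
    fe <- .solve_steady_state(z, Ds_fe, k_fe, R_fe, fe_bw)
    fe[fe < 0] <- 0
    i0 <- 1
    grad_fe <- (fe[i0 + 1] - fe[i0]) / (scen$depth_step * 1e-3)
    true_flux <- c(true_flux, Fe = phi * Ds_fe * grad_fe)
    field <- rbind(field,
                   data.frame(depth_mm = z, analyte = "Fe", conc_uM = fe,
                              stringsAsFactors = FALSE))
  }

  set.seed(scen$seed)
  noisy <- field
  noisy$conc_uM <- pmax(noisy$conc_uM +
                          stats::rnorm(nrow(noisy), 0, scen$noise_sd), 0)
  noisy$sd_uM <- scen$noise_sd
  noisy$censored <- "ok"
  noisy$source_signal <- "forward_peak"

  prof <- porewater_profile(
    station = scen$station_label, water_depth_m = scen$water_depth_m,
    data = noisy, porosity_surface = phi, mat_layer = scen$mat_layer,
    salinity = scen$salinity, temperature = scen$temperature,
    seed = scen$seed)

  list(profile = prof,
       truth = list(scenario = scen, true_flux = true_flux, field = field,
                    fit_window = fit_window))
}

#' Generate a synthetic cyclic voltammogram
#'
#' Builds a cyclic scan (-0.1 to -1.8 V and back, 1000 mV/s) for a set of
#' true concentrations. Forward-scan peaks are Gaussian at each analyte's
#' characteristic potential; the sulfide peak drifts from -0.70 V toward
#' -0.90 V with concentration and its amplitude saturates at the 250 uM
#' equivalent. A polysulfide entry (`Sx`, molecule concentration in uM with
#' chain length `x`) produces the characteristic double peak. The backward
#' scan carries the sigmoidal total-sulfide wave, proportional to free
#' sulfide + polysulfide over 2--1200 uM. Replicate 1 carries a conditioning
#' bias (`first_scan_bias`), which is why the protocol discards it.
#'
#' @param true_conc named vector of concentrations (uM); names from
#'   `H2S`, `Fe`, `Mn`, `O2`, `FeS` (signal intensity), `Sx`.
#' @param calib a [calibration_model()].
#' @param noise_sd_nA instrument current noise (nA).
#' @param seed integer seed.
#' @param depth_mm,replicate scan metadata.
#' @param x polysulfide chain length for the `Sx` entry.
#' @param step_V potential grid step (V).
#' @param first_scan_bias relative amplitude bias applied to replicate 1.
#' @return a [voltammogram()].
#' @export
generate_voltammogram <- function(true_conc, calib = calibration_model(),
                                  noise_sd_nA = 0.1, seed = 1L,
                                  depth_mm = NA_real_, replicate = 1L,
                                  x = 5L, step_V = 0.002,
                                  first_scan_bias = 0.15) {
  centers <- c(FeS = -1.12, Fe = -1.41, Mn = -1.60, O2 = -0.30)
  unknown <- setdiff(names(true_conc), c(names(centers), "H2S", "Sx"))
  if (length(unknown))
    stop("no configured potential window for analyte(s): ",
         paste(unknown, collapse = ", "))
  missing_sens <- setdiff(setdiff(names(true_conc), "Sx"),
                          names(calib$sensitivity))
  if (length(missing_sens))
    stop("calibration lacks sensitivity for: ",
         paste(missing_sens, collapse = ", "))

  pot_f <- seq(-0.1, -1.8, by = -step_V)
  pot_b <- rev(pot_f)
  cur_f <- numeric(length(pot_f))
  cur_b <- numeric(length(pot_b))
  gain <- if (replicate == 1L) 1 + first_scan_bias else 1
  slope_s <- calib$sensitivity[["H2S"]]
  sigma <- 0.025 # peak width (V)
  gauss <- function(p, center, amp) amp * exp(-(p - center)^2 / (2 * sigma^2))

  h2s <- if ("H2S" %in% names(true_conc)) true_conc[["H2S"]] else 0
  sx <- if ("Sx" %in% names(true_conc)) true_conc[["Sx"]] else 0
  if (h2s > 0 || sx > 0) {
    if (sx > 0) {
      # double peak: free + terminal S(-II) at -0.72 V, zerovalent at -0.88 V
      cur_f <- cur_f + gauss(pot_f, -0.72, gain * slope_s *
                               min(h2s + sx, calib$forward_saturation_uM))
      cur_f <- cur_f + gauss(pot_f, -0.88, gain * slope_s *
                               min((x - 1) * sx, calib$forward_saturation_uM))
    } else {
      # peak drifts from -0.70 V toward -0.88 V with concentration
      center <- -0.70 - 0.0008 * min(h2s, 225)
      cur_f <- cur_f + gauss(pot_f, center, gain * slope_s *
                               min(h2s, calib$forward_saturation_uM))
    }
    total <- min(h2s + sx, calib$wave_range_uM[2])
    wave_h <- gain * slope_s * total
    cur_b <- cur_b + wave_h / (1 + exp(-(pot_b - (-0.75)) / 0.05))
  }
  for (an in names(centers)) {
    if (an %in% names(true_conc) && true_conc[[an]] > 0)
      cur_f <- cur_f + gauss(pot_f, centers[[an]],
                             gain * calib$sensitivity[[an]] * true_conc[[an]])
  }
  set.seed(seed)
  cur_f <- cur_f + stats::rnorm(length(cur_f), 0, noise_sd_nA)
  cur_b <- cur_b + stats::rnorm(length(cur_b), 0, noise_sd_nA)
  voltammogram(c(pot_f, pot_b), c(cur_f, cur_b),
               c(rep("forward", length(pot_f)), rep("backward", length(pot_b))),
               scan_rate_mV_s = 1000, depth_mm = depth_mm,
               replicate = replicate)
}

#' Generate a synthetic benthic chamber time series
#'
#' Concentration in the enclosed water rises (or falls) linearly at
#' `true_flux / height` plus truncated Gaussian noise. Defaults mirror the
#' lander protocol: six syringe samples over a 30 h incubation.
#'
#' @param true_flux sediment-water flux (mmol m-2 day-1, positive out).
#' @param height enclosed (sediment-free) water height (m); chamber volume
#'   divided by area.
#' @param n_samples number of samples (>= 2).
#' @param duration_h incubation length (h).
#' @param noise_sd sampling/analytical noise (uM).
#' @param seed integer seed.
#' @param start_conc initial concentration (uM).
#' @param deployment,chamber,water_depth_m metadata.
#' @param detection_limit_uM censoring threshold for the sulfide analysis.
#' @return a [chamber_incubation()].
#' @export
generate_chamber_series <- function(true_flux, height = 0.15, n_samples = 6,
                                    duration_h = 30, noise_sd = 1, seed = 1L,
                                    start_conc = 0, deployment = "SYN-1",
                                    chamber = "CH1", water_depth_m = 140,
                                    detection_limit_uM = 2) {
  if (n_samples < 2) stop("need at least 2 samples")
  if (duration_h <= 0) stop("duration must be positive")
  if (height <= 0) stop("enclosed height must be positive")
  times <- seq(0, duration_h, length.out = n_samples)
  rate_uM_day <- true_flux / height # mmol m-3 day-1 == uM/day
  set.seed(seed)
  conc <- pmax(start_conc + rate_uM_day * times / 24 +
                 stats::rnorm(n_samples, 0, noise_sd), 0)
  chamber_incubation(
    deployment = deployment, chamber = chamber,
    water_depth_m = water_depth_m, time_h = times, conc_uM = conc,
    censored = conc < detection_limit_uM, height_m = height,
    duration_h = duration_h, seed = seed)
}
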