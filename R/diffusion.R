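# Free-solution and in-sediment diffusion coefficients.
#
# Formulations follow Boudreau (1997, "Diagenetic Models and Their
# Implementation", ch. 4): dissolved gases through Stokes-Einstein-type
# viscosity correlations, ions through linear infinite-dilution temperature
# fits rescaled by the seawater/freshwater viscosity ratio.

#' Dynamic viscosity of seawater
#'
#' Millero (1974) correlation for the dynamic viscosity of seawater as a
#' function of salinity, temperature and applied pressure. Valid for roughly
#' 0--36 psu and 0--30 degC, which covers brackish basin bottom waters.
#'
#' @param salinity practical salinity (psu).
#' @param temperature temperature (degC).
#' @param pressure total pressure (atm).
#' @return dynamic viscosity in centipoise (mPa s).
#' @examples
#' seawater_viscosity(12, 10) # brackish bottom water, ~1.34 cP
#' @export
seawater_viscosity <- function(salinity = 35, temperature = 25, pressure = 1) {
  stopifnot(is.numeric(salinity), is.numeric(temperature), is.numeric(pressure))
  if (any(salinity < 0) || any(pressure <= 0))
    stop("salinity must be >= 0 and pressure > 0")
  if (any(temperature < -2) || any(temperature > 40))
    stop("temperature outside the validity range of the viscosity correlation")
  t <- temperature
  P <- pressure * 1.013253 # bar
  S <- salinity
  1.7910 - t * (6.144e-02 - t * (1.4510e-03 - t * 1.6826e-05)) -
    1.5290e-04 * P + 8.3885e-08 * P^2 + 2.4727e-03 * S +
    (6.0574e-06 * P - 2.6760e-09 * P^2) * t +
    (t * (4.8429e-05 - t * (4.7172e-06 - t * 7.5986e-08))) * S
}

# Infinite-dilution linear temperature fits for ions,
# D0 = (m0 + m1 * t) x 1e-6 cm2/s with t in degC (Boudreau 1997).
.ion_D0 <- data.frame(
  analyte = c("Fe", "Mn", "HS", "NH4", "NO3", "SO4", "Ca", "Mg"),
  m0 = c(3.31, 3.18, 10.4, 9.50, 9.50, 4.88, 3.60, 3.43),
  m1 = c(0.150, 0.155, 0.273, 0.413, 0.388, 0.232, 0.179, 0.144),
  stringsAsFactors = FALSE
)

# LeBas molar volumes at the normal boiling point (cm3/mol) for the
# Hayduk-Laudie correlation (Boudreau 1997).
.gas_Vb <- c(H2S = 35.2, CH4 = 37.7, NH3 = 24.5, N2 = 31.2, Ar = 29.2)

#' Free-solution diffusion coefficient in seawater
#'
#' Computes the diffusion coefficient of a dissolved gas or ion in
#' sediment-free seawater at ambient salinity, temperature and pressure.
#' Gases use viscosity-based correlations: O2 and CO2 the dedicated
#' linear-in-(T/mu) fits, other gases the Hayduk-Laudie relation with LeBas
#' molar volumes. Ions use linear infinite-dilution temperature fits scaled
#' by the Stokes-Einstein viscosity ratio between fresh water and seawater
#' at the same temperature.
#'
#' @param analyte one of `"O2"`, `"H2S"`, `"CO2"`, `"CH4"`, `"NH3"`, `"N2"`,
#'   `"Ar"`, `"Fe"`, `"Mn"`, `"HS"`, `"NH4"`, `"NO3"`, `"SO4"`, `"Ca"`,
#'   `"Mg"`. `"Fe"`/`"Mn"` denote the free divalent cations.
#' @param salinity practical salinity (psu).
#' @param temperature temperature (degC).
#' @param pressure total pressure (atm).
#' @return an object of class `diffusion_constants`: a list with `analyte`,
#'   `D_free` (m2/day), `salinity`, `temperature`, `pressure`.
#' @examples
#' diffusion_coefficient("H2S", salinity = 12, temperature = 10)$D_free
#' @export
diffusion_coefficient <- function(analyte, salinity = 35, temperature = 25,
                                  pressure = 1) {
  stopifnot(is.character(analyte), length(analyte) == 1)
  if (temperature < 0 || temperature > 35)
    stop("temperature outside 0-35 degC fit range")
  if (salinity < 0 || salinity > 40)
    stop("salinity outside 0-40 psu fit range")
  mu  <- seawater_viscosity(salinity, temperature, pressure)
  mu0 <- seawater_viscosity(0, temperature, 1)
  TK  <- temperature + 273.15

  if (analyte %in% c("O2", "CO2")) {
    co <- switch(analyte,
      O2  = c(0.2604, 0.006383),
      CO2 = c(0.1954, 0.005089)
    )
    D_cm2s <- (co[1] + co[2] * TK / mu) * 1e-5
  } else if (analyte %in% names(.gas_Vb)) {
    # Hayduk & Laudie (1974): D = 4.72e-9 T ... reduced form with mu in cP
    D_cm2s <- 13.26e-5 / (mu^1.14 * .gas_Vb[[analyte]]^0.589)
  } else if (analyte %in% .ion_D0$analyte) {
    row <- .ion_D0[.ion_D0$analyte == analyte, ]
    D0 <- (row$m0 + row$m1 * temperature) * 1e-6 # cm2/s, S = 0
    D_cm2s <- D0 * mu0 / mu
  } else {
    stop("no diffusion coefficient data for analyte '", analyte, "'")
  }

  structure(
    list(analyte = analyte,
         D_free = D_cm2s * 1e-4 * 86400, # m2/day
         salinity = salinity, temperature = temperature, pressure = pressure),
    class = "diffusion_constants"
  )
}

#' @export
print.diffusion_constants <- function(x, ...) {
  cat(sprintf("D(%s) = %.3e m2/day at S = %g, T = %g degC, P = %g atm\n",
              x$analyte, x$D_free, x$salinity, x$temperature, x$pressure))
  invisible(x)
}

#' Sediment diffusivity from the modified Weissberg relation
#'
#' Corrects a free-solution diffusion coefficient for the tortuosity of the
#' sediment matrix: `Ds = D / (1 - 2 ln(phi))`, with `phi` the surface
#' porosity. `Ds <= D` for all admissible porosities, with equality at
#' `phi = 1`.
#'
#' @param D_free free-solution diffusion coefficient (m2/day).
#' @param porosity surface porosity, in (0, 1].
#' @return sediment diffusion coefficient Ds (m2/day).
#' @examples
#' sediment_diffusivity(1.02e-4, 0.9)
#' @export
sediment_diffusivity <- function(D_free, porosity) {
  stopifnot(is.numeric(D_free), is.numeric(porosity))
  if (any(D_free <= 0)) stop("D_free must be positive")
  if (any(porosity <= 0) || any(porosity > 1))
    stop("porosity must be in (0, 1]")
  D_free / (1 - 2 * log(porosity))
}
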