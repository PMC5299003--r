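# Regional sulfide mass balance: upscaling station fluxes to basin-scale
# annual sulfur loads and the fraction retained by the benthic filter.

#' Mean station flux
#'
#' Arithmetic mean of station fluxes, used to represent a depth stratum
#' (e.g. the mean of the mat-station fluxes for the hypoxic transition
#' zone).
#'
#' @param fluxes numeric vector of fluxes (mmol m-2 day-1), non-empty.
#' @return mean flux (mmol m-2 day-1).
#' @examples
#' mean_station_flux(c(3.38, 2.50, 2.73)) # 2.87
#' @export
mean_station_flux <- function(fluxes) {
  if (!length(fluxes)) stop("empty flux list")
  if (!is.numeric(fluxes) || any(!is.finite(fluxes)))
    stop("fluxes must be finite numbers")
  mean(fluxes)
}

#' Annual areal sulfur load
#'
#' Converts an areal flux over a seafloor area to an annual sulfur load:
#' `flux [mmol m-2 day-1] * 1e-3 [mol/mmol] * area [km2] * 1e6 [m2/km2]
#' * days_per_year * molar_mass [g/mol] / 1e9 [g/kton]`. The default
#' constants (32 g/mol, 365 day/yr) are the conventional rounded values for
#' sulfur budgets.
#'
#' @param flux areal flux (mmol m-2 day-1), >= 0.
#' @param area_km2 seafloor area (km2), >= 0.
#' @param molar_mass_g molar mass of sulfur (g/mol).
#' @param days_per_year days per year.
#' @return load in kton S per year.
#' @examples
#' areal_load(3.14, 18954) # ~695 kton S/yr
#' @export
areal_load <- function(flux, area_km2, molar_mass_g = 32,
                       days_per_year = 365) {
  if (any(flux < 0) || any(area_km2 < 0))
    stop("flux and area must be non-negative")
  flux * 1e-3 * area_km2 * 1e6 * days_per_year * molar_mass_g / 1e9
}

#' Basin-scale benthic sulfide filter budget
#'
#' Splits the basin into the hypoxic-transition-zone (HTZ) stratum, where
#' mats retain the upward sulfide flux at the interface, and the permanently
#' anoxic stratum, where sulfide escapes to the bottom water. The retained
#' load is the HTZ flux times the HTZ area, the escaping load the anoxic
#' flux times the anoxic area, and the retained fraction their share of the
#' total.
#'
#' @param flux_htz mean HTZ (mat station) flux (mmol m-2 day-1); default the
#'   mean of the measured mat-station fluxes.
#' @param area_htz_km2 HTZ seafloor area (km2; 80--120 m water depth).
#' @param flux_anoxic deep-station flux (mmol m-2 day-1).
#' @param area_anoxic_km2 permanently anoxic seafloor area (km2; >120 m).
#' @param molar_mass_g,days_per_year conversion constants, see
#'   [areal_load()].
#' @return an object of class `regional_budget`: list with the inputs plus
#'   `load_retained`, `load_to_water`, `load_total` (kton S/yr) and
#'   `fraction_retained`.
#' @examples
#' filter_budget() # 1586 + 695 = 2281 kton S/yr, 70% retained
#' @export
filter_budget <- function(flux_htz = mean_station_flux(c(3.38, 2.50, 2.73)),
                          area_htz_km2 = 47320,
                          flux_anoxic = 3.14,
                          area_anoxic_km2 = 18954,
                          molar_mass_g = 32, days_per_year = 365) {
  if (area_htz_km2 == 0 && area_anoxic_km2 == 0)
    stop("both areas are zero: retained fraction undefined")
  load_retained <- areal_load(flux_htz, area_htz_km2, molar_mass_g,
                              days_per_year)
  load_to_water <- areal_load(flux_anoxic, area_anoxic_km2, molar_mass_g,
                              days_per_year)
  load_total <- load_retained + load_to_water
  structure(
    list(flux_htz = flux_htz, area_htz_km2 = area_htz_km2,
         flux_anoxic = flux_anoxic, area_anoxic_km2 = area_anoxic_km2,
         molar_mass_g = molar_mass_g, days_per_year = days_per_year,
         load_retained = load_retained, load_to_water = load_to_water,
         load_total = load_total,
         fraction_retained = if (load_total > 0)
           load_retained / load_total else 0),
    class = "regional_budget"
  )
}

#' Round half away from zero
#'
#' Rounding rule used when comparing computed loads with values printed at a
#' fixed number of digits (base R's `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.regional_budget <- function(x, ...) {
  cat("Benthic sulfide filter budget\n")
  cat(sprintf("  HTZ:    %.2f mmol m-2 day-1 over %g km2 -> %.0f kton S/yr retained\n",
              x$flux_htz, x$area_htz_km2, round_half_up(x$load_retained)))
  cat(sprintf("  anoxic: %.2f mmol m-2 day-1 over %g km2 -> %.0f kton S/yr to water\n",
              x$flux_anoxic, x$area_anoxic_km2, round_half_up(x$load_to_water)))
  cat(sprintf("  total:  %.0f kton S/yr; %.0f%% retained by the benthic filter\n",
              round_half_up(x$load_total),
              round_half_up(100 * x$fraction_retained)))
  invisible(x)
}
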