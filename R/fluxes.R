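# Diffusive flux estimation from porewater profiles: gradient fits, Fick's
# first law with tortuosity correction, and batch station reports.

#' Construct a porewater profile
#'
#' Depth-gridded analyte concentrations for one station. Depths are in mm,
#' positive downward with 0 at the sediment-water interface; overlying-water
#' points carry negative depths. Depths supplied in metres are converted.
#'
#' @param station station label.
#' @param water_depth_m water depth (m).
#' @param data data frame with columns `depth_mm`, `analyte`, `conc_uM` and
#'   optionally `sd_uM`, `censored` (`"ok"`/`"below_dl"`/`"saturated"`),
#'   `source_signal`.
#' @param porosity_surface surface porosity phi(0) in (0, 1]. The default
#'   0.9 is an assumption for organic-rich mud and is logged whenever used.
#' @param mat_layer optional `c(top_mm, bottom_mm)` of a bacterial mat
#'   (registration uncertainty about +/-0.5 mm).
#' @param salinity,temperature,pressure ambient conditions.
#' @param depth_unit `"mm"` (default) or `"m"` for the `depth_mm` column of
#'   `data`; metres are converted to mm on construction.
#' @param seed generator seed, recorded in outputs (synthetic data only).
#' @return an object of class `porewater_profile`.
#' @export
porewater_profile <- function(station, water_depth_m, data,
                              porosity_surface = NULL, mat_layer = NULL,
                              salinity = 12, temperature = 10, pressure = 1,
                              depth_unit = c("mm", "m"), seed = NA_integer_) {
  depth_unit <- match.arg(depth_unit)
  req <- c("depth_mm", "analyte", "conc_uM")
  if (!all(req %in% names(data)))
    stop("profile data must have columns: ", paste(req, collapse = ", "))
  if (depth_unit == "m") data$depth_mm <- data$depth_mm * 1000
  if (is.null(data$censored)) data$censored <- "ok"
  if (is.null(data$sd_uM)) data$sd_uM <- NA_real_
  if (is.null(data$source_signal)) data$source_signal <- NA_character_
  for (an in unique(data$analyte)) {
    d <- data$depth_mm[data$analyte == an]
    if (any(diff(d) <= 0)) stop("depth must be strictly increasing per analyte")
  }
  if (is.null(porosity_surface)) {
    porosity_surface <- 0.9
    message("porosity_surface not supplied; assuming 0.9 (organic-rich mud)")
  }
  if (porosity_surface <= 0 || porosity_surface > 1)
    stop("porosity must be in (0, 1]")
  structure(
    list(station = station, water_depth_m = water_depth_m,
         data = data[order(data$analyte, data$depth_mm), ],
         porosity_surface = porosity_surface, mat_layer = mat_layer,
         salinity = salinity, temperature = temperature, pressure = pressure,
         seed = seed),
    class = "porewater_profile"
  )
}

#' @export
print.porewater_profile <- function(x, ...) {
  cat(sprintf(
    "Porewater profile '%s' (%g m water depth): %d points, analytes %s\n",
    x$station, x$water_depth_m, nrow(x$data),
    paste(unique(x$data$analyte), collapse = ", ")))
  cat(sprintf("depth convention: mm, positive down, 0 = interface; phi(0) = %g\n",
              x$porosity_surface))
  invisible(x)
}

#' Fit a linear concentration gradient
#'
#' Ordinary least-squares slope of concentration against depth over a closed
#' depth window (points exactly at an endpoint are included). Censored
#' points are excluded with a warning rather than substituted, since
#' substitution biases the slope in short windows. At least three uncensored
#' points are required.
#'
#' @param profile a [porewater_profile()].
#' @param analyte analyte to fit.
#' @param depth_window `c(top_mm, bottom_mm)` closed window in mm (positive
#'   down; negative values select overlying-water points).
#' @return list with `slope` (uM/mm == mmol m-3 mm-1), `se_slope`, `n`,
#'   `depth_window`.
#' @export
fit_gradient <- function(profile, analyte, depth_window) {
  stopifnot(inherits(profile, "porewater_profile"))
  depth_window <- sort(depth_window)
  d <- profile$data[profile$data$analyte == analyte, ]
  if (nrow(d) == 0) stop("profile has no data for analyte '", analyte, "'")
  d <- d[d$depth_mm >= depth_window[1] & d$depth_mm <= depth_window[2], ]
  ncens <- sum(d$censored != "ok")
  if (ncens > 0) {
    warning(sprintf("excluding %d censored point(s) from the %s gradient fit",
                    ncens, analyte))
    d <- d[d$censored == "ok", ]
  }
  if (nrow(d) < 3)
    stop("need >= 3 uncensored points in the depth window (have ",
         nrow(d), ")")
  if (diff(range(d$depth_mm)) <= 0) stop("zero depth variance in window")
  fit <- stats::lm(conc_uM ~ depth_mm, data = d)
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]), se_slope = unname(sm[2, 2]),
       n = nrow(d), depth_window = depth_window)
}

#' Diffusive flux from a fitted gradient (Fick's first law)
#'
#' `J = phi(0) * Ds * dC/dz`, with the gradient taken on the positive-down
#' depth axis so that a concentration increasing with depth yields a
#' positive flux, i.e. directed out of the sediment (the reporting
#' convention used throughout the package). The 95% confidence interval is
#' reported as exactly +/- 2 standard errors of the slope, propagated
#' linearly.
#'
#' @param slope concentration gradient (uM/mm, positive-down axis).
#' @param se_slope standard error of the slope (uM/mm).
#' @param porosity surface porosity phi(0).
#' @param Ds sediment diffusion coefficient (m2/day), see
#'   [sediment_diffusivity()].
#' @param analyte,station,depth_window metadata carried into the estimate.
#' @return one-row data frame of class `flux_estimate` with columns
#'   `station`, `analyte`, `flux` (mmol m-2 day-1, positive out of the
#'   sediment), `two_se`, `window_top_mm`, `window_bottom_mm`, `gradient`
#'   (uM/mm), `Ds`, `sign_convention`.
#' @examples
#' # sulfide rising 0 -> 200 uM over 0-5 mm
#' diffusive_flux(40, 0, porosity = 0.9, Ds = 8.43e-5)
#' @export
diffusive_flux <- function(slope, se_slope, porosity, Ds,
                           analyte = NA_character_, station = NA_character_,
                           depth_window = c(NA_real_, NA_real_)) {
  stopifnot(is.finite(slope), is.finite(se_slope), se_slope >= 0)
  if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]")
  if (Ds <= 0) stop("Ds must be positive")
  # uM/mm -> mmol m-4 requires *1000; J then in mmol m-2 day-1
  flux <- porosity * Ds * slope * 1000
  out <- data.frame(
    station = station, analyte = analyte, flux = flux,
    two_se = 2 * porosity * Ds * se_slope * 1000,
    window_top_mm = depth_window[1], window_bottom_mm = depth_window[2],
    gradient = slope, Ds = Ds,
    sign_convention = "positive = out of sediment",
    stringsAsFactors = FALSE)
  class(out) <- c("flux_estimate", "data.frame")
  out
}

#' Batch diffusive-flux report for a set of profiles
#'
#' One flux per (station, analyte, window). Windows default to the 0--5 mm
#' surface interval and can be overridden per station and analyte through
#' `config$windows[[station]][[analyte]]`, which may be a single window or a
#' list of windows (deeper intervals are used for, e.g., sulfide consumption
#' below a subsurface maximum).
#'
#' @param profiles list of [porewater_profile()]s.
#' @param config optional list: `windows` (station -> analyte -> window(s)),
#'   `default_window` (default `c(0, 5)`).
#' @return data frame of class `flux_estimate`, one row per fit, sorted by
#'   station then analyte; zero rows for an empty input.
#' @export
station_flux_report <- function(profiles, config = list()) {
  default_window <- config$default_window
  if (is.null(default_window)) default_window <- c(0, 5)
  rows <- list()
  for (p in profiles) {
    stopifnot(inherits(p, "porewater_profile"))
    for (an in unique(p$data$analyte)) {
      wins <- config$windows[[p$station]][[an]]
      if (is.null(wins)) wins <- list(default_window)
      if (!is.list(wins)) wins <- list(wins)
      for (w in wins) {
        g <- fit_gradient(p, an, w)
        D <- diffusion_coefficient(an, p$salinity, p$temperature, p$pressure)
        Ds <- sediment_diffusivity(D$D_free, p$porosity_surface)
        rows[[length(rows) + 1]] <- diffusive_flux(
          g$slope, g$se_slope, p$porosity_surface, Ds, analyte = an,
          station = p$station, depth_window = g$depth_window)
      }
    }
  }
  if (!length(rows)) {
    out <- diffusive_flux(0, 0, 0.9, 1e-4)[0, ]
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$station, out$analyte), ]
    rownames(out) <- NULL
  }
  class(out) <- c("flux_estimate", "data.frame")
  out
}
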