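# Benthic chamber incubations: total sulfide flux from the slope of the
# time-concentration series and the enclosed sediment-free water height.

#' Construct a benthic chamber incubation
#'
#' Time series of total dissolved sulfide in the enclosed water of a benthic
#' lander chamber. The standard chamber has an internal diameter of 28.8 cm
#' (area 651.4 cm2); the enclosed height is the measured sediment-free
#' volume divided by that area and must be supplied per deployment.
#'
#' @param deployment deployment label.
#' @param chamber chamber label within the deployment (e.g. `"CH1"`).
#' @param water_depth_m water depth (m).
#' @param time_h sampling times (h), strictly increasing.
#' @param conc_uM concentrations (uM).
#' @param censored logical (or `"bdl"`-style flags): sample below the
#'   analytical detection limit.
#' @param area_m2 chamber area (m2).
#' @param height_m enclosed water height (m).
#' @param duration_h incubation duration (h); defaults to the last sample
#'   time.
#' @param seed generator seed (synthetic series only).
#' @return an object of class `chamber_incubation`.
#' @export
chamber_incubation <- function(deployment, chamber = "CH1",
                               water_depth_m = NA_real_, time_h, conc_uM,
                               censored = FALSE, area_m2 = 651.4e-4,
                               height_m, duration_h = max(time_h),
                               seed = NA_integer_) {
  n <- length(time_h)
  stopifnot(length(conc_uM) == n, n >= 2)
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (area_m2 <= 0) stop("chamber area must be positive")
  if (height_m <= 0) stop("enclosed height must be positive")
  if (is.character(censored)) censored <- censored %in% c("bdl", "below_dl")
  censored <- rep_len(as.logical(censored), n)
  structure(
    list(deployment = deployment, chamber = chamber,
         water_depth_m = water_depth_m,
         data = data.frame(time_h = time_h, conc_uM = conc_uM,
                           censored = censored),
         area_m2 = area_m2, height_m = height_m, duration_h = duration_h,
         seed = seed),
    class = "chamber_incubation"
  )
}

#' @export
print.chamber_incubation <- function(x, ...) {
  cat(sprintf("Chamber incubation %s/%s (%g m): %d samples over %g h\n",
              x$deployment, x$chamber, x$water_depth_m, nrow(x$data),
              x$duration_h))
  invisible(x)
}

#' Total sulfide flux from a chamber incubation
#'
#' OLS slope of concentration against time, converted with the enclosed
#' water height: `flux = slope (mmol m-3 day-1) * height (m)`. The result
#' is reported as below detection (`bdl`) when every sample is censored, or
#' when (with at least four quantified samples) the slope is not
#' distinguishable from zero in a two-sided t-test at `alpha`.
#'
#' @param inc a [chamber_incubation()].
#' @param alpha significance level for the slope test.
#' @return one-row data frame of class `chamber_flux_estimate` with columns
#'   `deployment`, `chamber`, `water_depth_m`, `duration_h`, `flux`
#'   (mmol m-2 day-1, positive out of the sediment; `NA` when bdl),
#'   `two_se`, `bdl`, `p_value`, `n`.
#' @export
chamber_flux <- function(inc, alpha = 0.05) {
  stopifnot(inherits(inc, "chamber_incubation"))
  d <- inc$data[!inc$data$censored, ]
  all_bdl <- nrow(d) == 0
  if (!all_bdl && nrow(d) < 2) stop("fewer than 2 quantified samples")
  flux <- NA_real_; two_se <- NA_real_; pval <- NA_real_; bdl <- all_bdl
  if (!all_bdl) {
    fit <- stats::lm(conc_uM ~ time_h, data = d)
    sm <- summary(fit)$coefficients
    slope_h <- unname(stats::coef(fit)[2]) # uM/h == mmol m-3 h-1
    se_h <- unname(sm[2, 2])
    flux <- slope_h * 24 * inc$height_m
    two_se <- 2 * se_h * 24 * inc$height_m
    pval <- if (nrow(d) >= 3) unname(sm[2, 4]) else NA_real_
    if (nrow(d) >= 4 && is.finite(pval) && pval > alpha) {
      bdl <- TRUE
      flux <- NA_real_
      two_se <- NA_real_
    }
  }
  out <- data.frame(
    deployment = inc$deployment, chamber = inc$chamber,
    water_depth_m = inc$water_depth_m, duration_h = inc$duration_h,
    flux = flux, two_se = two_se, bdl = bdl, p_value = pval,
    n = sum(!inc$data$censored), stringsAsFactors = FALSE)
  class(out) <- c("chamber_flux_estimate", "data.frame")
  out
}

#' Deployment-level chamber flux table
#'
#' One row per chamber, paired chambers grouped under their deployment
#' (sorted by deployment, then chamber label).
#'
#' @param incubations list of [chamber_incubation()]s.
#' @param alpha significance level passed to [chamber_flux()].
#' @return data frame as in [chamber_flux()]; zero rows for empty input.
#' @export
deployment_report <- function(incubations, alpha = 0.05) {
  if (!length(incubations)) {
    out <- chamber_flux(chamber_incubation(
      "x", time_h = c(0, 1), conc_uM = c(0, 0), height_m = 0.1))[0, ]
    return(out)
  }
  out <- do.call(rbind, lapply(incubations, chamber_flux, alpha = alpha))
  out <- out[order(out$deployment, out$chamber), ]
  rownames(out) <- NULL
  out
}
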