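# Processing of cyclic voltammograms from Au/Hg microelectrodes: peak
# detection, backward-wave measurement, standard-addition calibration,
# pilot-ion rescaling, replicate averaging and polysulfide speciation.

#' Construct a voltammogram object
#'
#' A cyclic scan from -0.1 V to -1.8 V and back. The forward segment sweeps
#' toward negative potentials; the backward segment returns. Potentials must
#' be strictly monotone within each segment.
#'
#' @param potential_V potentials (V), forward points first.
#' @param current_nA currents (nA), same length.
#' @param segment `"forward"`/`"backward"` per point.
#' @param scan_rate_mV_s scan rate (mV/s); the field protocol uses 1000.
#' @param depth_mm measurement depth (mm, positive down, 0 = sediment-water
#'   interface; overlying-water points are negative).
#' @param replicate replicate index at this depth (1-based; replicate 1 is
#'   conventionally discarded).
#' @param conditioning conditioning step, `c(potential_V, seconds)`.
#' @return an object of class `vgram` (a data frame with scan metadata
#'   attributes).
#' @export
voltammogram <- function(potential_V, current_nA, segment,
                         scan_rate_mV_s = 1000, depth_mm = NA_real_,
                         replicate = 1L, conditioning = c(-0.9, 10)) {
  n <- length(potential_V)
  stopifnot(length(current_nA) == n, length(segment) == n, n > 3)
  if (!all(segment %in% c("forward", "backward")))
    stop("segment must be 'forward' or 'backward'")
  if (scan_rate_mV_s <= 0) stop("scan_rate must be positive")
  for (seg in unique(segment)) {
    dp <- diff(potential_V[segment == seg])
    if (!(all(dp > 0) || all(dp < 0)))
      stop("potential not strictly monotone within segment '", seg, "'")
  }
  structure(
    data.frame(potential_V = potential_V, current_nA = current_nA,
               segment = segment, stringsAsFactors = FALSE),
    scan_rate_mV_s = scan_rate_mV_s, depth_mm = depth_mm,
    replicate = as.integer(replicate), conditioning = conditioning,
    class = c("vgram", "data.frame")
  )
}

#' Default potential windows for peak detection
#'
#' Sulfide spans -0.95 to -0.60 V because the HS-/H2S peak near -0.7 V
#' shifts toward -0.9 V with increasing concentration; FeS(aq) appears near
#' -1.1 V; Fe2+ and Mn2+ at more negative potentials; O2 as a reduction
#' signal near -0.3 V.
#'
#' @return named list of `c(V_min, V_max)` windows.
#' @export
default_windows <- function() {
  list(
    H2S = c(-0.95, -0.60),
    FeS = c(-1.20, -1.05),
    Fe  = c(-1.50, -1.32),
    Mn  = c(-1.68, -1.52),
    O2  = c(-0.45, -0.18)
  )
}

#' Default calibration for the voltammetric cell
#'
#' Sensitivities in nA/uM with detection limits of 20 uM (O2), 10 uM (Mn2+
#' and Fe2+), 0.2 uM (H2S forward peak) and 2 uM for the total-sulfide
#' backward wave (quantification range 2--1200 uM). Mn2+ is the pilot ion
#' used to rescale the full calibration between casts. FeS(aq) cannot be
#' calibrated for lack of standards and carries a nominal unit sensitivity:
#' its "concentrations" are signal intensities (nA).
#'
#' @param sensitivity named numeric vector of sensitivities (nA/uM).
#' @param detection_limit named numeric vector of detection limits (uM).
#' @param pilot_analyte analyte used as pilot ion.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(
    sensitivity = c(H2S = 1.0, O2 = 0.8, Fe = 1.2, Mn = 1.5, FeS = 1.0),
    detection_limit = c(H2S = 0.2, O2 = 20, Fe = 10, Mn = 10, FeS = NA),
    pilot_analyte = "Mn") {
  if (any(sensitivity <= 0, na.rm = TRUE)) stop("sensitivities must be > 0")
  if (!pilot_analyte %in% names(sensitivity))
    stop("pilot analyte has no sensitivity entry")
  structure(
    list(sensitivity = sensitivity, detection_limit = detection_limit,
         pilot_analyte = pilot_analyte,
         pilot_reference_sensitivity = unname(sensitivity[pilot_analyte]),
         wave_range_uM = c(2, 1200), forward_saturation_uM = 250),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Voltammetric calibration (pilot ion:", x$pilot_analyte, ")\n")
  print(data.frame(sensitivity_nA_uM = x$sensitivity,
                   detection_limit_uM = x$detection_limit[names(x$sensitivity)]))
  invisible(x)
}

# Interpolate the linear baseline drawn between the currents at the window
# edges and return the baseline-corrected currents for the forward segment
# restricted to the window.
.window_baseline <- function(fwd, window) {
  idx <- which(fwd$potential_V >= window[1] & fwd$potential_V <= window[2])
  if (length(idx) < 5) stop("potential window outside the scanned range")
  pot <- fwd$potential_V[idx]
  cur <- fwd$current_nA[idx]
  # anchor on the mean of the 3 outermost points at each edge
  k <- seq_len(min(3, length(idx)))
  e1 <- c(mean(pot[k]), mean(cur[k]))
  e2 <- c(mean(rev(pot)[k]), mean(rev(cur)[k]))
  base <- e1[2] + (pot - e1[1]) * (e2[2] - e1[2]) / (e2[1] - e1[1])
  list(potential = pot, corrected = cur - base)
}

#' Detect peaks in the forward scan
#'
#' Local maxima above a linear baseline drawn between the edges of each
#' analyte's potential window. Within the sulfide window up to two peaks are
#' reported (a resolved double peak flags a polysulfide candidate); maxima
#' separated by less than `min_separation_V` are treated as a single peak
#' and the taller one is kept, and secondary maxima below 10% of the tallest
#' peak in a window are treated as flanks of that peak rather than peaks.
#'
#' @param scan a [voltammogram()].
#' @param windows named list of `c(V_min, V_max)` windows
#'   (default [default_windows()]).
#' @param min_height minimum baseline-corrected height (nA) for a peak.
#' @param min_separation_V minimum separation between two reported maxima in
#'   the same window.
#' @return data frame of class `peak_signal` with columns `analyte`,
#'   `peak_potential`, `height`, `baseline_method`; zero rows if nothing is
#'   detected. Peaks are ordered by potential (most negative first).
#' @export
detect_peaks <- function(scan, windows = default_windows(),
                         min_height = 0.5, min_separation_V = 0.05) {
  stopifnot(inherits(scan, "vgram"))
  fwd <- scan[scan$segment == "forward", ]
  if (nrow(fwd) == 0) stop("scan has no forward segment")
  out <- list()
  for (an in names(windows)) {
    wb <- .window_baseline(fwd, sort(windows[[an]]))
    y <- wb$corrected
    n <- length(y)
    loc <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-(1:2)]) + 1
    loc <- loc[y[loc] >= min_height]
    if (!length(loc)) next
    loc <- loc[order(y[loc], decreasing = TRUE)]
    # secondary maxima below 10% of the tallest are flanks/noise, not peaks
    loc <- loc[y[loc] >= 0.10 * y[loc[1]]]
    keep <- integer(0)
    nmax <- if (an == "H2S") 2L else 1L
    for (i in loc) {
      if (length(keep) >= nmax) break
      if (all(abs(wb$potential[i] - wb$potential[keep]) >= min_separation_V))
        keep <- c(keep, i)
    }
    keep <- keep[order(wb$potential[keep])]
    out[[an]] <- data.frame(
      analyte = an, peak_potential = wb$potential[keep],
      height = y[keep], baseline_method = "linear_window_edges",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(analyte = character(0), peak_potential = numeric(0),
               height = numeric(0), baseline_method = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("peak_signal", "data.frame")
  res
}

#' Measure the total-sulfide backward wave
#'
#' Dissolved sulfide species (HS-, H2S, polysulfides, labile metal
#' sulfides) produce a single sigmoidal wave on the backward scan whose
#' height is proportional to total dissolved sulfide over 2--1200 uM. The
#' height is measured as plateau minus baseline: the median current at the
#' shallow-potential end of the return sweep (beyond `plateau_V`) minus the
#' median at the deep end (below `baseline_V`).
#'
#' @param scan a [voltammogram()].
#' @param baseline_V potentials more negative than this define the
#'   pre-wave baseline.
#' @param plateau_V potentials more positive than this define the plateau.
#' @return wave height (nA), floored at 0.
#' @export
measure_backward_wave <- function(scan, baseline_V = -1.4, plateau_V = -0.45) {
  stopifnot(inherits(scan, "vgram"))
  bwd <- scan[scan$segment == "backward", ]
  if (nrow(bwd) == 0) stop("scan has no backward segment")
  base <- stats::median(bwd$current_nA[bwd$potential_V <= baseline_V])
  plat <- stats::median(bwd$current_nA[bwd$potential_V >= plateau_V])
  if (is.na(base) || is.na(plat))
    stop("backward segment does not span the baseline/plateau regions")
  max(plat - base, 0)
}

#' Calibrate an analyte by standard additions
#'
#' Ordinary least-squares line (with intercept) through standard-addition
#' points; the slope is the sensitivity. At least three additions spanning a
#' non-zero concentration range are required and the fitted slope must be
#' positive.
#'
#' @param additions data frame or 2-column matrix with concentration (uM)
#'   and signal (nA), or a list of `c(conc, signal)` pairs.
#' @param analyte analyte label (metadata only).
#' @return list with `analyte`, `sensitivity` (nA/uM), `se` (standard error
#'   of the slope), `n`.
#' @examples
#' calibrate_standard_additions(cbind(c(0, 50, 100), c(0, 100, 200)), "H2S")
#' @export
calibrate_standard_additions <- function(additions, analyte = "H2S") {
  if (is.list(additions) && !is.data.frame(additions))
    additions <- do.call(rbind, additions)
  additions <- as.data.frame(additions)
  if (ncol(additions) < 2) stop("additions need (conc, signal) columns")
  conc <- additions[[1]]; sig <- additions[[2]]
  if (length(conc) < 3) stop("need at least 3 standard additions")
  if (diff(range(conc)) <= 0) stop("additions must span a non-zero range")
  fit <- stats::lm(sig ~ conc)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope for ", analyte)
  se <- summary(fit)$coefficients[2, 2]
  list(analyte = analyte, sensitivity = slope, se = unname(se),
       n = length(conc))
}

#' Rescale a calibration with a fresh pilot-ion sensitivity
#'
#' The cell is fully calibrated once; later casts measure only the pilot ion
#' (Mn2+) and rescale every sensitivity by the ratio of the new pilot
#' sensitivity to the reference one.
#'
#' @param calib a [calibration_model()].
#' @param new_pilot_sensitivity freshly measured pilot sensitivity (nA/uM).
#' @return a rescaled `calibration_model`.
#' @export
pilot_ion_rescale <- function(calib, new_pilot_sensitivity) {
  stopifnot(inherits(calib, "calibration_model"))
  if (!is.numeric(new_pilot_sensitivity) || new_pilot_sensitivity <= 0)
    stop("new pilot sensitivity must be positive")
  if (calib$pilot_reference_sensitivity <= 0)
    stop("calibration has no positive pilot reference sensitivity")
  r <- new_pilot_sensitivity / calib$pilot_reference_sensitivity
  calib$sensitivity <- calib$sensitivity * r
  calib$pilot_reference_sensitivity <- new_pilot_sensitivity
  calib
}

# Signal (nA) for one analyte from one scan: tallest forward peak in the
# analyte window, or the backward wave for total sulfide.
.scan_signal <- function(scan, analyte, windows, source) {
  if (source == "backward_wave") return(measure_backward_wave(scan))
  pk <- detect_peaks(scan, windows[analyte])
  if (nrow(pk) == 0) 0 else max(pk$height)
}

#' Replicate scans to a calibrated concentration
#'
#' Implements the field protocol: four (or more) scans are taken at each
#' depth, the first is discarded (electrode conditioning), and the rest are
#' averaged. Signals are converted to uM with the analyte sensitivity. Means
#' below the detection limit are reported at the DL and flagged
#' `below_dl`. For sulfide the forward peak is used below the 250 uM
#' saturation point; at or above it (with a 5% guard band, since a saturated
#' peak reads at or slightly below the ceiling after baseline correction)
#' the backward wave takes over and the result is flagged `saturated` on the
#' forward channel. A replicate relative SD above
#' 5% sets a QC flag but does not reject the value.
#'
#' @param scans list of [voltammogram()]s from one depth (>= 4).
#' @param calib a [calibration_model()].
#' @param analyte analyte to quantify.
#' @param windows potential windows (default [default_windows()]).
#' @return one-row data frame of class `analyte_concentration` with columns
#'   `analyte`, `value` (uM), `sd` (uM), `censored`
#'   (`"ok"`/`"below_dl"`/`"saturated"`), `source_signal`, `n_replicates`,
#'   `qc_high_sd`.
#' @export
replicates_to_concentration <- function(scans, calib, analyte,
                                        windows = default_windows()) {
  stopifnot(inherits(calib, "calibration_model"))
  if (length(scans) < 4)
    stop("need >= 4 scans per depth (first is discarded)")
  if (!analyte %in% names(calib$sensitivity))
    stop("no sensitivity for analyte '", analyte, "'")
  use <- scans[-1]
  if (length(use) < 2) stop("fewer than 2 usable replicates")
  slope <- calib$sensitivity[[analyte]]
  dl <- calib$detection_limit[[analyte]]

  fwd_uM <- vapply(use, .scan_signal, 0, analyte, windows, "forward_peak") / slope
  source <- "forward_peak"
  vals <- fwd_uM
  censored <- "ok"
  if (analyte == "H2S") {
    # a saturated forward channel reads at (or, after baseline correction,
    # slightly below) the ceiling, so the switch carries a 5% guard band
    if (mean(fwd_uM) >= 0.95 * calib$forward_saturation_uM) {
      vals <- vapply(use, .scan_signal, 0, analyte, windows, "backward_wave") /
        slope
      source <- "backward_wave"
      censored <- "saturated"
    }
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  if (!is.na(dl) && m < dl) {
    censored <- "below_dl"
    m <- dl
  }
  out <- data.frame(
    analyte = analyte, value = m, sd = s, censored = censored,
    source_signal = source, n_replicates = length(use),
    qc_high_sd = is.finite(s) && m > 0 && censored == "ok" && s / m > 0.05,
    stringsAsFactors = FALSE)
  class(out) <- c("analyte_concentration", "data.frame")
  out
}

#' Polysulfide speciation from the double sulfide peak
#'
#' At fast scan rates a polysulfide molecule S_x^2- splits the forward
#' sulfide signal into two peaks: the more negative peak measures the
#' (x-1) zerovalent sulfur atoms per molecule, the more positive peak the
#' free sulfide plus the terminal S(-II). Both peaks are quantified with the
#' free-sulfide calibration slope; the backward wave provides total
#' dissolved sulfide.
#'
#' @param peak_negative height (nA) of the more negative peak.
#' @param peak_positive height (nA) of the more positive peak.
#' @param wave_total_uM total dissolved sulfide from the backward wave (uM).
#' @param calib a [calibration_model()].
#' @param x assumed polysulfide chain length (default 5, the dominant chain
#'   at porewater pH 7--8).
#' @return list of class `polysulfide_speciation` with `chain_length_x`,
#'   `zerovalent_conc`, `polysulfide_conc`, `free_sulfide`, `total_sulfide`
#'   (all uM) and `fraction_of_total`.
#' @examples
#' cal <- calibration_model()
#' speciate_polysulfide(48, 60, 85.7, cal) # ~12 uM S5^2-, 14% of total
#' @export
speciate_polysulfide <- function(peak_negative, peak_positive, wave_total_uM,
                                 calib, x = 5L) {
  stopifnot(inherits(calib, "calibration_model"))
  if (x < 2) stop("chain length x must be >= 2")
  if (peak_negative < 0 || peak_positive < 0 || wave_total_uM < 0)
    stop("signals must be non-negative")
  slope <- calib$sensitivity[["H2S"]]
  zerovalent <- peak_negative / slope
  poly <- zerovalent / (x - 1)
  free <- max(peak_positive / slope - poly, 0)
  fraction <- if (wave_total_uM > 0) poly / wave_total_uM else 0
  if (fraction > 1 + 1e-9)
    stop(sprintf(
      "inconsistent signals: polysulfide (%.3g uM) exceeds total sulfide (%.3g uM)",
      poly, wave_total_uM))
  structure(
    list(chain_length_x = as.integer(x), zerovalent_conc = zerovalent,
         polysulfide_conc = poly, free_sulfide = free,
         total_sulfide = wave_total_uM, fraction_of_total = fraction),
    class = "polysulfide_speciation"
  )
}

#' @export
print.polysulfide_speciation <- function(x, ...) {
  cat(sprintf(
    "S%d^2-: %.3g uM (%.1f%% of total sulfide %.3g uM); free sulfide %.3g uM\n",
    x$chain_length_x, x$polysulfide_conc, 100 * x$fraction_of_total,
    x$total_sulfide, x$free_sulfide))
  invisible(x)
}
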