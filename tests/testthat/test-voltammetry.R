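# Peak detection, wave measurement, calibration and speciation.

make_scan <- function(peaks = list(), wave = 0, noise = 0, seed = 1,
                      step = 0.002) {
  pot_f <- seq(-0.1, -1.8, by = -step)
  pot_b <- rev(pot_f)
  cur_f <- numeric(length(pot_f))
  for (p in peaks)
    cur_f <- cur_f + p$amp * exp(-(pot_f - p$center)^2 / (2 * 0.025^2))
  cur_b <- wave / (1 + exp(-(pot_b + 0.75) / 0.05))
  set.seed(seed)
  cur_f <- cur_f + rnorm(length(cur_f), 0, noise)
  cur_b <- cur_b + rnorm(length(cur_b), 0, noise)
  voltammogram(c(pot_f, pot_b), c(cur_f, cur_b),
               rep(c("forward", "backward"), each = length(pot_f)))
}

test_that("detect_peaks finds constructed peaks and ignores flat traces", {
  expect_equal(nrow(detect_peaks(make_scan(noise = 0.1))), 0)

  one <- detect_peaks(make_scan(list(list(center = -0.75, amp = 50)),
                                noise = 0.1))
  expect_equal(nrow(one), 1)
  expect_equal(one$height, 50, tolerance = 0.02)
  expect_equal(one$peak_potential, -0.75, tolerance = 0.003)

  two <- detect_peaks(make_scan(list(list(center = -0.72, amp = 85),
                                     list(center = -0.88, amp = 48)),
                                noise = 0.1))
  two <- two[two$analyte == "H2S", ]
  expect_equal(nrow(two), 2)
  # returned in potential order, most negative first
  expect_equal(two$peak_potential, c(-0.88, -0.72), tolerance = 0.003)
  expect_equal(two$height, c(48, 85), tolerance = 0.03)

  expect_error(detect_peaks(make_scan(), windows = list(H2S = c(0.5, 0.9))),
               "window")
})

test_that("shoulders closer than the separation limit merge into one peak", {
  sh <- detect_peaks(make_scan(list(list(center = -0.75, amp = 80),
                                    list(center = -0.78, amp = 60))))
  sh <- sh[sh$analyte == "H2S", ]
  expect_equal(nrow(sh), 1)
})

test_that("backward wave height is plateau minus baseline", {
  expect_equal(measure_backward_wave(make_scan(wave = 0)), 0)
  expect_equal(measure_backward_wave(make_scan(wave = 120, noise = 0.1)),
               120, tolerance = 0.01)
  fwd_only <- make_scan()
  expect_error(
    measure_backward_wave(fwd_only[fwd_only$segment == "forward", ]),
    "backward")
})

test_that("standard additions give the OLS slope, with a positive-slope guard", {
  exact <- calibrate_standard_additions(cbind(c(0, 50, 100), c(0, 100, 200)))
  expect_equal(exact$sensitivity, 2.0)

  noisy <- calibrate_standard_additions(cbind(c(0, 50, 100), c(1, 99, 201)))
  orc <- ols_oracle(c(0, 50, 100), c(1, 99, 201))
  expect_equal(noisy$sensitivity, orc$slope, tolerance = 1e-12)
  expect_equal(noisy$se, orc$se, tolerance = 1e-12)

  expect_error(
    calibrate_standard_additions(cbind(c(0, 50, 100), c(5, 5, 5))),
    "slope")
  expect_error(calibrate_standard_additions(cbind(c(0, 50), c(0, 100))),
               "at least 3")
  # linearity: doubling all signals doubles the sensitivity exactly
  base <- calibrate_standard_additions(cbind(c(0, 40, 80), c(2, 81, 162)))
  dbl <- calibrate_standard_additions(cbind(c(0, 40, 80), 2 * c(2, 81, 162)))
  expect_identical(dbl$sensitivity, 2 * base$sensitivity)
})

test_that("pilot-ion rescaling multiplies every sensitivity by the ratio", {
  cal <- calibration_model(sensitivity = c(H2S = 1.5, Mn = 2.0, Fe = 1.0),
                           detection_limit = c(H2S = 0.2, Mn = 10, Fe = 10))
  same <- pilot_ion_rescale(cal, 2.0)
  expect_equal(same$sensitivity, cal$sensitivity)
  down <- pilot_ion_rescale(cal, 1.6) # 0.8 x reference
  expect_equal(unname(down$sensitivity), unname(0.8 * cal$sensitivity))
  expect_equal(pilot_ion_rescale(cal, 1.0)$sensitivity[["H2S"]], 0.75)
  expect_error(pilot_ion_rescale(cal, 0), "positive")
})

test_that("replicates are averaged after discarding the first scan", {
  cal <- calibration_model()
  concs <- c(130, 99, 100, 101) # first scan deliberately off
  scans <- lapply(seq_along(concs), function(i)
    generate_voltammogram(c(H2S = concs[i]), cal, noise_sd_nA = 0,
                          replicate = i, first_scan_bias = 0))
  res <- replicates_to_concentration(scans, cal, "H2S")
  expect_equal(res$value, 100, tolerance = 0.005)
  expect_equal(res$sd, 1, tolerance = 0.05)
  expect_identical(res$censored, "ok")
  expect_identical(res$source_signal, "forward_peak")
  expect_false(res$qc_high_sd)
  expect_error(replicates_to_concentration(scans[1:3], cal, "H2S"), ">= 4")
})

test_that("sub-detection-limit sulfide is censored at the DL", {
  cal <- calibration_model()
  scans <- replicate_scans(c(H2S = 0.1), cal, noise_sd_nA = 0.02, seed = 40)
  res <- replicates_to_concentration(scans, cal, "H2S")
  expect_identical(res$censored, "below_dl")
  expect_identical(res$value, 0.2)
})

test_that("saturated forward sulfide switches to the backward wave", {
  cal <- calibration_model()
  scans <- replicate_scans(c(H2S = 300), cal, seed = 50)
  res <- replicates_to_concentration(scans, cal, "H2S")
  expect_identical(res$source_signal, "backward_wave")
  expect_identical(res$censored, "saturated")
  expect_equal(res$value, 300, tolerance = 0.02)
  # saturation ordering: the wave sees more than the clipped forward peak
  one <- generate_voltammogram(c(H2S = 600), cal, noise_sd_nA = 0,
                               replicate = 2)
  fwd <- max(detect_peaks(one)$height)
  expect_gt(measure_backward_wave(one), fwd)
})

test_that("round trip through scan generation recovers concentrations", {
  cal <- calibration_model()
  noise_nA <- 0.1
  for (conc in c(5, 50, 150)) {
    scans <- replicate_scans(c(H2S = conc), cal, noise_sd_nA = noise_nA,
                             seed = conc)
    res <- replicates_to_concentration(scans, cal, "H2S")
    expect_lt(abs(res$value - conc), 3 * noise_nA / cal$sensitivity[["H2S"]]
              + 0.01 * conc) # 3 sigma plus baseline-grid tolerance
    expect_identical(res$censored, "ok")
  }
  # a non-sulfide analyte goes through its own window
  scans <- replicate_scans(c(Fe = 60), cal, seed = 9)
  res <- replicates_to_concentration(scans, cal, "Fe")
  expect_equal(res$value, 60, tolerance = 0.02)
})

test_that("no uncensored value is emitted below its detection limit", {
  cal <- calibration_model()
  set.seed(11)
  for (conc in runif(6, 0, 3)) {
    res <- replicates_to_concentration(
      replicate_scans(c(H2S = conc), cal, seed = round(conc * 100)),
      cal, "H2S")
    if (res$censored == "ok") expect_gte(res$value, 0.2)
  }
})

test_that("polysulfide speciation follows the (x-1) zerovalent rule", {
  cal <- calibration_model() # H2S slope 1 nA/uM
  sp <- speciate_polysulfide(48, 60, 85.7, cal, x = 5)
  expect_equal(sp$zerovalent_conc, 48)
  expect_equal(sp$polysulfide_conc, 12)
  expect_equal(sp$fraction_of_total, 0.14, tolerance = 1e-3)
  expect_equal(sp$free_sulfide, 48) # 60 - 12

  # no negative peak -> no polysulfide, all free sulfide
  none <- speciate_polysulfide(0, 60, 85.7, cal)
  expect_identical(none$polysulfide_conc, 0)
  expect_equal(none$free_sulfide, 60)

  # x = 2: one zerovalent atom per molecule
  x2 <- speciate_polysulfide(48, 60, 85.7, cal, x = 2)
  expect_identical(x2$zerovalent_conc, x2$polysulfide_conc)

  expect_error(speciate_polysulfide(480, 60, 85.7, cal), "inconsistent")
})

test_that("speciation conserves sulfide on synthetic double-peak scans", {
  cal <- calibration_model()
  for (seed in 1:5) {
    set.seed(seed)
    poly <- runif(1, 4, 20)
    free <- runif(1, 30, 120)
    scan <- generate_voltammogram(c(H2S = free, Sx = poly), cal,
                                  noise_sd_nA = 0.1, seed = seed,
                                  replicate = 2)
    pk <- detect_peaks(scan)
    pk <- pk[pk$analyte == "H2S", ]
    expect_equal(nrow(pk), 2)
    total <- measure_backward_wave(scan) / cal$sensitivity[["H2S"]]
    sp <- speciate_polysulfide(pk$height[1], pk$height[2], total, cal)
    expect_lte(sp$free_sulfide + sp$polysulfide_conc, total + 2)
    expect_equal(sp$polysulfide_conc, poly, tolerance = 0.05)
  }
})
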