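# Steady-state generator: solver correctness, conservation, ground truth.

test_that("zero production with no mat gives a uniform profile and zero flux", {
  sc <- scenario(bottom_water_conc = c(H2S = 100),
                 production_zone = c(5, 40, 0), mat_layer = NULL,
                 noise_sd = 0, seed = 1)
  gp <- generate_profile(sc)
  expect_true(all(abs(gp$truth$field$conc_uM - 100) < 1e-9))
  expect_equal(unname(gp$truth$true_flux["H2S"]), 0)
})

test_that("mat scenario produces a linear gradient whose flux matches truth", {
  sc <- scenario(production_zone = c(5, 40, 75), mat_layer = c(0, 1),
                 noise_sd = 2, seed = 3)
  gp <- generate_profile(sc)
  fld <- gp$truth$field
  # total consumption: concentration ~0 at the mat top
  expect_lt(fld$conc_uM[fld$depth_mm == 0][1], 0.1)
  # linearity between mat base and production top
  lin <- fld[fld$depth_mm >= 1 & fld$depth_mm <= 5, ]
  fit <- lm(conc_uM ~ depth_mm, data = lin)
  expect_lt(summary(fit)$sigma / max(lin$conc_uM), 1e-3)
  # noisy-profile recovery within 5% at noise_sd = 2 uM
  rec <- recover_flux(gp)
  expect_lt(abs(rec / gp$truth$true_flux["H2S"] - 1), 0.05)
})

test_that("the mat consumes exactly the flux it receives (budget closure)", {
  sc <- scenario(production_zone = c(5, 40, 75), mat_layer = c(0, 1),
                 noise_sd = 0, seed = 4)
  gp <- generate_profile(sc, k_mat = 1e5)
  fld <- gp$truth$field
  z <- fld$depth_mm; C <- fld$conc_uM
  h <- (z[2] - z[1]) * 1e-3
  phi <- 0.9
  Ds <- sediment_diffusivity(diffusion_coefficient("H2S", 12, 10)$D_free, phi)
  i_mat <- which(z >= 0 & z < 1) # first-order sink cells
  i_lo <- max(i_mat) # flux enters between the last mat cell and the next
  J_in <- phi * Ds * (C[i_lo + 1] - C[i_lo]) / h
  J_out <- phi * Ds * (C[2] - C[1]) / h
  consumption <- phi * 1e5 * sum(C[i_mat[-1]]) * h # node 1 is Dirichlet
  expect_lt(abs((J_in - J_out - consumption) / J_in), 0.01)
  # and the received flux is the analytic production flux
  expect_equal(J_in, unname(gp$truth$true_flux["H2S"]), tolerance = 0.01)
})

test_that("surface flux is monotone in the production rate", {
  fluxes <- vapply(c(20, 50, 100, 200), function(rate) {
    gp <- generate_profile(scenario(production_zone = c(5, 40, rate),
                                    noise_sd = 0, seed = 5))
    unname(gp$truth$true_flux["H2S"])
  }, 0)
  expect_true(all(diff(fluxes) > 0))
})

test_that("deep Fe(II) source and sulfide fields do not overlap", {
  sc <- scenario(production_zone = c(5, 75, 40), mat_layer = NULL,
                 fe_source = c(100, 0.05), max_depth_mm = 150,
                 bottom_water_conc = c(H2S = 50, Fe = 0),
                 noise_sd = 0, seed = 6)
  gp <- generate_profile(sc)
  fld <- gp$truth$field
  h2s <- fld[fld$analyte == "H2S", ]
  fe <- fld[fld$analyte == "Fe", ]
  # sulfide maximum above the production bottom, decaying to ~0 at the source
  expect_lt(h2s$depth_mm[which.max(h2s$conc_uM)], 80)
  expect_lt(max(h2s$conc_uM[h2s$depth_mm >= 102]), 1)
  # Fe(II) appears only below the sulfide-depletion depth
  expect_gt(max(fe$conc_uM[fe$depth_mm > 105]), 1)
  expect_lt(max(fe$conc_uM[fe$depth_mm < 95]), 1)
  overlap <- merge(h2s, fe, by = "depth_mm")
  expect_equal(sum(overlap$conc_uM.x > 5 & overlap$conc_uM.y > 5), 0)
})

test_that("identical seeds reproduce identical outputs", {
  sc <- scenario(seed = 42)
  expect_identical(generate_profile(sc)$profile$data,
                   generate_profile(sc)$profile$data)
  a <- generate_chamber_series(2, seed = 7)
  b <- generate_chamber_series(2, seed = 7)
  expect_identical(a$data, b$data)
  v1 <- generate_voltammogram(c(H2S = 50), seed = 9)
  v2 <- generate_voltammogram(c(H2S = 50), seed = 9)
  expect_identical(v1$current_nA, v2$current_nA)
})

test_that("scenario validation rejects unphysical inputs", {
  expect_error(scenario(depth_step = 0.1), "0.25")
  expect_error(scenario(porosity = 0), "porosity")
  expect_error(scenario(production_zone = c(5, 40, -1)), "production_zone")
  expect_error(scenario(mat_layer = c(2, 1)), "mat layer")
})

test_that("synthetic voltammograms encode concentrations as specified", {
  cal <- calibration_model()
  flat <- generate_voltammogram(c(H2S = 0), cal, noise_sd_nA = 0.1, seed = 2,
                                replicate = 2)
  expect_lt(max(abs(flat$current_nA)), 0.6)

  v100 <- generate_voltammogram(c(H2S = 100), cal, noise_sd_nA = 0,
                                replicate = 2)
  expect_equal(max(detect_peaks(v100)$height), 100, tolerance = 0.01)
  expect_equal(measure_backward_wave(v100), 100, tolerance = 0.01)

  # forward peak clips at the 250 uM equivalent, wave stays proportional
  v600 <- generate_voltammogram(c(H2S = 600), cal, noise_sd_nA = 0,
                                replicate = 2)
  expect_lt(max(detect_peaks(v600)$height), 255)
  expect_equal(measure_backward_wave(v600), 600, tolerance = 0.01)

  expect_error(generate_voltammogram(c(Zn = 10), cal), "potential window")
})

test_that("chamber series rise linearly at flux/height", {
  # 0.8 mmol m-2 day-1 over 0.1 m for 30 h: +10 uM
  inc <- generate_chamber_series(0.8, height = 0.1, duration_h = 30,
                                 noise_sd = 0, start_conc = 50, seed = 1)
  expect_equal(max(inc$data$conc_uM) - min(inc$data$conc_uM), 10)
  expect_equal(nrow(inc$data), 6)

  flat <- generate_chamber_series(0, height = 0.1, noise_sd = 1,
                                  start_conc = 50, seed = 2)
  expect_lt(diff(range(flat$data$conc_uM)), 6) # constant within noise

  expect_error(generate_chamber_series(1, height = 0), "height")
  expect_error(generate_chamber_series(1, n_samples = 1), "2 samples")
})
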