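test_that("piecewise model is continuous at both breakpoints and handles the degenerate single-slope case", {
  slopes <- c(0.02, 0.06, 0.01)
  breaks <- c(220, 330)
  eps <- 1e-7
  for (b in breaks) {
    jump <- abs(piecewise_absorption(b + eps, slopes, breaks) -
                  piecewise_absorption(b - eps, slopes, breaks))
    expect_lt(jump, 1e-9 + 0.06 * 2 * eps)
  }
  # equal slopes collapse to one straight line
  tt <- seq(100, 380, 10)
  y <- piecewise_absorption(tt, c(0.05, 0.05, 0.05), breaks, anchor = 5)
  fit <- lm(y ~ tt)
  expect_equal(unname(coef(fit)[2]), 0.05, tolerance = 1e-12)
})

test_that("temperature-series generator returns the exact line when noiseless and honest SDs when noisy", {
  s0 <- simulate_temperature_series(c(0.033, 0.062, 0.021), c(262, 336),
                                    noise_sd = 0)
  expect_equal(s0$absorption,
               piecewise_absorption(s0$temperature, c(0.033, 0.062, 0.021),
                                    c(262, 336)))
  expect_true(all(s0$sd == 0))

  s1 <- simulate_temperature_series(c(0.033, 0.062, 0.021), c(262, 336),
                                    noise_sd = 0.1, replicates = 3, seed = 11)
  # bit-reproducible under the same seed (brute-force re-simulation oracle)
  s2 <- simulate_temperature_series(c(0.033, 0.062, 0.021), c(262, 336),
                                    noise_sd = 0.1, replicates = 3, seed = 11)
  expect_identical(s1$absorption, s2$absorption)
  expect_identical(s1$sd, s2$sd)
  # mean replicate SD is an estimate of 0.1; 3-sigma Monte Carlo band for
  # the mean over 29 points of a chi-distributed sd estimate
  expect_lt(abs(mean(s1$sd) - 0.1), 3 * 0.1 / sqrt(2 * (3 - 1)) / sqrt(29) * 2)
})

test_that("temperature-series generator validates its specification", {
  expect_error(simulate_temperature_series(c(1, 1, 1), c(90, 200)),
               class = "lyoglass_invalid_spec")
  expect_error(simulate_temperature_series(c(1, 1, 1), c(330, 220)),
               class = "lyoglass_invalid_spec")
})

test_that("vacuum slab leaves the terahertz pulse unchanged", {
  pair <- simulate_thz_pair(n_index = 1, alpha = 0, thickness = 0.05)
  expect_equal(pair$sample$amplitude, pair$reference$amplitude,
               tolerance = 1e-12)
})

test_that("a lossless slab applies the closed-form delay and Fresnel attenuation", {
  d <- 0.05
  pair <- simulate_thz_pair(n_index = 1.5, alpha = 0, thickness = d)
  tf <- thz_transfer_function(thz_spectrum(pair$sample),
                              thz_spectrum(pair$reference))
  band <- tf$usable & tf$frequency > 0.3 & tf$frequency < 2
  expect_equal(tf$magnitude[band], rep(24 / 25, sum(band)), tolerance = 1e-6)
  # phase slope gives the group delay (n - 1) d / c
  delay_expect <- 0.5 * d / 0.0299792458
  slope <- coef(lm(tf$phase[band] ~ tf$frequency[band]))[[2]]
  expect_equal(-slope / (2 * pi), delay_expect, tolerance = 1e-4)
})

test_that("slab delays exceeding the time window are refused", {
  expect_error(simulate_thz_pair(n_index = 3, alpha = 0, thickness = 0.5,
                                 time_end = 20),
               class = "lyoglass_truncation")
})

test_that("simulated spectra follow Gaussian band bookkeeping", {
  # single band: closed-form amplitude and area
  b <- tibble::tibble(centre = 1650, width = 5, area = 2)
  s <- simulate_ftir(b, wavenumbers = seq(1580, 1720, 1))
  expect_equal(max(s$absorbance), 2 / (5 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(pracma::trapz(s$wavenumber, s$absorbance), 2, tolerance = 2e-3)
  # mixture: total area equals the sum of band areas within 0.1%
  bands <- amide_band_template()
  sm <- simulate_ftir(bands, wavenumbers = seq(1580, 1720, 1))
  expect_equal(pracma::trapz(sm$wavenumber, sm$absorbance), sum(bands$area),
               tolerance = 1e-3)
  # seed reproducibility
  n1 <- simulate_ftir(bands, noise_sd = 0.01, seed = 3)
  n2 <- simulate_ftir(bands, noise_sd = 0.01, seed = 3)
  expect_identical(n1$absorbance, n2$absorbance)
})

test_that("amide band template hits requested class fractions and stays inside the window", {
  fr <- c(helix = 0.36, sheet = 0.30, turn = 0.20, random = 0.14)
  b <- amide_band_template(fr)
  expect_equal(nrow(b), 10)
  sums <- tapply(b$area, b$class, sum)
  expect_equal(as.numeric(sums[names(fr)]), unname(fr), tolerance = 1e-12)
  expect_true(all(b$centre > 1600 & b$centre < 1700))
  expect_true(all(b$area >= 0))
})

test_that("relaxation generator follows the inversion-recovery and spin-lock models exactly", {
  # inversion recovery at t = 0 with ideal inversion gives -M0
  s <- simulate_relaxation("t1", m0 = 2, a = 1, time_constant = 0.8,
                           delays = c(0, 0.1, 1, 5))
  expect_equal(s$magnetisation[1], -2)
  # spin-lock at tSL = T1rho gives M0 / e
  s2 <- simulate_relaxation("t1rho", m0 = 1, time_constant = 0.01,
                            delays = c(0.001, 0.01, 0.02, 0.05))
  expect_equal(s2$magnetisation[2], exp(-1))
  # the default grids are the eight-point experiment grids
  expect_equal(relaxation_delays("t1"), c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5))
  expect_equal(relaxation_delays("t1rho"),
               c(0.1, 1, 5, 10, 20, 30, 40, 50) / 1000)
  expect_error(simulate_relaxation("t1", time_constant = -1),
               class = "lyoglass_invalid_spec")
  # reproducibility
  a <- simulate_relaxation("t1", 1, 1, 0.8, noise_sd = 0.01, seed = 5)
  b <- simulate_relaxation("t1", 1, 1, 0.8, noise_sd = 0.01, seed = 5)
  expect_identical(a$magnetisation, b$magnetisation)
})

test_that("CD generator produces the canonical basis signatures", {
  h <- simulate_cd(c(helix = 1))
  # negative bands at 222 and 208 nm, positive at 193 nm
  at <- function(s, wl) s$ellipticity[which.min(abs(s$wavelength - wl))]
  expect_lt(at(h, 222), 0)
  expect_lt(at(h, 208), 0)
  expect_gt(at(h, 193), 0)
  sh <- simulate_cd(c(sheet = 1))
  expect_equal(sh$wavelength[which.min(sh$ellipticity)], 218, tolerance = 1)
  expect_error(simulate_cd(c(helix = 0.7, sheet = 0.2)),
               class = "lyoglass_invalid_spec")
  expect_error(simulate_cd(c(helix = 1.5, sheet = -0.5)),
               class = "lyoglass_invalid_spec")
})
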