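test_that("excipient subtraction removes a scaled excipient contribution", {
  wn <- seq(800, 1800, 1)
  exc <- simulate_ftir(excipient_band_template(1), wavenumbers = wn)
  # self-subtraction: k = 1, residual ~ 0
  self <- ftir_subtract_excipient(exc, exc)
  expect_lt(max(abs(self$absorbance)), 1e-12)
  expect_equal(attr(self, "scale"), 1, tolerance = 1e-9)

  protein <- simulate_ftir(amide_band_template(), wavenumbers = wn)
  mixed <- simulate_ftir(amide_band_template(),
                         excipient_bands = excipient_band_template(0.7),
                         wavenumbers = wn)
  recovered <- ftir_subtract_excipient(mixed, exc)
  expect_equal(attr(recovered, "scale"), 0.7, tolerance = 1e-3)
  expect_lt(max(abs(recovered$absorbance - protein$absorbance)),
            0.01 * max(protein$absorbance))

  # an excipient without the anchor band is refused
  no_band <- tibble::tibble(wavenumber = wn, absorbance = 0.3)
  expect_error(ftir_subtract_excipient(mixed, no_band),
               class = "lyoglass_no_anchor_peak")
})

test_that("area normalisation yields unit integral and is scale invariant", {
  s <- simulate_ftir(amide_band_template(), wavenumbers = seq(1580, 1720, 1))
  n1 <- ftir_normalize_area(s)
  expect_equal(pracma::trapz(n1$wavenumber, n1$absorbance), 1,
               tolerance = 1e-9)
  s2 <- s
  s2$absorbance <- 2 * s2$absorbance
  n2 <- ftir_normalize_area(s2)
  expect_equal(n2$absorbance, n1$absorbance, tolerance = 1e-12)
  neg <- s
  neg$absorbance <- -neg$absorbance
  expect_error(ftir_normalize_area(neg), class = "lyoglass_nonpositive_area")
})

test_that("Savitzky-Golay second derivative reproduces polynomials and locates band centres", {
  wn <- seq(1580, 1720, 1)
  quad <- tibble::tibble(wavenumber = wn, absorbance = 3 + 0.1 * wn +
                           0.002 * wn^2)
  d2 <- ftir_second_derivative(quad)
  expect_equal(d2$d2, rep(0.004, nrow(d2)), tolerance = 1e-9)
  # the derivative grid shrinks by half a window at each end
  expect_equal(nrow(d2), length(wn) - 14)

  g <- simulate_ftir(tibble::tibble(centre = 1650, width = 6, area = 1),
                     wavenumbers = wn)
  d2g <- ftir_second_derivative(g)
  expect_equal(d2g$wavenumber[which.min(d2g$d2)], 1650)

  # under noise the minimum stays within 1 cm^-1 of the centre
  hits <- vapply(1:20, function(seed) {
    gn <- simulate_ftir(tibble::tibble(centre = 1650, width = 6, area = 1),
                        wavenumbers = wn, noise_sd = 5e-4, seed = seed)
    d2n <- ftir_second_derivative(gn)
    abs(d2n$wavenumber[which.min(d2n$d2)] - 1650) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(ftir_second_derivative(g, sg_width = 2), "5 grid points")
  expect_error(ftir_second_derivative(g[1:10, ], sg_width = 14),
               "exceeds the spectrum")
})

test_that("band locator finds every component of a resolvable mixture", {
  b <- amide_band_template()
  s <- ftir_normalize_area(simulate_ftir(b, wavenumbers = seq(1580, 1720, 1)))
  cen <- ftir_locate_bands(s)
  expect_equal(length(cen), 10)
  expect_true(all(abs(sort(cen) - sort(b$centre)) < 1))
})

test_that("band fitting recovers small mixtures exactly", {
  wn <- seq(1580, 1720, 1)
  # one band: exact centre / width / area
  b1 <- tibble::tibble(centre = 1655, width = 5, area = 1)
  d2 <- ftir_second_derivative(ftir_normalize_area(simulate_ftir(b1, wavenumbers = wn)))
  f1 <- ftir_fit_bands(d2, k = 1)
  expect_equal(f1$peaks$centre, 1655, tolerance = 1e-4)
  expect_equal(f1$peaks$width, 5, tolerance = 1e-3)
  expect_equal(f1$peaks$area, 1 / pracma::trapz(wn, simulate_ftir(b1, wavenumbers = wn)$absorbance) *
                 1, tolerance = 1e-3)

  # three bands: centres within 0.5 cm^-1
  b3 <- tibble::tibble(centre = c(1620, 1652, 1680), width = c(4, 5, 4),
                       area = c(0.4, 0.8, 0.3))
  s3 <- ftir_normalize_area(simulate_ftir(b3, wavenumbers = wn))
  f3 <- ftir_fit_bands(ftir_second_derivative(s3), k = 3,
                       init_centres = ftir_locate_bands(s3))
  expect_equal(f3$peaks$centre, b3$centre, tolerance = 0.5)
  expect_equal(f3$peaks$area / sum(f3$peaks$area),
               b3$area / sum(b3$area), tolerance = 0.01)
})

test_that("band assignment maps canonical anchor positions to the right classes", {
  peaks <- tibble::tibble(centre = c(1658, 1640, 1670, 1690, 1644),
                          width = 4, area = c(1, 1, 1, 1, 1))
  est <- ftir_assign_bands(peaks)
  expect_equal(est$peaks$class,
               c("helix", "sheet", "turn", "sheet", "random"))
  expect_equal(sum(est$fractions$fraction), 100, tolerance = 1e-6)

  solo <- ftir_assign_bands(tibble::tibble(centre = 1658, width = 5, area = 2))
  expect_equal(solo$fractions$fraction[solo$fractions$class == "helix"], 100)

  # out-of-window bands are excluded with a warning
  expect_warning(
    out <- ftir_assign_bands(tibble::tibble(centre = c(1658, 1750),
                                            width = 5, area = c(1, 1))),
    "excluded")
  expect_equal(out$fractions$fraction[out$fractions$class == "helix"], 100)
})

test_that("the full chain recovers noiseless class fractions and is scale invariant", {
  s <- amide_fixture(frac_helix_rich)
  est <- ftir_secondary_structure(s)
  expect_lt(max(fraction_errors(est, frac_helix_rich)), 2)

  s7 <- s
  s7$absorbance <- 7 * s7$absorbance
  est7 <- ftir_secondary_structure(s7)
  expect_equal(est7$fractions$fraction, est$fractions$fraction,
               tolerance = 1e-6)
  expect_equal(sum(est$fractions$fraction), 100, tolerance = 1e-6)
})

test_that("the full chain stays within five points at a signal-to-noise ratio of 100", {
  peak <- max(amide_fixture(frac_helix_rich)$absorbance)
  for (seed in 1:3) {
    est <- suppressWarnings(ftir_secondary_structure(
      amide_fixture(frac_helix_rich, noise_sd = peak / 100, seed = seed)))
    expect_lt(max(fraction_errors(est, frac_helix_rich)), 5)
  }
})

test_that("structure estimates expose tidy output and plots", {
  est <- ftir_secondary_structure(amide_fixture(frac_helix_rich))
  expect_equal(nrow(tidy(est)), 4)
  expect_s3_class(autoplot(est), "ggplot")
  d2 <- ftir_second_derivative(ftir_normalize_area(amide_fixture(frac_helix_rich)))
  fit <- ftir_fit_bands(d2, k = 10)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(tidy(fit)), 10)
})
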