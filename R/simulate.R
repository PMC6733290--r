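#' Continuous three-region piecewise-linear absorption model
#'
#' Evaluates the idealised temperature dependence of the terahertz absorption
#' coefficient at the probe frequency: three linear regions (below the beta
#' glass transition, between the two transitions, and above the alpha glass
#' transition) joined continuously at the two breakpoints. Because the curve
#' is continuous, the pairwise intersections of the three lines coincide
#' exactly with the breakpoints, which makes transition-temperature recovery
#' well defined.
#'
#' @param temperature Numeric vector of temperatures (K).
#' @param slopes Numeric length-3 vector: absorption-change rate per region
#'   (cm^-1 K^-1), low to high temperature.
#' @param breakpoints Numeric length-2 vector `(Tb_low, Tb_high)` in K, the
#'   region boundaries (equal to the beta and alpha transition temperatures).
#' @param anchor Absorption coefficient (cm^-1) at the lowest temperature of
#'   `temperature` (defines the intercept of region 1).
#' @return Numeric vector of absorption coefficients (cm^-1).
#' @export
#' @examples
#' piecewise_absorption(c(100, 250, 350), slopes = c(0.02, 0.05, 0.01),
#'                      breakpoints = c(220, 330))
piecewise_absorption <- function(temperature, slopes, breakpoints, anchor = 10) {
  .assert(length(slopes) == 3 && is.numeric(slopes), "`slopes` must be numeric length 3.")
  .assert(length(breakpoints) == 2 && breakpoints[1] < breakpoints[2],
          "`breakpoints` must be length 2 with Tb_low < Tb_high.")
  t0 <- min(temperature)
  b1 <- breakpoints[1]
  b2 <- breakpoints[2]
  # Region intercepts chained for continuity at both breakpoints.
  y_b1 <- anchor + slopes[1] * (b1 - t0)
  y_b2 <- y_b1 + slopes[2] * (b2 - b1)
  ifelse(temperature <= b1, anchor + slopes[1] * (temperature - t0),
         ifelse(temperature <= b2, y_b1 + slopes[2] * (temperature - b1),
                y_b2 + slopes[3] * (temperature - b2)))
}

#' Simulate a temperature series of terahertz absorption at the probe frequency
#'
#' Generates replicate measurements of the absorption coefficient at the probe
#' frequency over a temperature ramp, following the continuous three-region
#' piecewise-linear model plus additive white Gaussian noise, and returns the
#' per-temperature mean and standard deviation — the same form in which
#' variable-temperature terahertz data are reported.
#'
#' @inheritParams piecewise_absorption
#' @param temperatures Strictly increasing temperature grid (K). The default
#'   is a 10 K ramp over 100–380 K, typical of variable-temperature
#'   terahertz experiments on lyophilised pellets.
#' @param noise_sd Standard deviation of the additive measurement noise
#'   (cm^-1) applied independently per replicate and temperature.
#' @param replicates Number of replicate sweeps averaged per temperature.
#' @param seed Optional integer seed; the output is bit-reproducible for a
#'   fixed seed and the caller's RNG state is left untouched.
#' @param label Formulation label carried into downstream fits.
#' @return A tibble with columns `temperature`, `absorption` (replicate
#'   mean, cm^-1), `sd` (replicate SD; 0 when `replicates == 1`) and `n_rep`.
#'   The generating parameters are attached as attribute `"truth"`.
#' @export
#' @examples
#' simulate_temperature_series(slopes = c(0.021, 0.054, 0.023),
#'                             breakpoints = c(219, 339), noise_sd = 0)
simulate_temperature_series <- function(slopes, breakpoints, anchor = 10,
                                        temperatures = seq(100, 380, by = 10),
                                        noise_sd = 0, replicates = 1,
                                        seed = NULL, label = NULL) {
  .assert(length(temperatures) >= 9 && all(diff(temperatures) > 0),
          "`temperatures` must be strictly increasing with at least 9 points.")
  .assert(length(breakpoints) == 2 && breakpoints[1] < breakpoints[2],
          "`breakpoints` must satisfy Tb_low < Tb_high.",
          class = "lyoglass_invalid_spec")
  .assert(breakpoints[1] > min(temperatures) && breakpoints[2] < max(temperatures),
          "Both breakpoints must lie strictly inside the temperature grid.",
          class = "lyoglass_invalid_spec")
  .assert(noise_sd >= 0 && replicates >= 1, "`noise_sd` >= 0 and `replicates` >= 1 required.")
  mu <- piecewise_absorption(temperatures, slopes, breakpoints, anchor)
  reps <- .with_seed(seed, {
    matrix(stats::rnorm(length(mu) * replicates, mean = mu, sd = noise_sd),
           nrow = length(mu), ncol = replicates)
  })
  out <- tibble(
    temperature = temperatures,
    absorption = rowMeans(reps),
    sd = if (replicates > 1) apply(reps, 1, stats::sd) else rep(0, length(mu)),
    n_rep = replicates
  )
  attr(out, "truth") <- list(slopes = slopes, breakpoints = breakpoints,
                             anchor = anchor, noise_sd = noise_sd)
  attr(out, "label") <- label
  out
}

#' Simulate a reference/sample terahertz waveform pair for a dielectric slab
#'
#' Forward model for terahertz time-domain transmission through a plane slab:
#' the reference single-cycle pulse (a Gaussian derivative, giving usable
#' bandwidth over roughly 0.2–2.5 THz) is propagated through a slab of
#' thickness `thickness` with refractive index `n_index` and absorption
#' coefficient `alpha` by multiplying its spectrum with the closed-form
#' transfer function
#' \deqn{H(\omega) = \frac{4n}{(n+1)^2}\, e^{-\alpha d/2}\, e^{-i\omega (n-1) d / c}.}
#' Etalon (Fabry-Perot) echoes are deliberately not generated, matching the
#' closed-form inversion in [thz_extract_constants()] which neglects them.
#'
#' @param n_index Refractive index: a single number (flat) or a function of
#'   frequency in THz. Must be >= 1.
#' @param alpha Absorption coefficient in cm^-1: a single number or a
#'   function of frequency in THz. Must be >= 0.
#' @param thickness Slab thickness in cm (pellets are typically 0.03–0.07 cm).
#' @param time_step Sampling interval in ps.
#' @param time_end End of the time window in ps.
#' @param pulse_centre,pulse_width Centre and Gaussian width (ps) of the
#'   reference pulse.
#' @param noise_sd Additive white-noise SD as a fraction of the reference
#'   peak amplitude.
#' @param seed Optional integer seed.
#' @param temperature Optional temperature metadata (K) attached to both
#'   waveforms.
#' @return A list with elements `reference` and `sample`, each a tibble with
#'   columns `time` (ps) and `amplitude`, carrying attributes `role`,
#'   `temperature` and (sample only) `thickness`.
#' @export
#' @examples
#' pair <- simulate_thz_pair(n_index = 1.8, alpha = 40, thickness = 0.05)
simulate_thz_pair <- function(n_index, alpha, thickness,
                              time_step = 0.05, time_end = 70,
                              pulse_centre = 10, pulse_width = 0.15,
                              noise_sd = 0, seed = NULL, temperature = NA_real_) {
  .assert(thickness > 0, "`thickness` must be positive (cm).",
          class = "lyoglass_invalid_spec")
  n_fun <- if (is.function(n_index)) n_index else function(f) rep(n_index, length(f))
  a_fun <- if (is.function(alpha)) alpha else function(f) rep(alpha, length(f))
  time <- seq(0, time_end, by = time_step)
  n_pts <- length(time)
  tt <- time - pulse_centre
  ref <- -tt / pulse_width^2 * exp(-tt^2 / (2 * pulse_width^2))
  ref <- ref / max(abs(ref))

  # Transfer function on the full DFT grid (Hermitian-symmetric so the
  # inverse transform is real).
  freq <- seq(0, n_pts - 1) / (n_pts * time_step)          # THz
  neg <- freq > 1 / (2 * time_step)
  freq[neg] <- freq[neg] - 1 / time_step
  fa <- abs(freq)
  nv <- n_fun(fa)
  av <- a_fun(fa)
  .assert(all(nv >= 1), "`n_index` must be >= 1 at all frequencies.",
          class = "lyoglass_invalid_spec")
  .assert(all(av >= 0), "`alpha` must be >= 0 at all frequencies.",
          class = "lyoglass_invalid_spec")
  delay <- (max(nv) - 1) * thickness / .c_light_cm_per_ps
  .assert(pulse_centre + delay + 8 * pulse_width < time_end,
          "Slab delay pushes the sample pulse outside the time window.",
          class = "lyoglass_truncation")
  h <- (4 * nv / (nv + 1)^2) * exp(-av * thickness / 2) *
    exp(-1i * 2 * pi * fa * (nv - 1) * thickness / .c_light_cm_per_ps)
  h[freq < 0] <- Conj(h[freq < 0])
  if (n_pts %% 2 == 0) h[n_pts / 2 + 1] <- Re(h[n_pts / 2 + 1])
  smp <- Re(fft(fft(ref) * h, inverse = TRUE)) / n_pts

  if (noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(2 * n_pts, sd = noise_sd * max(abs(ref))))
    ref <- ref + noise[seq_len(n_pts)]
    smp <- smp + noise[n_pts + seq_len(n_pts)]
  }
  mk <- function(amp, role, d = NULL) {
    w <- tibble(time = time, amplitude = amp)
    attr(w, "role") <- role
    attr(w, "temperature") <- temperature
    if (!is.null(d)) attr(w, "thickness") <- d
    w
  }
  list(reference = mk(ref, "reference"),
       sample = mk(smp, "sample", thickness))
}

#' Ten-component amide-I band table with prescribed class fractions
#'
#' Builds the default synthetic amide-I band set: ten Gaussian components at
#' fixed centres spanning 1600–1700 cm^-1 (low-frequency beta-sheet bands,
#' a main sheet band near 1640 cm^-1, a random-coil band, two alpha-helix
#' bands around 1658 cm^-1, two turn bands, and high-frequency sheet
#' shoulders near 1670/1690 cm^-1, following the canonical amide-I
#' assignments). Within-class shape weights are fixed; class totals are
#' rescaled so the integrated class area fractions equal `fractions`.
#'
#' @param fractions Named numeric vector over
#'   `c("helix", "sheet", "turn", "random")`, non-negative, summing to 1
#'   (values are renormalised if they sum to 100 instead).
#' @return A band-table tibble with columns `centre` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1), `area` (fraction of total) and `class`.
#' @export
#' @examples
#' amide_band_template(c(helix = 0.36, sheet = 0.30, turn = 0.20, random = 0.14))
amide_band_template <- function(fractions = c(helix = 0.36, sheet = 0.30,
                                              turn = 0.20, random = 0.14)) {
  .assert(all(c("helix", "sheet", "turn", "random") %in% names(fractions)),
          "`fractions` must name helix, sheet, turn and random.")
  .assert(all(fractions >= 0), "Fractions must be non-negative.")
  tot <- sum(fractions)
  .assert(tot > 0, "Fractions must not all be zero.")
  if (abs(tot - 100) < 1) fractions <- fractions / 100
  fractions <- fractions / sum(fractions)
  # Centres spaced ~9 cm^-1 so every component stays resolvable in the
  # 14 cm^-1 Savitzky-Golay second derivative (the premise of the
  # deconvolution method); width 3.2 cm^-1 (~7.5 cm^-1 FWHM).
  base <- tibble(
    centre = c(1609, 1618, 1627.5, 1636.5, 1645, 1653.5, 1662, 1671.5, 1680, 1689),
    width  = rep(3.2, 10),
    class  = c("sheet", "sheet", "sheet", "sheet", "random",
               "helix", "helix", "turn", "turn", "sheet"),
    weight = c(0.12, 0.15, 0.18, 0.40, 1, 0.5, 0.5, 0.55, 0.45, 0.15)
  )
  base |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(area = .data$weight / sum(.data$weight) *
                    fractions[[dplyr::first(.data$class)]]) |>
    dplyr::ungroup() |>
    dplyr::select("centre", "width", "area", "class")
}

#' Excipient (sugar) infrared band table
#'
#' Minimal excipient spectrum for exercising scaled subtraction: a marker
#' band at 851 cm^-1 (the anchor used for linear excipient subtraction) plus
#' sugar fingerprint bands in the 900–1200 cm^-1 region.
#'
#' @param scale Multiplies all band areas.
#' @return A band-table tibble (`centre`, `width`, `area`, `class`).
#' @export
excipient_band_template <- function(scale = 1) {
  tibble(
    centre = c(851, 925, 1055, 1110),
    width  = c(4, 8, 12, 10),
    area   = scale * c(0.15, 0.2, 0.45, 0.3),
    class  = "excipient"
  )
}

#' @noRd
.gaussian_mixture <- function(x, bands) {
  amp <- bands$area / (bands$width * sqrt(2 * pi))
  rowSums(vapply(seq_len(nrow(bands)), function(i) {
    amp[i] * exp(-(x - bands$centre[i])^2 / (2 * bands$width[i]^2))
  }, numeric(length(x))))
}

#' Simulate an infrared absorbance spectrum from a Gaussian band table
#'
#' The spectrum is the sum of the protein bands, optional excipient bands,
#' and additive white Gaussian noise, on a uniform wavenumber grid. Each
#' band contributes a Gaussian of integrated area `area` (so amplitude =
#' area / (width * sqrt(2*pi))).
#'
#' @param bands Band table (`centre`, `width`, `area`, and optionally
#'   `class`), e.g. from [amide_band_template()].
#' @param excipient_bands Optional band table added on top (e.g.
#'   [excipient_band_template()]).
#' @param wavenumbers Uniform increasing grid in cm^-1.
#' @param noise_sd Additive noise SD in absorbance units.
#' @param seed Optional integer seed.
#' @param label Label attached to the spectrum.
#' @return A tibble with columns `wavenumber` and `absorbance`; the band
#'   table is attached as attribute `"truth"`.
#' @export
#' @examples
#' s <- simulate_ftir(amide_band_template(), wavenumbers = seq(1580, 1720, 1))
simulate_ftir <- function(bands, excipient_bands = NULL,
                          wavenumbers = seq(800, 1800, by = 1),
                          noise_sd = 0, seed = NULL, label = NULL) {
  .assert(is.data.frame(bands) && nrow(bands) > 0,
          "`bands` must be a non-empty band table.")
  .assert(all(c("centre", "width", "area") %in% names(bands)),
          "`bands` needs columns centre, width, area.")
  .assert(all(bands$area >= 0) && all(bands$width > 0),
          "Band areas must be >= 0 and widths > 0.")
  .check_uniform(wavenumbers, what = "wavenumber grid")
  y <- .gaussian_mixture(wavenumbers, bands)
  if (!is.null(excipient_bands) && nrow(excipient_bands) > 0) {
    y <- y + .gaussian_mixture(wavenumbers, excipient_bands)
  }
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  }
  out <- tibble(wavenumber = wavenumbers, absorbance = y)
  attr(out, "truth") <- list(bands = bands, excipient_bands = excipient_bands,
                             noise_sd = noise_sd)
  attr(out, "label") <- label
  out
}

#' Default experiment delay grids for relaxation series
#'
#' The standard eight-point acquisition grids: inversion-recovery delays of
#' 0.01–5 s for T1 and spin-lock times of 0.1–50 ms for T1rho.
#'
#' @param kind `"t1"` or `"t1rho"`.
#' @return Numeric vector of delays in seconds.
#' @export
relaxation_delays <- function(kind = c("t1", "t1rho")) {
  kind <- match.arg(kind)
  switch(kind,
         t1 = c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5),
         t1rho = c(0.1, 1, 5, 10, 20, 30, 40, 50) * 1e-3)
}

#' Simulate an NMR relaxation series
#'
#' Inversion-recovery magnetisation follows
#' \eqn{M(t) = M_0 (1 - 2 A e^{-t/T_1})} and spin-lock decay follows
#' \eqn{M(t_{SL}) = M_0 e^{-t_{SL}/T_{1\rho}}}; additive white Gaussian
#' noise is applied on top.
#'
#' @param kind `"t1"` (inversion recovery) or `"t1rho"` (spin-lock decay).
#' @param m0 Equilibrium magnetisation (arbitrary units).
#' @param a Inversion correction factor (T1 only; ideal inversion gives 1).
#' @param time_constant The relaxation time T1 or T1rho in seconds; must be
#'   positive.
#' @param delays Delay grid in seconds (defaults to the experiment grid for
#'   `kind`, see [relaxation_delays()]).
#' @param noise_sd Additive noise SD in magnetisation units.
#' @param seed Optional integer seed.
#' @param component Component tag, e.g. `"protein"` (carbonyl 165–185 ppm
#'   integral) or `"sugar"` (alcohol/anomeric 67–102 ppm integral).
#' @param label Formulation label.
#' @return A tibble with columns `delay` (s) and `magnetisation`, with
#'   attributes `kind`, `component`, `label` and `truth`.
#' @export
#' @examples
#' simulate_relaxation("t1", m0 = 1, a = 1, time_constant = 0.8)
simulate_relaxation <- function(kind = c("t1", "t1rho"), m0 = 1, a = 1,
                                time_constant, delays = NULL,
                                noise_sd = 0, seed = NULL,
                                component = NA_character_, label = NULL) {
  kind <- match.arg(kind)
  .assert(time_constant > 0, "`time_constant` must be positive.",
          class = "lyoglass_invalid_spec")
  delays <- delays %||% relaxation_delays(kind)
  .assert(length(delays) >= 1 && !anyDuplicated(delays) && all(delays >= 0),
          "`delays` must be non-empty, unique and non-negative.")
  mu <- if (kind == "t1") {
    m0 * (1 - 2 * a * exp(-delays / time_constant))
  } else {
    m0 * exp(-delays / time_constant)
  }
  y <- if (noise_sd > 0) {
    mu + .with_seed(seed, stats::rnorm(length(mu), sd = noise_sd))
  } else mu
  out <- tibble(delay = delays, magnetisation = y)
  attr(out, "kind") <- kind
  attr(out, "component") <- component
  attr(out, "label") <- label
  attr(out, "truth") <- list(m0 = m0, a = a, time_constant = time_constant,
                             noise_sd = noise_sd)
  out
}

# Parameterised far-UV basis curves (arbitrary ellipticity units). The helix
# basis has the canonical double minimum at 222/208 nm and positive band at
# 193 nm; sheet a single broad minimum at 218 nm; random coil a deep minimum
# near 198 nm.
#' @noRd
.cd_basis <- function(wavelength) {
  g <- function(c0, w) exp(-(wavelength - c0)^2 / (2 * w^2))
  list(
    helix  = 70 * g(193, 5) - 34 * g(208, 5.5) - 33 * g(222, 6),
    sheet  = 28 * g(196, 5.5) - 30 * g(218, 9),
    turn   = 12 * g(205, 7) - 8 * g(225, 8),
    random = -42 * g(198, 6) + 4 * g(220, 12)
  )
}

#' Simulate a far-UV circular dichroism spectrum
#'
#' Mixture of parameterised secondary-structure basis curves over the
#' 190–250 nm acquisition range at 0.5 nm steps, plus additive noise.
#'
#' @param fractions Named non-negative fractions over a subset of
#'   `c("helix", "sheet", "turn", "random")`, summing to 1.
#' @param wavelengths Uniform wavelength grid in nm.
#' @param noise_sd Additive noise SD (mdeg).
#' @param seed Optional integer seed.
#' @param label Label attached to the spectrum.
#' @return A tibble with columns `wavelength` (nm) and `ellipticity` (mdeg).
#' @export
#' @examples
#' simulate_cd(c(helix = 1))
simulate_cd <- function(fractions, wavelengths = seq(190, 250, by = 0.5),
                        noise_sd = 0, seed = NULL, label = NULL) {
  basis <- .cd_basis(wavelengths)
  .assert(length(fractions) > 0 && all(names(fractions) %in% names(basis)),
          "`fractions` must be named with helix/sheet/turn/random.")
  .assert(all(fractions >= 0), "Fractions must be non-negative.",
          class = "lyoglass_invalid_spec")
  .assert(abs(sum(fractions) - 1) < 1e-8, "Fractions must sum to 1.",
          class = "lyoglass_invalid_spec")
  y <- Reduce(`+`, purrr::map2(fractions, names(fractions),
                               function(fr, nm) fr * basis[[nm]]))
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  }
  out <- tibble(wavelength = wavelengths, ellipticity = y)
  attr(out, "truth") <- list(fractions = fractions, noise_sd = noise_sd)
  attr(out, "label") <- label
  out
}
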