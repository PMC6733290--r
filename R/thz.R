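#' Discrete Fourier spectrum of a terahertz waveform
#'
#' Transforms a uniformly sampled time-domain waveform to its one-sided
#' complex spectrum. The phase is unwrapped along frequency and anchored at
#' zero frequency: a straight line is fitted to the unwrapped phase over the
#' 0.2–0.8 THz mid-band and the whole phase is shifted by the integer
#' multiple of 2*pi nearest the extrapolated intercept, which removes the
#' arbitrary unwrapping offset without distorting the phase slope.
#'
#' @param waveform Tibble with columns `time` (ps, uniform, increasing) and
#'   `amplitude`, e.g. from [simulate_thz_pair()] or [read_thz_waveform()].
#' @param taper Half-cosine (Tukey) taper fraction in `[0, 1]` applied to
#'   the waveform ends before transforming; 0 means no window.
#' @param anchor_band Length-2 frequency range (THz) used for the phase
#'   anchoring fit.
#' @return A tibble with columns `frequency` (THz, positive bins),
#'   `amplitude` (complex), `magnitude` and `phase` (radians, unwrapped and
#'   anchored). Waveform attributes (`role`, `temperature`, `thickness`)
#'   are carried over.
#' @export
thz_spectrum <- function(waveform, taper = 0, anchor_band = c(0.2, 0.8)) {
  w <- .as_xy(waveform, "time", "amplitude", "thz_spectrum")
  n_pts <- nrow(w)
  .assert(n_pts >= 64, "Waveform must have at least 64 samples.")
  dt <- .check_uniform(w$time, what = "time axis")
  y <- w$amplitude
  if (taper > 0) {
    .assert(taper <= 1, "`taper` must be in [0, 1].")
    y <- y * .tukey_window(n_pts, taper)
  }
  spec <- fft(y)
  half <- seq(2, floor(n_pts / 2) + 1)            # positive frequencies only
  freq <- (half - 1) / (n_pts * dt)
  amp <- spec[half]
  phase <- signal::unwrap(Arg(amp))
  band <- freq >= anchor_band[1] & freq <= anchor_band[2]
  if (sum(band) >= 3) {
    fit <- lm(phase[band] ~ freq[band])
    offset <- 2 * pi * round(coef(fit)[[1]] / (2 * pi))
    phase <- phase - offset
  }
  out <- tibble(frequency = freq, amplitude = amp,
                magnitude = Mod(amp), phase = phase)
  for (a in c("role", "temperature", "thickness")) {
    attr(out, a) <- attr(waveform, a, exact = TRUE)
  }
  out
}

#' Complex transfer function of a sample/reference spectrum pair
#'
#' Elementwise complex ratio sample/reference on a common frequency axis.
#' The phase is taken as the difference of the two anchored unwrapped
#' phases, which keeps it continuous. Bins where the reference magnitude
#' falls below `noise_floor` times its peak are masked as unusable.
#'
#' @param sample,reference Spectra from [thz_spectrum()] with identical
#'   frequency axes.
#' @param noise_floor Reference-magnitude fraction below which a bin is
#'   masked.
#' @return A tibble with columns `frequency`, `amplitude` (complex ratio),
#'   `magnitude`, `phase` and `usable`. The sample's `thickness` attribute
#'   is carried over.
#' @export
thz_transfer_function <- function(sample, reference, noise_floor = 0.01) {
  .assert(nrow(sample) == nrow(reference) &&
            max(abs(sample$frequency - reference$frequency)) < 1e-9,
          "Sample and reference must share the same frequency axis.")
  ratio <- sample$amplitude / reference$amplitude
  out <- tibble(
    frequency = sample$frequency,
    amplitude = ratio,
    magnitude = Mod(ratio),
    phase = sample$phase - reference$phase,
    usable = reference$magnitude >= noise_floor * max(reference$magnitude)
  )
  attr(out, "thickness") <- attr(sample, "thickness", exact = TRUE)
  attr(out, "temperature") <- attr(sample, "temperature", exact = TRUE)
  out
}

#' Extract optical constants from a slab transfer function
#'
#' Closed-form thick-slab inversion neglecting etalon reflections: the
#' refractive index follows from the phase delay,
#' \deqn{n(\omega) = 1 + \frac{c\,|\phi(\omega)|}{\omega d},}
#' and the absorption coefficient from the magnitude after removing the
#' Fresnel amplitude-transmission factor,
#' \deqn{\alpha(\omega) = -\frac{2}{d}\,
#'   \ln\!\left[|H(\omega)|\,\frac{(n+1)^2}{4n}\right] \quad (\mathrm{cm}^{-1}).}
#' Bins where the magnitude exceeds the Fresnel factor (which would give a
#' negative absorption coefficient) are flagged as unusable rather than
#' raising an error.
#'
#' @param tf Transfer function from [thz_transfer_function()].
#' @param thickness Slab thickness in cm; taken from the `thickness`
#'   attribute of `tf` when omitted.
#' @return A tibble with columns `frequency` (THz), `n`, `alpha` (cm^-1)
#'   and `usable`.
#' @export
thz_extract_constants <- function(tf, thickness = NULL) {
  thickness <- thickness %||% attr(tf, "thickness", exact = TRUE)
  .assert(is.numeric(thickness) && length(thickness) == 1 && thickness > 0,
          "`thickness` must be a positive scalar (cm).")
  omega <- 2 * pi * tf$frequency               # rad / ps
  n <- 1 + .c_light_cm_per_ps * abs(tf$phase) / (omega * thickness)
  alpha <- -(2 / thickness) * log(tf$magnitude * (n + 1)^2 / (4 * n))
  usable <- tf$usable & is.finite(n) & is.finite(alpha) &
    tf$frequency > 0 & alpha >= 0 & n >= 1
  out <- tibble(frequency = tf$frequency, n = n, alpha = alpha,
                usable = usable)
  attr(out, "thickness") <- thickness
  attr(out, "temperature") <- attr(tf, "temperature", exact = TRUE)
  out
}

#' Absorption coefficient at a probe frequency
#'
#' Mean absorption coefficient over a symmetric frequency window centred on
#' the probe frequency (1 THz by default, where amorphous lyophilisates
#' have a high signal-to-noise, featureless response). When fewer than
#' three usable bins fall inside the window the single nearest usable bin
#' is used instead.
#'
#' @param optics Tibble from [thz_extract_constants()].
#' @param frequency Probe frequency in THz.
#' @param window Half-width of the averaging window in THz.
#' @return The absorption coefficient in cm^-1 (scalar).
#' @export
thz_absorption_at <- function(optics, frequency = 1.0, window = 0.05) {
  ok <- optics$usable
  .assert(any(ok), "No usable frequency bins.")
  .assert(frequency >= min(optics$frequency[ok]) &&
            frequency <= max(optics$frequency[ok]),
          "Probe frequency lies outside the usable band.",
          class = "lyoglass_out_of_band")
  sel <- ok & abs(optics$frequency - frequency) <= window
  if (sum(sel) < 3) {
    idx <- which(ok)[which.min(abs(optics$frequency[ok] - frequency))]
    return(optics$alpha[idx])
  }
  mean(optics$alpha[sel])
}

#' One-call optical-constant extraction from a waveform pair
#'
#' Convenience wrapper running [thz_spectrum()] on both waveforms,
#' [thz_transfer_function()] and [thz_extract_constants()].
#'
#' @param sample,sample_waveform,reference_waveform Waveform tibbles.
#' @param thickness Slab thickness in cm (defaults to the sample waveform's
#'   `thickness` attribute).
#' @param taper,noise_floor Passed to the underlying steps.
#' @return A tibble of optical constants, see [thz_extract_constants()].
#' @export
#' @examples
#' pair <- simulate_thz_pair(n_index = 1.8, alpha = 40, thickness = 0.05)
#' oc <- thz_optical_constants(pair$sample, pair$reference)
#' thz_absorption_at(oc, 1.0)
thz_optical_constants <- function(sample_waveform, reference_waveform,
                                  thickness = NULL, taper = 0,
                                  noise_floor = 0.01) {
  thickness <- thickness %||% attr(sample_waveform, "thickness", exact = TRUE)
  tf <- thz_transfer_function(thz_spectrum(sample_waveform, taper = taper),
                              thz_spectrum(reference_waveform, taper = taper),
                              noise_floor = noise_floor)
  thz_extract_constants(tf, thickness = thickness)
}
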