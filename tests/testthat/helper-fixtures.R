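# Shared fixture builders. All synthetic, generated at test time.

# Noiseless temperature series built from a published-parameters row.
ref_series <- function(row, temperatures = seq(100, 380, by = 2), ...) {
  simulate_temperature_series(
    slopes = c(row$m1, row$m2, row$m3),
    breakpoints = c(row$tg_beta, row$tg_alpha),
    temperatures = temperatures,
    noise_sd = 0,
    label = row$formulation,
    ...
  )
}

# Default class-fraction sets used for amide-I fixtures (percent).
frac_helix_rich <- c(helix = 0.36, sheet = 0.30, turn = 0.20, random = 0.14)
frac_sheet_rich <- c(helix = 0.15, sheet = 0.56, turn = 0.19, random = 0.10)

amide_fixture <- function(fractions, noise_sd = 0, seed = NULL,
                          wavenumbers = seq(1580, 1720, by = 1)) {
  simulate_ftir(amide_band_template(fractions), wavenumbers = wavenumbers,
                noise_sd = noise_sd, seed = seed)
}

fraction_errors <- function(est, fractions) {
  truth <- 100 * fractions / sum(fractions)
  abs(est$fractions$fraction - truth[est$fractions$class])
}

# Independent brute-force three-region scan using lm() per segment; the
# oracle against which the fast prefix-sum search is checked.
brute_force_sse <- function(data, min_pts = 3) {
  x <- data$temperature
  y <- data$absorption
  n <- length(x)
  best <- Inf
  for (i in seq(min_pts, n - 2 * min_pts)) {
    for (j in seq(i + min_pts, n - min_pts)) {
      idx <- list(1:i, (i + 1):j, (j + 1):n)
      sse <- sum(vapply(idx, function(ii) {
        sum(stats::residuals(stats::lm(y[ii] ~ x[ii]))^2)
      }, numeric(1)))
      if (sse < best) best <- sse
    }
  }
  best
}
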