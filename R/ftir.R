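#' Scaled linear excipient subtraction
#'
#' Removes the excipient contribution from a formulation spectrum by
#' subtracting the pure-excipient spectrum scaled to the excipient marker
#' band at 851 cm^-1: the scale factor is the ratio of the
#' baseline-corrected peak heights of sample and excipient near the anchor.
#' The peak is the interior local maximum within `search` cm^-1 of the
#' anchor after removing a local linear baseline drawn between the window
#' edges.
#'
#' @param sample,excipient Spectra (tibbles with `wavenumber`,
#'   `absorbance`). The excipient is linearly interpolated onto the sample
#'   grid if the grids differ.
#' @param anchor Anchor wavenumber in cm^-1.
#' @param search Half-width of the peak search window in cm^-1.
#' @return The subtracted spectrum (tibble, sample grid) with the applied
#'   scale factor as attribute `"scale"`.
#' @export
ftir_subtract_excipient <- function(sample, excipient, anchor = 851,
                                    search = 5) {
  s <- .as_xy(sample, "wavenumber", "absorbance", "ftir_subtract_excipient")
  e <- .as_xy(excipient, "wavenumber", "absorbance", "ftir_subtract_excipient")
  ey <- approx(e$wavenumber, e$absorbance, xout = s$wavenumber, rule = 2)$y

  peak_height <- function(y, what) {
    idx <- which(abs(s$wavenumber - anchor) <= search)
    .assert(length(idx) >= 3,
            "Anchor window must contain at least 3 grid points.")
    base <- approx(s$wavenumber[idx][c(1, length(idx))],
                   y[idx][c(1, length(idx))],
                   xout = s$wavenumber[idx])$y
    corr <- y[idx] - base
    interior <- seq(2, length(idx) - 1)
    is_max <- corr[interior] >= corr[interior - 1] &
      corr[interior] >= corr[interior + 1] & corr[interior] > 0
    if (!any(is_max)) {
      abort(sprintf("No local maximum near %g cm^-1 in the %s spectrum.",
                    anchor, what),
            class = "lyoglass_no_anchor_peak")
    }
    max(corr[interior][is_max])
  }
  h_e <- peak_height(ey, "excipient")
  h_s <- tryCatch(peak_height(s$absorbance, "sample"),
                  lyoglass_no_anchor_peak = function(err) 0)
  k <- h_s / h_e
  out <- tibble(wavenumber = s$wavenumber,
                absorbance = s$absorbance - k * ey)
  attr(out, "scale") <- k
  attr(out, "label") <- attr(sample, "label", exact = TRUE)
  out
}

#' Normalise a spectrum to unit integrated area
#'
#' Divides the spectrum by its trapezoidal integral over `window`, so that
#' the area under the curve in the window equals 1. Downstream area-ratio
#' quantities are thereby independent of acquisition scaling.
#'
#' @param spectrum Tibble with `wavenumber`, `absorbance`.
#' @param window Length-2 integration window in cm^-1; defaults to the
#'   whole grid.
#' @return The normalised spectrum.
#' @export
ftir_normalize_area <- function(spectrum, window = NULL) {
  s <- .as_xy(spectrum, "wavenumber", "absorbance", "ftir_normalize_area")
  window <- window %||% range(s$wavenumber)
  .assert(window[1] >= min(s$wavenumber) && window[2] <= max(s$wavenumber),
          "`window` must lie inside the wavenumber grid.")
  sel <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  total <- .trapz(s$wavenumber[sel], s$absorbance[sel])
  .assert(total > 0, "Integrated area must be positive.",
          class = "lyoglass_nonpositive_area")
  out <- tibble(wavenumber = s$wavenumber, absorbance = s$absorbance / total)
  attr(out, "label") <- attr(spectrum, "label", exact = TRUE)
  out
}

# Savitzky-Golay derivative filter spanning `sg_width` wavenumber units.
# Returns the filtered series (full length, edges included).
#' @noRd
.sg_deriv <- function(y, dx, sg_width, poly_order, deriv) {
  n_win <- round(sg_width / dx) + 1
  if (n_win %% 2 == 0) n_win <- n_win + 1
  .assert(n_win >= 5, "`sg_width` must span at least 5 grid points.")
  .assert(n_win <= length(y), "Filter window exceeds the spectrum length.")
  .assert(poly_order > deriv - 1, "`poly_order` too low for this derivative.")
  list(values = signal::sgolayfilt(y, p = poly_order, n = n_win, m = deriv,
                                   ts = dx),
       half = (n_win - 1) / 2)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Smoothed second derivative computed with a Savitzky-Golay filter whose
#' window spans `sg_width` in wavenumber units (14 cm^-1 by default — i.e.
#' 15 points on a 1 cm^-1 grid). Edge points where the filter window is not
#' fully supported are truncated, so the returned grid shrinks by half a
#' window at each end.
#'
#' @param spectrum Tibble with `wavenumber`, `absorbance` on a uniform grid.
#' @param sg_width Filter window span in cm^-1.
#' @param poly_order Polynomial order of the filter (default 3).
#' @return Tibble with `wavenumber` and `d2` (absorbance per cm^-2).
#' @export
ftir_second_derivative <- function(spectrum, sg_width = 14, poly_order = 3) {
  s <- .as_xy(spectrum, "wavenumber", "absorbance", "ftir_second_derivative")
  dx <- .check_uniform(s$wavenumber, what = "wavenumber grid")
  f <- .sg_deriv(s$absorbance, dx, sg_width, poly_order, deriv = 2)
  keep <- seq(f$half + 1, nrow(s) - f$half)
  out <- tibble(wavenumber = s$wavenumber[keep], d2 = f$values[keep])
  attr(out, "label") <- attr(spectrum, "label", exact = TRUE)
  attr(out, "sg") <- list(sg_width = sg_width, poly_order = poly_order, dx = dx)
  out
}

#' Locate candidate band centres from the fourth derivative
#'
#' Band centres appear as positive maxima of the (Savitzky-Golay smoothed)
#' fourth derivative of the absorbance spectrum; the fourth derivative
#' resolves overlapping components considerably better than the second, so
#' it is the preferred source of initial centres for the band fit.
#' Sub-grid positions are obtained by parabolic interpolation through each
#' maximum.
#'
#' @param spectrum Absorbance spectrum tibble (`wavenumber`, `absorbance`).
#' @param window Length-2 search window in cm^-1.
#' @param sg_width Savitzky-Golay window span in cm^-1 (matched to the
#'   second-derivative step).
#' @return Numeric vector of candidate centres (cm^-1), increasing.
#' @export
ftir_locate_bands <- function(spectrum, window = c(1600, 1700),
                              sg_width = 14) {
  s <- .as_xy(spectrum, "wavenumber", "absorbance", "ftir_locate_bands")
  dx <- .check_uniform(s$wavenumber, what = "wavenumber grid")
  d4 <- .sg_deriv(s$absorbance, dx, sg_width, poly_order = 5, deriv = 4)$values
  x <- s$wavenumber
  keep <- which(x >= window[1] & x <= window[2])
  keep <- keep[-c(1, length(keep))]          # strict interior of the window
  keep <- keep[keep > 1 & keep < length(x)]
  cen <- numeric(0)
  for (j in keep) {
    if (d4[j] >= d4[j - 1] && d4[j] >= d4[j + 1] && d4[j] > 0) {
      denom <- d4[j - 1] - 2 * d4[j] + d4[j + 1]
      off <- if (denom < 0) 0.5 * (d4[j - 1] - d4[j + 1]) / denom else 0
      cen <- c(cen, x[j] + off * dx)
    }
  }
  sort(cen)
}

#' Fit Gaussian band profiles to a second-derivative spectrum
#'
#' Decomposes the amide-I second-derivative trace into `k` Gaussian
#' absorbance components. Each component profile is a Gaussian passed
#' through the same Savitzky-Golay second-derivative filter that produced
#' the trace, so the forward model matches the data processing exactly and
#' band areas are not biased by the filter's smoothing. The fit is a
#' two-stage variable-projection nonlinear least squares: component
#' amplitudes are solved linearly inside the residual, widths are first
#' refined with centres pinned at their initial estimates, then centres
#' and widths are freed together; final amplitudes are obtained by
#' non-negative least squares. Initial centres come from `init_centres`
#' (normally the fourth-derivative band locator, see
#' [ftir_locate_bands()]); without them, the `k` deepest interior local
#' minima of the trace are used, padded with evenly spaced centres. A
#' short ladder of initial widths is tried and the best solution kept.
#'
#' @param d2 Second-derivative spectrum from [ftir_second_derivative()].
#' @param k Number of Gaussian bands (10 for the standard amide-I
#'   deconvolution).
#' @param window Fit window in cm^-1 (amide I, 1600–1700 by default).
#' @param sg_width,poly_order Savitzky-Golay parameters used to produce
#'   `d2` (taken from its `sg` attribute when available; must match).
#' @param init_centres Optional numeric vector of initial band centres.
#' @param width_init Initial Gaussian sigma in cm^-1 (first rung of the
#'   ladder).
#' @param width_bounds Length-2 allowed sigma range in cm^-1. The default
#'   2–12 cm^-1 spans the physical range of amide-I component bands
#'   (roughly 5–28 cm^-1 full width at half maximum).
#' @param restarts Additional width-ladder attempts after the first.
#' @return An object of class `"amide_band_fit"`: list with `peaks`
#'   (tibble: `centre`, `width`, `amplitude`, `area` where area is that of
#'   the underlying absorbance Gaussian, amplitude * width * sqrt(2*pi)),
#'   `residual_norm`, `converged`, `window` and the fitted `d2` data
#'   (with a `fitted` column).
#' @export
ftir_fit_bands <- function(d2, k = 10, window = c(1600, 1700),
                           sg_width = NULL, poly_order = NULL,
                           init_centres = NULL, width_init = 3.5,
                           width_bounds = c(2, 12), restarts = 3) {
  s <- .as_xy(d2, "wavenumber", "d2", "ftir_fit_bands")
  sg <- attr(d2, "sg", exact = TRUE)
  sg_width <- sg_width %||% sg$sg_width %||% 14
  poly_order <- poly_order %||% sg$poly_order %||% 3
  dx <- .check_uniform(s$wavenumber, what = "wavenumber grid")
  .assert(window[1] >= min(s$wavenumber) && window[2] <= max(s$wavenumber),
          "Fit window must lie inside the (truncated) derivative grid.")
  sel <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  x <- s$wavenumber[sel]
  y <- s$d2[sel]
  .assert(length(x) > 3 * k, "Window too narrow for the requested band count.")

  # Model machinery: Gaussians evaluated on a grid extended by half a
  # filter window, filtered, and cropped back to the fit window.
  n_win <- round(sg_width / dx) + 1
  if (n_win %% 2 == 0) n_win <- n_win + 1
  half <- (n_win - 1) / 2
  xe <- seq(min(x) - half * dx, max(x) + half * dx, by = dx)
  idx <- seq(half + 1, length(xe) - half)
  col_for <- function(c0, w) {
    signal::sgolayfilt(exp(-(xe - c0)^2 / (2 * w^2)), p = poly_order,
                       n = n_win, m = 2, ts = dx)[idx]
  }
  design <- function(cen, wid) {
    vapply(seq_along(cen), function(i) col_for(cen[i], wid[i]),
           numeric(length(x)))
  }
  proj_resid <- function(A) {
    a <- qr.coef(qr(A), y)
    a[is.na(a)] <- 0
    as.numeric(A %*% a) - y
  }

  # Initial centres: supplied locator candidates, else deep d2 minima
  # padded with evenly spaced positions.
  cen0 <- init_centres
  if (!is.null(cen0)) {
    cen0 <- cen0[cen0 >= window[1] & cen0 <= window[2]]
    if (length(cen0) == 0) cen0 <- NULL
  }
  if (is.null(cen0)) {
    interior <- seq(2, length(y) - 1)
    is_min <- y[interior] <= y[interior - 1] & y[interior] <= y[interior + 1] &
      y[interior] < 0
    cen0 <- x[interior][is_min]
    cen0 <- cen0[order(y[match(cen0, x)])]
  }
  depth_at <- approx(x, y, xout = cen0, rule = 2)$y
  if (length(cen0) > k) {
    # Let the data choose which surplus candidates to drop: try removing
    # each combination of the shallowest few and keep the subset whose
    # fixed-width linear fit explains the trace best.
    surplus <- length(cen0) - k
    pool <- order(depth_at, decreasing = TRUE)[seq_len(min(length(cen0), surplus + 3))]
    combos <- utils::combn(pool, surplus)
    devs <- apply(combos, 2, function(drop_idx) {
      A <- design(cen0[-drop_idx], rep(width_init, k))
      sum(proj_resid(A)^2)
    })
    cen0 <- cen0[-combos[, which.min(devs)]]
    depth_at <- approx(x, y, xout = cen0, rule = 2)$y
  }
  if (length(cen0) < k) {
    pad <- seq(window[1] + 2, window[2] - 2, length.out = k - length(cen0))
    cen0 <- c(cen0, pad)
  }
  cen0 <- sort(pmin(pmax(cen0, window[1]), window[2]))

  width_ladder <- unique(c(width_init, 2.6, 5, 8))[seq_len(restarts + 1)]
  lo_c <- rep(window[1], k); hi_c <- rep(window[2], k)
  lo_w <- rep(width_bounds[1], k); hi_w <- rep(width_bounds[2], k)
  y2 <- max(sum(y^2), .Machine$double.xmin)
  best <- NULL
  best_ok <- FALSE
  for (w0 in width_ladder) {
    stage1 <- minpack.lm::nls.lm(
      par = rep(w0, k),
      fn = function(w) proj_resid(design(cen0, w)),
      lower = lo_w, upper = hi_w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    stage2 <- minpack.lm::nls.lm(
      par = c(cen0, stage1$par),
      fn = function(p) proj_resid(design(p[seq_len(k)], p[k + seq_len(k)])),
      lower = c(lo_c, lo_w), upper = c(hi_c, hi_w),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    ok <- stage2$info %in% 1:4
    if (is.null(best) || stage2$deviance < best$deviance) {
      best <- stage2
      best_ok <- ok
    }
    if (ok && best$deviance / y2 < 1e-10) break
  }
  if (!best_ok) {
    abort(sprintf("Band fit did not converge (best residual %.3g).",
                  best$deviance),
          class = "lyoglass_fit_failure", residual = best$deviance)
  }
  cen <- best$par[seq_len(k)]
  wid <- best$par[k + seq_len(k)]
  A <- design(cen, wid)
  amp <- pracma::lsqnonneg(A, y)$x
  o <- order(cen)
  peaks <- tibble(centre = cen[o], width = wid[o], amplitude = amp[o],
                  area = (amp * wid * sqrt(2 * pi))[o])
  structure(list(
    peaks = peaks,
    residual_norm = sqrt(best$deviance),
    converged = best_ok,
    window = window,
    sg = list(sg_width = sg_width, poly_order = poly_order, dx = dx),
    d2 = tibble(wavenumber = x, d2 = y, fitted = as.numeric(A %*% amp))
  ), class = "amide_band_fit")
}

#' Amide-I band-class boundary table
#'
#' Default mapping from fitted band centre to secondary-structure class:
#' low-frequency beta-sheet up to 1640 cm^-1, random coil 1640–1646,
#' alpha-helix 1646–1664, turns 1664–1680 and the high-frequency beta-sheet
#' component 1680–1700 cm^-1 (boundaries placed at half-integers so bands
#' on integer grids are never on a boundary). Consistent with the canonical
#' anchors: 1658 helix, 1640 sheet main band, 1670 turn, 1690 sheet
#' shoulder. Override by passing a modified table to
#' [ftir_assign_bands()].
#'
#' @return A tibble with columns `class`, `lower`, `upper` (cm^-1,
#'   intervals `(lower, upper]`).
#' @export
amide_class_boundaries <- function() {
  tibble(
    class = c("sheet", "random", "helix", "turn", "sheet"),
    lower = c(1600, 1640.5, 1645.5, 1664.5, 1680.5),
    upper = c(1640.5, 1645.5, 1664.5, 1680.5, 1700)
  )
}

#' Assign fitted bands to structure classes and quantify fractions
#'
#' Each fitted band is assigned a secondary-structure class by its centre
#' using the boundary table; class fractions are the class areas divided by
#' the total assigned area, in percent. Bands whose centres fall outside
#' the boundary table are excluded from the denominator with a warning.
#'
#' @param fit An `"amide_band_fit"` or a peaks tibble (`centre`, `width`,
#'   `area`).
#' @param boundaries Boundary table, see [amide_class_boundaries()].
#' @return An object of class `"secondary_structure"`: list with `peaks`
#'   (tibble incl. `class`), `fractions` (tibble `class`, `fraction` in %,
#'   all of helix/sheet/turn/random present) and `window`.
#' @export
ftir_assign_bands <- function(fit, boundaries = amide_class_boundaries()) {
  peaks <- if (inherits(fit, "amide_band_fit")) fit$peaks else as_tibble(fit)
  .assert(all(c("centre", "area") %in% names(peaks)),
          "`fit` must carry band centres and areas.")
  assign_one <- function(centre) {
    hit <- which(centre > boundaries$lower & centre <= boundaries$upper)
    if (length(hit) == 0) NA_character_ else boundaries$class[hit[1]]
  }
  peaks$class <- vapply(peaks$centre, assign_one, character(1))
  if (anyNA(peaks$class)) {
    warn(sprintf("%d band(s) outside the amide-I class boundaries were excluded.",
                 sum(is.na(peaks$class))))
  }
  assigned <- peaks[!is.na(peaks$class), ]
  total <- sum(assigned$area)
  .assert(total > 0, "No assignable band area.", class = "lyoglass_fit_failure")
  fractions <- assigned |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(fraction = 100 * sum(.data$area) / total) |>
    dplyr::ungroup()
  all_classes <- tibble(class = c("helix", "sheet", "turn", "random"))
  fractions <- dplyr::left_join(all_classes, fractions, by = "class") |>
    dplyr::mutate(fraction = dplyr::coalesce(.data$fraction, 0))
  structure(list(peaks = peaks, fractions = fractions,
                 window = if (inherits(fit, "amide_band_fit")) fit$window else NULL),
            class = "secondary_structure")
}

#' Full secondary-structure estimation chain
#'
#' Runs the complete amide-I analysis: optional scaled excipient
#' subtraction, total-area normalisation, Savitzky-Golay second derivative
#' over `sg_width`, band location from the fourth derivative,
#' `k`-Gaussian band fit inside the amide-I window, class assignment and
#' area-ratio fractions.
#'
#' @param sample Spectrum tibble (`wavenumber`, `absorbance`).
#' @param excipient Optional pure-excipient spectrum for subtraction.
#' @param anchor Excipient-subtraction anchor (cm^-1).
#' @param window Amide-I fit window (cm^-1).
#' @param sg_width,poly_order Savitzky-Golay parameters.
#' @param k Number of Gaussian bands.
#' @param boundaries Band-class boundary table.
#' @param ... Passed on to [ftir_fit_bands()].
#' @return A `"secondary_structure"` object, see [ftir_assign_bands()].
#' @export
#' @examples
#' s <- simulate_ftir(amide_band_template(), wavenumbers = seq(1580, 1720, 1))
#' est <- ftir_secondary_structure(s)
#' est$fractions
ftir_secondary_structure <- function(sample, excipient = NULL, anchor = 851,
                                     window = c(1600, 1700), sg_width = 14,
                                     poly_order = 3, k = 10,
                                     boundaries = amide_class_boundaries(),
                                     ...) {
  s <- sample
  if (!is.null(excipient)) {
    s <- ftir_subtract_excipient(s, excipient, anchor = anchor)
  }
  s <- ftir_normalize_area(s)
  cen0 <- ftir_locate_bands(s, window = window, sg_width = sg_width)
  d2 <- ftir_second_derivative(s, sg_width = sg_width, poly_order = poly_order)
  fit <- ftir_fit_bands(d2, k = k, window = window,
                        init_centres = if (length(cen0) > 0) cen0 else NULL,
                        ...)
  ftir_assign_bands(fit, boundaries = boundaries)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary-structure estimate (amide-I band deconvolution)\n")
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  %-7s %5.1f %%\n", x$fractions$class[i], x$fractions$fraction[i]))
  }
  invisible(x)
}

#' @export
print.amide_band_fit <- function(x, ...) {
  cat(sprintf("Amide-I band fit: %d Gaussians in %g-%g cm^-1, residual %.3g\n",
              nrow(x$peaks), x$window[1], x$window[2], x$residual_norm))
  print(x$peaks)
  invisible(x)
}
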