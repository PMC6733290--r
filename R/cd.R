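#' Subtract a blank (solvent) CD spectrum
#'
#' Pointwise subtraction of a water-blank spectrum recorded on the same
#' wavelength grid; accumulation metadata is carried from the sample.
#'
#' @param sample,blank Tibbles with `wavelength` (nm) and `ellipticity`
#'   (mdeg) on identical grids.
#' @return The blank-corrected spectrum.
#' @export
cd_subtract_blank <- function(sample, blank) {
  s <- .as_xy(sample, "wavelength", "ellipticity", "cd_subtract_blank")
  b <- .as_xy(blank, "wavelength", "ellipticity", "cd_subtract_blank")
  .assert(nrow(s) == nrow(b) && max(abs(s$wavelength - b$wavelength)) < 1e-9,
          "Sample and blank must share the same wavelength grid.",
          class = "lyoglass_grid_mismatch")
  out <- tibble(wavelength = s$wavelength,
                ellipticity = s$ellipticity - b$ellipticity)
  for (a in c("accumulations", "label")) {
    attr(out, a) <- attr(sample, a, exact = TRUE)
  }
  out
}

#' Average repeated CD accumulations
#'
#' Pointwise mean (and SD) of repeated spectra on a common grid; no outlier
#' rejection is applied.
#'
#' @param spectra List of spectra tibbles with identical wavelength grids.
#' @return A tibble with `wavelength`, `ellipticity` (mean) and `sd`, with
#'   attribute `accumulations` set to the number of spectra.
#' @export
cd_average <- function(spectra) {
  .assert(is.list(spectra) && length(spectra) >= 1, "Need at least one spectrum.")
  mats <- purrr::map(spectra, ~ .as_xy(.x, "wavelength", "ellipticity", "cd_average"))
  wl <- mats[[1]]$wavelength
  purrr::walk(mats, ~ .assert(max(abs(.x$wavelength - wl)) < 1e-9,
                              "All spectra must share the same grid.",
                              class = "lyoglass_grid_mismatch"))
  y <- vapply(mats, function(m) m$ellipticity, numeric(length(wl)))
  y <- matrix(y, nrow = length(wl))
  out <- tibble(wavelength = wl, ellipticity = rowMeans(y),
                sd = if (ncol(y) > 1) apply(y, 1, stats::sd) else rep(0, length(wl)))
  attr(out, "accumulations") <- length(spectra)
  out
}

#' Mean residue ellipticity
#'
#' Normalises observed ellipticity by path length, molar protein
#' concentration and residue count:
#' \deqn{[\theta](\lambda) = \frac{\theta_{obs}(\lambda)}{l \, c \, n},}
#' with the path length `l` in millimetres, `c` in molar and `n` the number
#' of amino-acid residues (583 for BSA, 1330 for mAb1). The millimetre
#' path-length convention embeds the usual factor of ten relative to
#' centimetre-based formulas, so the input units are recorded on the
#' result.
#'
#' @param spectrum Tibble with `wavelength` (nm) and `ellipticity` (mdeg).
#' @param path_mm Cuvette path length in mm (> 0).
#' @param conc_molar Molar protein concentration (> 0).
#' @param n_residues Number of residues (> 0).
#' @return A tibble with `wavelength` and `mre` (deg cm^2 dmol^-1), with
#'   the normalisation constants stored in attribute `"units"`.
#' @export
#' @examples
#' s <- simulate_cd(c(helix = 1))
#' mre <- cd_mean_residue_ellipticity(s, path_mm = 1, conc_molar = 3e-6,
#'                                    n_residues = 583)
cd_mean_residue_ellipticity <- function(spectrum, path_mm, conc_molar,
                                        n_residues) {
  s <- .as_xy(spectrum, "wavelength", "ellipticity", "cd_mean_residue_ellipticity")
  .assert(is.numeric(path_mm) && path_mm > 0, "`path_mm` must be positive.",
          class = "lyoglass_invalid_spec")
  .assert(is.numeric(conc_molar) && conc_molar > 0, "`conc_molar` must be positive.",
          class = "lyoglass_invalid_spec")
  .assert(is.numeric(n_residues) && n_residues > 0, "`n_residues` must be positive.",
          class = "lyoglass_invalid_spec")
  out <- tibble(wavelength = s$wavelength,
                mre = s$ellipticity / (path_mm * conc_molar * n_residues))
  attr(out, "units") <- list(path_mm = path_mm, conc_molar = conc_molar,
                             n_residues = n_residues,
                             convention = "theta_obs/(l[mm]*c[M]*n)")
  attr(out, "label") <- attr(spectrum, "label", exact = TRUE)
  out
}

#' Classify the gross secondary-structure signature of a CD spectrum
#'
#' `"helix-rich"` when the curve has local minima within 3 nm of both 222
#' and 208 nm and is positive near 193 nm (the canonical alpha-helix
#' double-minimum signature); `"sheet-rich"` when instead a single dominant
#' negative minimum sits within 4 nm of 218 nm; `"indeterminate"`
#' otherwise. The call is invariant under positive scaling of the signal.
#'
#' @param spectrum Tibble with `wavelength` plus `mre` (or `ellipticity`).
#' @return `"helix-rich"`, `"sheet-rich"` or `"indeterminate"`.
#' @export
cd_classify <- function(spectrum) {
  ycol <- if ("mre" %in% names(spectrum)) "mre" else "ellipticity"
  s <- .as_xy(spectrum, "wavelength", ycol, "cd_classify")
  wl <- s$wavelength
  y <- s[[ycol]]
  .assert(min(wl) <= 191 && max(wl) >= 225,
          "Spectrum must cover at least 191-225 nm.",
          class = "lyoglass_out_of_band")
  interior <- seq(2, length(y) - 1)
  is_min <- y[interior] < y[interior - 1] & y[interior] <= y[interior + 1] &
    y[interior] < 0
  min_wl <- wl[interior][is_min]
  has_min_near <- function(target, tol) any(abs(min_wl - target) <= tol)
  positive_193 <- max(y[abs(wl - 193) <= 2]) > 0
  if (has_min_near(222, 3) && has_min_near(208, 3) && positive_193) {
    return("helix-rich")
  }
  gmin <- which.min(y)
  if (y[gmin] < 0 && abs(wl[gmin] - 218) <= 4) {
    return("sheet-rich")
  }
  "indeterminate"
}
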