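#' Published three-region fit parameters for the study formulations
#'
#' Region slopes (with standard errors), transition temperatures from the
#' terahertz analysis, calorimetric glass transitions where measured, and
#' the qualitative mobility call reported for each of the nine lyophilised
#' systems (four BSA formulations, neat BSA, a sucrose/glycine excipient
#' mixture and three mAb1 formulations). These values serve as generator
#' ground truth for synthetic fixtures and as the reference against which
#' round-trip fits are checked.
#'
#' @return A tibble with one row per formulation and columns `formulation`,
#'   `protein`, `m1`, `m1_se`, `m2`, `m2_se`, `m3`, `m3_se` (cm^-1 K^-1),
#'   `tg_beta`, `tg_alpha`, `tg_dsc` (K) and `confined` (logical, the
#'   reported high-temperature plateau call).
#' @export
#' @examples
#' reference_transition_params()
reference_transition_params <- function() {
  tibble::tribble(
    ~formulation, ~protein, ~m1, ~m1_se, ~m2, ~m2_se, ~m3, ~m3_se,
    ~tg_beta, ~tg_alpha, ~tg_dsc, ~confined,
    "F1", "BSA", 0.033, 0.00059, 0.062, 0.0018, 0.021, 0.0036, 262, 336, 310, TRUE,
    "F2", "BSA", 0.021, 0.0020, 0.054, 0.0028, 0.023, 0.0027, 219, 339, 311, TRUE,
    "F3", "BSA", 0.027, 0.0091, 0.074, 0.0016, 0.0051, 0.0028, 217, 318, 302, TRUE,
    "F4", "BSA", 0.00014, 0.0017, 0.028, 0.0011, 0.048, 0.0014, 205, 298, 305, FALSE,
    "Neat BSA", "BSA", 0.034, 0.0031, 0.071, 0.0017, 0.12, 0.0023, 216, 331, NA, FALSE,
    "Sucrose/glycine", "none", 0.011, 0.0014, 0.047, 0.0021, 0.070, 0.0018, 220, 303, NA, FALSE,
    "F5", "mAb1", 0.00056, 0.0050, 0.061, 0.0020, 0.020, 0.011, 151, 272, 282, FALSE,
    "F6", "mAb1", 0.0033, 0.0034, 0.023, 0.00087, 0.053, 0.0021, 135, 262, 297, FALSE,
    "F7", "mAb1", 0.0038, 0.0047, 0.067, 0.0011, 0.020, 0.0046, 168, 334, 304, TRUE
  )
}

#' Compositions of the study formulations
#'
#' Long-format component table for the seven lyophilised formulations (F1–F7)
#' plus the sucrose/glycine excipient mixture.
#'
#' @return A tibble with columns `formulation`, `protein`, `component`,
#'   `concentration` and `unit`.
#' @export
formulation_compositions <- function() {
  tibble::tribble(
    ~formulation, ~protein, ~component, ~concentration, ~unit,
    "F1", "BSA", "BSA", 2.3, "mM",
    "F1", "BSA", "histidine-HCl", 25, "mM",
    "F1", "BSA", "sucrose", 265, "mM",
    "F2", "BSA", "BSA", 1.1, "mM",
    "F2", "BSA", "histidine-HCl", 25, "mM",
    "F2", "BSA", "sucrose", 265, "mM",
    "F3", "BSA", "BSA", 1.5, "mM",
    "F3", "BSA", "histidine-HCl", 25, "mM",
    "F3", "BSA", "trehalose", 130, "mM",
    "F3", "BSA", "arginine-HCl", 50, "mM",
    "F3", "BSA", "polysorbate 80", 1.7, "uM",
    "F4", "BSA", "BSA", 1.1, "mM",
    "F4", "BSA", "histidine-HCl", 25, "mM",
    "F4", "BSA", "sucrose", 265, "mM",
    "F4", "BSA", "polysorbate 80", 3.3, "uM",
    "F5", "mAb1", "mAb1", 0.28, "mM",
    "F5", "mAb1", "histidine-HCl", 25, "mM",
    "F5", "mAb1", "sucrose", 205, "mM",
    "F6", "mAb1", "mAb1", 0.49, "mM",
    "F6", "mAb1", "histidine-HCl", 25, "mM",
    "F6", "mAb1", "sucrose", 265, "mM",
    "F7", "mAb1", "mAb1", 0.49, "mM",
    "F7", "mAb1", "histidine-HCl", 25, "mM",
    "F7", "mAb1", "sucrose", 265, "mM",
    "F7", "mAb1", "polysorbate 80", 3.3, "uM",
    "Sucrose/glycine", "none", "sucrose", 234, "mM",
    "Sucrose/glycine", "none", "glycine", 533, "mM"
  )
}
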