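Package: lyoglass
Title: Molecular Mobility and Structure of Lyophilised Protein Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising the molecular mobility and
    structure of freeze-dried (lyophilised) protein formulations from
    spectroscopic measurements. Extracts frequency-dependent optical constants
    (refractive index, absorption coefficient) from terahertz time-domain
    waveform pairs; fits the three-temperature-region linear model to the
    absorption coefficient at 1 THz to locate the lower (beta) and upper
    (alpha) glass transitions and classify high-temperature confinement of
    molecular mobility; estimates protein secondary structure from amide-I
    infrared spectra by Savitzky-Golay second-derivative Gaussian band
    deconvolution; computes circular-dichroism mean residue ellipticity and
    gross structural signatures; and fits inversion-recovery (T1) and
    spin-lock (T1rho) solid-state NMR relaxation series to assess
    protein-sugar phase homogeneity. A synthetic-data module generates every
    input modality with known ground truth so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
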