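#' Analysis configuration with study-faithful defaults
#'
#' Collects every tunable analysis constant in one validated list: the
#' terahertz probe frequency and averaging half-window, segmentation
#' settings, the amide-I window and Savitzky-Golay parameters, the
#' excipient anchor, band count, class boundaries, the homogeneity
#' significance multiple and the residual-moisture QC threshold.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `"lyoglass_config"`.
#' @export
#' @examples
#' cfg <- lyoglass_config(probe_window = 0.1)
lyoglass_config <- function(...) {
  cfg <- list(
    probe_frequency = 1.0,     # THz
    probe_window = 0.05,       # THz half-width
    taper = 0,
    noise_floor = 0.01,
    min_pts = 3,
    ratio_threshold = 1,
    amide_window = c(1600, 1700),  # cm^-1
    sg_width = 14,             # cm^-1
    poly_order = 3,
    k_bands = 10,
    anchor = 851,              # cm^-1
    homogeneity_z = 2,
    moisture_threshold = 2.5   # % w/w
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  .assert(length(unknown) == 0,
          sprintf("Unknown config keys: %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  .assert(cfg$probe_frequency > 0 && cfg$probe_window >= 0 &&
            cfg$min_pts >= 2 && cfg$k_bands >= 1 &&
            cfg$moisture_threshold > 0 && cfg$homogeneity_z > 0 &&
            length(cfg$amide_window) == 2 &&
            cfg$amide_window[1] < cfg$amide_window[2],
          "Invalid configuration values.")
  structure(cfg, class = "lyoglass_config")
}

#' Residual-moisture quality-control gate
#'
#' Lyophilised vials are acceptable when their residual moisture is
#' strictly below the threshold (2.5 % w/w by default). Failing records
#' are still analysed downstream but carry a failing QC status; missing
#' moisture produces an `"unknown"` status with a warning.
#'
#' @param moisture Residual moisture in % w/w (vectorised; `NA` allowed).
#' @param threshold Threshold in % w/w; the comparison is strict (`<`).
#' @return Character vector of `"pass"`, `"fail"` or `"unknown"`.
#' @export
#' @examples
#' qc_moisture(c(2.4, 2.5, NA))
qc_moisture <- function(moisture, threshold = 2.5) {
  .assert(threshold > 0, "`threshold` must be positive.")
  if (anyNA(moisture)) {
    warn("Missing residual moisture: record passed through with status 'unknown'.")
  }
  dplyr::case_when(
    is.na(moisture) ~ "unknown",
    moisture < threshold ~ "pass",
    TRUE ~ "fail"
  )
}

#' Run all available analyses for one formulation
#'
#' Orchestrates a per-formulation run: the moisture QC gate, then every
#' analysis stage for which input data are supplied — terahertz
#' transition analysis, FTIR secondary structure, CD classification and
#' NMR relaxation with phase-homogeneity calls. A failure in one stage is
#' recorded in the report's `errors` field and never aborts the other
#' stages; given fixed inputs and config the report is deterministic.
#'
#' @param record Formulation metadata: a list (or one-row data frame) with
#'   at least `label`; optionally `protein`, `moisture` (% w/w) and
#'   `tg_dsc` (K).
#' @param inputs Named list of stage inputs, all optional but at least one
#'   present:
#'   * `thz_series`: temperature series for [fit_three_regions()];
#'   * `ftir`: list with `sample` and optional `excipient` spectra;
#'   * `cd`: list with `sample`, optional `blank`, and `path_mm`,
#'     `conc_molar`, `n_residues`;
#'   * `nmr`: list with optional `t1` and `t1rho`, each a list with
#'     `protein` and `sugar` relaxation series.
#' @param config A [lyoglass_config()] list.
#' @return An object of class `"formulation_report"`: list with `label`,
#'   `qc` (status + moisture), `transitions` (one-row tibble or NULL),
#'   `secondary_structure` (fractions tibble or NULL), `cd_class`,
#'   `relaxation` (per-fit tibble), `homogeneity` (per-kind tibble),
#'   `errors` (named list) and `config`. The underlying fit objects are
#'   attached as attribute `"fits"`.
#' @export
run_formulation <- function(record, inputs, config = lyoglass_config()) {
  record <- as.list(record)
  .assert(!is.null(record$label), "`record` must carry a `label`.")
  .assert(is.list(inputs) && length(inputs) > 0 &&
            any(!vapply(inputs, is.null, logical(1))),
          "At least one stage input must be present.",
          class = "lyoglass_no_inputs")
  errors <- list()
  fits <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  qc <- list(moisture = record$moisture %||% NA_real_)
  qc$status <- suppressWarnings(
    qc_moisture(qc$moisture, threshold = config$moisture_threshold)
  )

  transitions <- NULL
  if (!is.null(inputs$thz_series)) {
    fit <- stage("transitions",
                 fit_three_regions(inputs$thz_series,
                                    min_pts = config$min_pts,
                                    ratio_threshold = config$ratio_threshold,
                                    label = record$label))
    if (!is.null(fit)) {
      fits$transitions <- fit
      transitions <- tabulate_transitions(list(fit), labels = record$label)
    }
  }

  structure_est <- NULL
  if (!is.null(inputs$ftir)) {
    est <- stage("ftir",
                 ftir_secondary_structure(inputs$ftir$sample,
                                           excipient = inputs$ftir$excipient,
                                           anchor = config$anchor,
                                           window = config$amide_window,
                                           sg_width = config$sg_width,
                                           poly_order = config$poly_order,
                                           k = config$k_bands))
    if (!is.null(est)) {
      fits$ftir <- est
      structure_est <- est$fractions
    }
  }

  cd_class <- NULL
  if (!is.null(inputs$cd)) {
    cd_res <- stage("cd", {
      s <- inputs$cd$sample
      if (!is.null(inputs$cd$blank)) s <- cd_subtract_blank(s, inputs$cd$blank)
      mre <- cd_mean_residue_ellipticity(s, inputs$cd$path_mm,
                                         inputs$cd$conc_molar,
                                         inputs$cd$n_residues)
      list(mre = mre, class = cd_classify(mre))
    })
    if (!is.null(cd_res)) {
      fits$cd <- cd_res$mre
      cd_class <- cd_res$class
    }
  }

  relaxation <- NULL
  homogeneity <- NULL
  if (!is.null(inputs$nmr)) {
    res <- stage("nmr", {
      rows <- list()
      hom <- list()
      nmr_fits <- list()
      for (kind in intersect(c("t1", "t1rho"), names(inputs$nmr))) {
        pair <- inputs$nmr[[kind]]
        fitter <- if (kind == "t1") fit_t1 else fit_t1rho
        pf <- fitter(pair$protein)
        sf <- fitter(pair$sugar)
        nmr_fits[[kind]] <- list(protein = pf, sugar = sf)
        rows[[kind]] <- tibble(
          kind = kind, component = c("protein", "sugar"),
          time_constant = c(pf$time_constant, sf$time_constant),
          se = c(pf$se, sf$se)
        )
        hom[[kind]] <- nmr_phase_homogeneity(pf, sf, z = config$homogeneity_z)
      }
      list(relaxation = dplyr::bind_rows(rows),
           homogeneity = dplyr::bind_rows(hom),
           fits = nmr_fits)
    })
    if (!is.null(res)) {
      relaxation <- res$relaxation
      homogeneity <- res$homogeneity
      fits <- c(fits, res$fits)
    }
  }

  report <- structure(list(
    label = record$label,
    protein = record$protein %||% NA_character_,
    qc = qc,
    transitions = transitions,
    secondary_structure = structure_est,
    cd_class = cd_class,
    relaxation = relaxation,
    homogeneity = homogeneity,
    errors = errors,
    config = unclass(config)
  ), class = "formulation_report")
  attr(report, "fits") <- fits
  report
}

#' Cross-formulation study summary
#'
#' One row per report with the three-region fit parameters, transition
#' temperatures, mobility class and QC status; optional stages appear as
#' `NA` where absent. Repeated labels are suffixed deterministically.
#'
#' @param reports List of `"formulation_report"` objects (a single report
#'   is accepted).
#' @return A tibble.
#' @export
summarise_study <- function(reports) {
  if (inherits(reports, "formulation_report")) reports <- list(reports)
  .assert(length(reports) >= 1, "Need at least one report.")
  rows <- purrr::map_dfr(reports, function(r) {
    .assert(inherits(r, "formulation_report"),
            "All elements must be formulation_report objects.")
    tr <- r$transitions
    helix <- sheet <- NA_real_
    if (!is.null(r$secondary_structure)) {
      fr <- r$secondary_structure
      helix <- fr$fraction[fr$class == "helix"]
      sheet <- fr$fraction[fr$class == "sheet"]
    }
    tibble(
      formulation = r$label,
      m1 = tr$m1 %||% NA_real_, m1_se = tr$m1_se %||% NA_real_,
      m2 = tr$m2 %||% NA_real_, m2_se = tr$m2_se %||% NA_real_,
      m3 = tr$m3 %||% NA_real_, m3_se = tr$m3_se %||% NA_real_,
      tg_beta = tr$tg_beta %||% NA_real_, tg_alpha = tr$tg_alpha %||% NA_real_,
      mobility = tr$mobility %||% NA_character_,
      helix_pct = helix, sheet_pct = sheet,
      cd_class = r$cd_class %||% NA_character_,
      qc_status = r$qc$status,
      n_errors = length(r$errors)
    )
  })
  rows$formulation <- make.unique(rows$formulation, sep = "_")
  rows
}

#' Serialise a formulation report to JSON
#'
#' The report's tabular and atomic fields serialise losslessly;
#' [report_from_json()] restores an equivalent report (serialise-parse-
#' serialise is the identity).
#'
#' @param report A `"formulation_report"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  .assert(inherits(report, "formulation_report"), "Not a formulation report.")
  payload <- unclass(report)
  payload$errors <- if (length(payload$errors) == 0) {
    stats::setNames(list(), character())
  } else payload$errors
  js <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a formulation report from JSON
#'
#' @param json A JSON string or path produced by [report_to_json()].
#' @return A `"formulation_report"` object.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (f in c("transitions", "secondary_structure", "relaxation", "homogeneity")) {
    if (!is.null(x[[f]])) x[[f]] <- as_tibble(as.data.frame(x[[f]]))
  }
  x$errors <- as.list(x$errors)
  if (!is.null(x$config$amide_window)) {
    x$config$amide_window <- as.numeric(x$config$amide_window)
  }
  structure(x, class = "formulation_report")
}

#' @export
print.formulation_report <- function(x, ...) {
  cat(sprintf("Formulation report: %s (QC %s)\n", x$label, x$qc$status))
  if (!is.null(x$transitions)) {
    cat(sprintf("  Tg,beta %.0f K | Tg,alpha %.0f K | mobility %s\n",
                x$transitions$tg_beta, x$transitions$tg_alpha,
                x$transitions$mobility))
  }
  if (!is.null(x$secondary_structure)) {
    fr <- x$secondary_structure
    cat("  structure:",
        paste(sprintf("%s %.0f%%", fr$class, fr$fraction), collapse = ", "), "\n")
  }
  if (!is.null(x$cd_class)) cat("  CD signature:", x$cd_class, "\n")
  if (!is.null(x$homogeneity)) {
    for (i in seq_len(nrow(x$homogeneity))) {
      cat(sprintf("  %s (%s): %s\n", x$homogeneity$kind[i],
                  x$homogeneity$length_scale[i], x$homogeneity$call[i]))
    }
  }
  if (length(x$errors) > 0) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
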