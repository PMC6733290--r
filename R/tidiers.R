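#' Tidy a three-region fit
#'
#' One row per temperature region with slope, intercept and standard
#' errors.
#'
#' @param x A `"three_region_fit"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.three_region_fit <- function(x, ...) {
  x$regions
}

#' Glance at a three-region fit
#'
#' @param x A `"three_region_fit"`.
#' @param ... Unused.
#' @return A one-row tibble with `tg_beta`, `tg_alpha`, `mobility`, `sse`,
#'   `n`, `weighted`.
#' @exportS3Method generics::glance
glance.three_region_fit <- function(x, ...) {
  tibble(tg_beta = x$tg_beta, tg_alpha = x$tg_alpha, mobility = x$mobility,
         sse = x$sse, n = nrow(x$data), weighted = x$weighted)
}

#' Tidy a relaxation fit
#'
#' @param x A `"relaxation_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @exportS3Method generics::tidy
tidy.relaxation_fit <- function(x, ...) {
  terms <- c("m0", if (x$kind == "t1") "a",
             if (x$kind == "t1") "t1" else "t1rho")
  est <- c(x$m0, if (x$kind == "t1") x$a, x$time_constant)
  se <- c(x$m0_se, if (x$kind == "t1") x$a_se, x$se)
  tibble(term = terms, estimate = est, std.error = se)
}

#' Glance at a relaxation fit
#'
#' @param x A `"relaxation_fit"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.relaxation_fit <- function(x, ...) {
  tibble(kind = x$kind, time_constant = x$time_constant, se = x$se,
         residual_norm = x$residual_norm, n = x$n,
         component = x$component %||% NA_character_)
}

#' Tidy a secondary-structure estimate
#'
#' @param x A `"secondary_structure"`.
#' @param ... Unused.
#' @return The class-fraction tibble (`class`, `fraction` in %).
#' @exportS3Method generics::tidy
tidy.secondary_structure <- function(x, ...) {
  x$fractions
}

#' Tidy an amide band fit
#'
#' @param x An `"amide_band_fit"`.
#' @param ... Unused.
#' @return The fitted-peak tibble.
#' @exportS3Method generics::tidy
tidy.amide_band_fit <- function(x, ...) {
  x$peaks
}
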