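#' Plot a three-region fit
#'
#' Absorption versus temperature with the three fitted lines drawn over
#' their regions and the two transition temperatures marked.
#'
#' @param object A `"three_region_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.three_region_fit <- function(object, ...) {
  seg <- object$regions |>
    dplyr::mutate(y_min = .data$intercept + .data$slope * .data$t_min,
                  y_max = .data$intercept + .data$slope * .data$t_max,
                  region = factor(.data$region))
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$temperature, y = .data$absorption)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_min, xend = .data$t_max,
                   y = .data$y_min, yend = .data$y_max,
                   colour = .data$region),
      linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = c(object$tg_beta, object$tg_alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Temperature (K)",
      y = expression(alpha ~ "at 1 THz (" * cm^-1 * ")"),
      colour = "Region",
      title = object$label %||% "Three-region absorption fit",
      subtitle = sprintf("Tg,beta = %.0f K, Tg,alpha = %.0f K (%s)",
                         object$tg_beta, object$tg_alpha, object$mobility)
    ) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(object$data) && any(object$data$sd > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$absorption - .data$sd,
                   ymax = .data$absorption + .data$sd),
      width = 0, alpha = 0.4
    )
  }
  p
}

#' Plot an amide-I band fit
#'
#' Second-derivative trace with the fitted total model and the individual
#' band components.
#'
#' @param object An `"amide_band_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.amide_band_fit <- function(object, ...) {
  x <- object$d2$wavenumber
  sg <- object$sg
  n_win <- round(sg$sg_width / sg$dx) + 1
  if (n_win %% 2 == 0) n_win <- n_win + 1
  half <- (n_win - 1) / 2
  xe <- seq(min(x) - half * sg$dx, max(x) + half * sg$dx, by = sg$dx)
  idx <- seq(half + 1, length(xe) - half)
  comp <- purrr::imap_dfr(seq_len(nrow(object$peaks)), function(i, ...) {
    p <- object$peaks[i, ]
    prof <- signal::sgolayfilt(p$amplitude * exp(-(xe - p$centre)^2 / (2 * p$width^2)),
                               p = sg$poly_order, n = n_win, m = 2, ts = sg$dx)
    tibble(wavenumber = x, band = factor(i), d2 = prof[idx])
  })
  total <- tibble(wavenumber = x, d2 = object$d2$fitted)
  ggplot2::ggplot(object$d2, ggplot2::aes(x = .data$wavenumber, y = .data$d2)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(colour = .data$band), alpha = 0.6,
                       show.legend = FALSE) +
    ggplot2::geom_line(data = total, colour = "red", linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression("Wavenumber (" * cm^-1 * ")"),
                  y = "Second derivative (a.u.)",
                  title = "Amide-I band deconvolution") +
    ggplot2::theme_minimal()
}

#' Plot a relaxation fit
#'
#' Measured magnetisation versus delay with the fitted model curve.
#'
#' @param object A `"relaxation_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.relaxation_fit <- function(object, ...) {
  grid <- tibble(delay = seq(min(object$data$delay), max(object$data$delay),
                             length.out = 200))
  grid$magnetisation <- if (object$kind == "t1") {
    object$m0 * (1 - 2 * object$a * exp(-grid$delay / object$time_constant))
  } else {
    object$m0 * exp(-grid$delay / object$time_constant)
  }
  lbl <- if (object$kind == "t1") "T1" else "T1rho"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$delay, y = .data$magnetisation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Delay (s)", y = "Integrated magnetisation (a.u.)",
                  title = sprintf("%s fit: %.3g s (SE %.2g)", lbl,
                                  object$time_constant, object$se)) +
    ggplot2::theme_minimal()
}

#' Plot a secondary-structure estimate
#'
#' Bar chart of the class area fractions.
#'
#' @param object A `"secondary_structure"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.secondary_structure <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Area fraction (%)",
                  title = "Secondary-structure composition") +
    ggplot2::theme_minimal()
}
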