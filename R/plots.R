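# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a design-space sweep as a sensitivity surface
#'
#' Tile map of the per-cell maximal sensitivity over (m_spl, n_uc), with
#' the reported best cell outlined.
#'
#' @param object A [sweep_design_space()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sipm_design_sweep <- function(object, ...) {
  best <- attr(object, "best")
  df <- dplyr::filter(tidy(object), .data$feasible)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$m_spl), factor(.data$n_uc),
                                   fill = 100 * .data$s_opt)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::semi_join(df, best,
                                               by = c("n_uc", "m_spl")),
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "max S (%)") +
    ggplot2::labs(x = "subpixels per pixel (m_spl)",
                  y = "SPADs per microcell (n_uc)") +
    ggplot2::theme_minimal()
}

#' Plot a multiplicity histogram
#'
#' @param object A [simulate_first_n_multiplicity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sipm_multiplicity <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(factor(.data$multiplicity),
                               .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("distinct pixels among first %d detected photons",
                  object$params$n_first),
      y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a yield-versus-area curve
#'
#' @param curve A [yield_curve()] tibble.
#' @return A ggplot with percentile ribbon.
#' @export
plot_yield_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$a_aspad_um2, .data$yield)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "SPAD active area (um^2)", y = "yield") +
    ggplot2::theme_minimal()
}

#' Plot a counted-photon response curve
#'
#' @param curve A [response_curve()] tibble (optionally with a
#'   [simulate_event_response()] overlay passed as `mc`).
#' @param mc Optional tibble with columns `n_ph`, `n_out`, `se`.
#' @return A ggplot.
#' @export
plot_response_curve <- function(curve, mc = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$n_ph, .data$n_out)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "incident photons", y = "counted photons") +
    ggplot2::theme_minimal()
  if (!is.null(mc)) {
    p <- p + ggplot2::geom_pointrange(
      data = mc,
      ggplot2::aes(ymin = .data$n_out - 3 * .data$se,
                   ymax = .data$n_out + 3 * .data$se),
      colour = "firebrick", size = 0.3)
  }
  p
}
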