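#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gamma diffusivity fit: ADC versus flip angle
#'
#' Observed values (ADC or attenuation, per the fit target) with the fitted
#' gamma-model curve overlaid.
#'
#' @param object A `dwssfp_gamma_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dwssfp_gamma_fit
#' @export
autoplot.dwssfp_gamma_fit <- function(object, ...) {
  lab <- if (object$fit_target == "adc") "ADC (mm²/s)" else
    "attenuation S(q)/S(0)"
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$flip_deg)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "#2b6cb0") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       colour = "#dd6b20", linetype = "dashed") +
    ggplot2::labs(x = "flip angle (deg)", y = lab,
                  title = sprintf("Gamma fit: Dm = %.3g, Ds = %.3g mm²/s",
                                  object$dm, object$ds)) +
    ggplot2::theme_minimal()
}

#' Plot a translation result: ADC versus effective b-value
#'
#' The DW-SSFP ADC estimates placed at their equivalent DW-SE b-values, with
#' the analytic DW-SE ADC(b) curve of the fitted gamma distribution.
#'
#' @param object A `dwssfp_beff`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dwssfp_beff
#' @export
autoplot.dwssfp_beff <- function(object, ...) {
  g <- gamma_diffusivity(object$fit$dm, object$fit$ds)
  grid <- tibble::tibble(
    b = seq(0, max(object$per_flip$b_eff) * 1.05 + 1, length.out = 200))
  grid$adc <- adc_se_gamma(grid$b, g)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$b, y = .data$adc),
                       colour = "grey40") +
    ggplot2::geom_point(data = object$per_flip,
                        ggplot2::aes(x = .data$b_eff, y = .data$adc,
                                     colour = .data$flip_deg)) +
    ggplot2::scale_colour_viridis_c(name = "flip (deg)") +
    ggplot2::labs(x = "effective b-value (s/mm²)", y = "ADC (mm²/s)",
                  title = "DW-SSFP ADC at equivalent DW-SE b-values") +
    ggplot2::theme_minimal()
}

#' Plot coherence-pathway amplitudes
#'
#' Pathway contributions of the two-transverse-period model versus flip
#' angle, absolute or normalized to the spin-echo pathway; the normalized
#' view shows how low flip angles weight long-diffusion-time pathways.
#'
#' @param p An [ssfp_protocol()].
#' @param tis A [tissue()].
#' @param n_max Largest stimulated-echo order shown.
#' @param normalize Normalize to the spin-echo pathway.
#' @param flip_deg Optional flip grid (degrees); defaults to 1-179.
#' @return A ggplot.
#' @export
plot_pathway_amplitudes <- function(p, tis, n_max = 6, normalize = FALSE,
                                    flip_deg = NULL) {
  flips <- flip_deg %||% seq(1, 179, by = 2)
  amps <- ssfp_pathway_amplitudes(p, tis, n_max = n_max, flip_deg = flips)
  amps$value <- if (normalize) amps$normalized else amps$amplitude
  amps$pathway <- factor(
    ifelse(amps$n == 0, "spin echo (Δ = TR)",
           sprintf("stim. echo n = %d (Δ = %d TR)", amps$n, amps$n + 1)),
    levels = c("spin echo (Δ = TR)",
               sprintf("stim. echo n = %d (Δ = %d TR)", seq_len(n_max),
                       seq_len(n_max) + 1)))
  ggplot2::ggplot(amps, ggplot2::aes(x = .data$flip_deg, y = .data$value,
                                     colour = .data$pathway)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flip angle (deg)",
                  y = if (normalize) "amplitude / spin-echo amplitude" else
                    "pathway amplitude (signal units)") +
    ggplot2::theme_minimal()
}
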