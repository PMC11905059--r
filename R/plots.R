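#' Plot a normalized tuning curve
#'
#' Mean coupling (normalized to the joint maximum) against orientation, one
#' line per stimulus type, with +/- 1 trial-SD ribbons on the same scale.
#'
#' @param tc a `tuning_curve` from [tuning_curves()].
#' @return a ggplot object.
#' @export
plot_tuning_curve <- function(tc) {
  nf <- attr(tc, "norm_factor")
  pair <- attr(tc, "pair")
  d <- as.data.frame(tc)
  d$se <- d$sd / nf
  ggplot2::ggplot(d, ggplot2::aes(x = .data$orientation_deg, y = .data$norm,
                                  colour = .data$stimulus_type,
                                  fill = .data$stimulus_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$norm - .data$se,
                                      ymax = .data$norm + .data$se),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(d$orientation_deg)) +
    ggplot2::labs(x = "orientation (deg)",
                  y = sprintf("%s (normalized to max)", attr(tc, "kind")),
                  colour = "stimulus", fill = "stimulus",
                  title = sprintf("%s–%s %s tuning", pair[1], pair[2],
                                  attr(tc, "kind"))) +
    ggplot2::theme_minimal()
}

#' Plot a band-pair selectivity heatmap
#'
#' -log10 orientation p-value per band pair (lower band on the x axis),
#' selective pairs outlined.
#'
#' @param report a `selectivity_report` from [anova_screen()].
#' @param effect "orientation" or "stimulus".
#' @return a ggplot object.
#' @export
plot_selectivity_heatmap <- function(report, effect = c("orientation", "stimulus")) {
  effect <- match.arg(effect)
  d <- as.data.frame(report)
  d$p <- d[[paste0("p_", effect)]]
  d$sel <- d[[paste0("selective_", effect)]]
  labs <- canonical_bands()$label
  d$low_band <- factor(d$low_band, levels = labs)
  d$high_band <- factor(d$high_band, levels = rev(labs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$low_band, y = .data$high_band,
                                  fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$sel, , drop = FALSE], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "lower band (phase / first envelope)",
                  y = "higher band (amplitude / second envelope)",
                  fill = expression(-log[10](p)),
                  title = sprintf("%s %s selectivity", d$kind[1], effect)) +
    ggplot2::theme_minimal()
}
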