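# Presentation helpers.  Figures are purely cosmetic wrappers over the
# model functions; all numbers come from upstream computations.

#' Adsorption isotherms for several repulsion strengths
#'
#' Plots normalised adsorption versus normalised bulk concentration for each
#' supplied repulsion strength; weaker repulsion sits uppermost and bends
#' away from linearity first (the cooperative-clustering signature).
#'
#' @param e_r_values Vector of positive repulsion strengths.
#' @param Cs_grid Positive concentration grid.
#' @param log_y Plot the adsorption axis on a log scale.
#' @return A ggplot object (invisibly `NULL` with a warning on empty input).
#' @export
plot_isotherms <- function(e_r_values, Cs_grid = seq(0.05, 2, by = 0.05),
                           log_y = FALSE) {
  if (length(e_r_values) == 0L || length(Cs_grid) == 0L) {
    warning("empty input: nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  df <- do.call(rbind, lapply(e_r_values, function(er) {
    data.frame(C_s = Cs_grid,
               C_v = vapply(Cs_grid, adsorption, 0, e_r = er),
               e_r = factor(er))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$C_s, y = .data$C_v,
                                        colour = .data$e_r)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(C[s]), y = expression(C[v]),
                  colour = expression(e[r])) +
    ggplot2::theme_classic()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Mean cluster size versus concentration
#'
#' Companion inset to [plot_isotherms()]: number-weighted mean cluster size
#' against bulk concentration for each repulsion strength.
#'
#' @inheritParams plot_isotherms
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(e_r_values, Cs_grid = seq(0.05, 2, by = 0.05)) {
  if (length(e_r_values) == 0L || length(Cs_grid) == 0L) {
    warning("empty input: nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  df <- do.call(rbind, lapply(e_r_values, function(er) {
    data.frame(C_s = Cs_grid,
               mean_size = vapply(Cs_grid, mean_cluster_size, 0, e_r = er),
               e_r = factor(er))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$C_s, y = .data$mean_size,
                                   colour = .data$e_r)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(C[s]), y = "mean cluster size",
                  colour = expression(e[r])) +
    ggplot2::theme_classic()
}

#' Localization fraction versus total adsorption
#'
#' The two-region localization figure: fraction of bound protein in the
#' high-curvature region against (log) total adsorption, with the per-region
#' mean cluster sizes available as a companion via `what = "sizes"`.
#'
#' @param curve A [localization_curve()] data frame.
#' @param what `"fraction"` (default) or `"sizes"`.
#' @return A ggplot object (invisibly `NULL` with a warning on empty input).
#' @export
plot_localization <- function(curve, what = c("fraction", "sizes")) {
  what <- match.arg(what)
  if (is.null(curve) || nrow(curve) == 0L) {
    warning("empty input: nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  if (what == "fraction") {
    ggplot2::ggplot(curve, ggplot2::aes(x = .data$total_adsorption,
                                        y = .data$fraction_1)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "total adsorption",
                    y = "fraction in high-curvature region") +
      ggplot2::theme_classic()
  } else {
    df <- rbind(
      data.frame(total_adsorption = curve$total_adsorption,
                 mean_size = curve$mean_size_1, region = "region 1"),
      data.frame(total_adsorption = curve$total_adsorption,
                 mean_size = curve$mean_size_2, region = "region 2"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$total_adsorption,
                                     y = .data$mean_size,
                                     linetype = .data$region)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "total adsorption", y = "mean cluster size") +
      ggplot2::theme_classic()
  }
}
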