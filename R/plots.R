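#' Additive-space view of a network ensemble
#'
#' Scatter of each network's additive Sobol sum (S0, x) against its
#' non-additive sum (epsT, y); point size encodes the median-normalised
#' two-component positive-feedback count when available, and networks above
#' the 80th percentile of epsT are highlighted.
#'
#' @param ensemble Result of [run_ensemble()] (or its `$table`).
#' @return A ggplot object.
#' @export
plot_additive_space <- function(ensemble) {
  tbl <- if (is.data.frame(ensemble)) ensemble else ensemble$table
  eps80 <- if (is.data.frame(ensemble)) {
    quantile(tbl$eps_sum, 0.8, names = FALSE)
  } else ensemble$eps80
  tbl$high_eps <- tbl$eps_sum > eps80
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$s0_sum,
                                         y = .data$eps_sum,
                                         colour = .data$high_eps))
  p <- if (all(is.na(tbl$n_pos_two_cycles_norm))) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$n_pos_two_cycles_norm),
                            alpha = 0.8) +
      ggplot2::labs(size = "positive feedbacks\n(/ ensemble median)")
  }
  p +
    ggplot2::geom_hline(yintercept = eps80, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "forestgreen"),
                                 guide = "none") +
    ggplot2::labs(x = expression(S[0] ~ "(additive sum)"),
                  y = expression(epsilon[T] ~ "(non-additive sum)"),
                  title = "Additive space of the network ensemble") +
    ggplot2::theme_minimal()
}

#' Heatmap of the cross-condition transfer matrix
#'
#' Tile plot of normalised transfer R^2 (train condition rows, test
#' condition columns); cells with negative raw R^2 — transfers worse than
#' the test-population mean — are blanked to white.
#'
#' @param sweep Result of [run_variation_sweep()] (or its `$transfer`).
#' @return A ggplot object.
#' @export
plot_transfer_matrix <- function(sweep) {
  tbl <- if (is.data.frame(sweep)) sweep else sweep$transfer
  tbl$fill <- ifelse(tbl$r2 < 0, NA_real_, tbl$r2_normalized)
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$test_sd),
                                    y = factor(.data$train_sd),
                                    fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "normalised R²") +
    ggplot2::labs(x = "test condition (s.d.)", y = "training condition (s.d.)",
                  title = "Polygenic-score transferability across variation regimes") +
    ggplot2::theme_minimal()
}

#' @describeIn sobol_indices Bar chart of per-edge additive (S0) and
#'   non-additive (epsT) indices.
#' @param object A `sobol_result`.
#' @export
autoplot.sobol_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$indices[, c("edge", "s0", "eps")],
                            c("s0", "eps"), names_to = "component",
                            values_to = "index")
  df$component <- factor(df$component, c("s0", "eps"),
                         labels = c("additive (S0)", "non-additive (epsT)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edge, y = .data$index,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "regulatory connection", y = "Sobol index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
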