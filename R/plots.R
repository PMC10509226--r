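#' Plot a motif enrichment profile
#'
#' Bar chart of per-pattern z-scores with the significance threshold drawn
#' as a dashed line, in the style of a motif-census panel.
#'
#' @param object A `motif_enrichment` table from [motif_significance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$z_plot <- ifelse(is.finite(d$z), d$z, NA_real_)
  thr <- attr(object, "z_threshold")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pattern_id, y = .data$z_plot,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::facet_wrap(~k, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "circuit pattern", y = "z-score vs. rewired null") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a phase portrait
#'
#' Draws the basins of attraction (when computed), nullclines and fixed
#' points of a circuit on the log-scale phase plane: stable points filled,
#' semi-stable half-tone, unstable open.
#'
#' @param object A `phase_portrait` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_portrait <- function(object, ...) {
  fp <- object$fixed_points
  nc <- dplyr::filter(object$nullclines, .data$branch != "axis")
  g <- ggplot2::ggplot()
  if (!is.null(object$basins)) {
    g <- g + ggplot2::geom_tile(
      data = object$basins,
      ggplot2::aes(x = .data$fF0, y = .data$fM0, fill = .data$basin),
      alpha = 0.35)
  }
  g +
    ggplot2::geom_path(
      data = nc,
      ggplot2::aes(x = .data$fF, y = .data$fM, group = paste(
        .data$cell_type, .data$branch), color = .data$cell_type),
      linetype = "dashed") +
    ggplot2::geom_point(
      data = fp,
      ggplot2::aes(x = .data$fF, y = .data$fM, shape = .data$stability),
      size = 3, stroke = 1.2) +
    ggplot2::scale_shape_manual(values = c(stable = 16, semi_stable = 10,
                                           unstable = 1)) +
    ggplot2::labs(x = "fibroblasts, log(F + 1)", y = "macrophages, log(M + 1)",
                  color = "nullcline", fill = "basin", shape = "fixed point") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap parameter distributions of a circuit fit
#'
#' Median (point), interquartile range (thick line) and 95% confidence
#' interval (thin line) per parameter, the standard forest-style summary of
#' the bootstrap.
#'
#' @param object A `circuit_fit` with bootstrap draws ([bootstrap_fit()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_fit <- function(object, ...) {
  if (is.null(object$boot)) {
    stop("no bootstrap draws; run bootstrap_fit()", call. = FALSE)
  }
  s <- object$boot$summary
  ggplot2::ggplot(s, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$conf_low,
                                       xend = .data$conf_high,
                                       yend = .data$parameter),
                          linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$q25, xend = .data$q75,
                                       yend = .data$parameter),
                          linewidth = 1.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median), size = 2.5) +
    ggplot2::labs(x = "bootstrap estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-capita growth-rate heatmaps
#'
#' Growth-rate field of both cell types over the phase plane; red indicates
#' growth, blue shrinkage, with sign changes on the nullclines.
#'
#' @param params A [circuit_params()] object.
#' @param f_max,grid_n Passed to [growth_rate_field()].
#' @return A ggplot object faceted by cell type.
#' @export
plot_growth_field <- function(params, f_max = NULL, grid_n = 80) {
  fld <- growth_rate_field(params, f_max = f_max, grid_n = grid_n) |>
    tidyr::pivot_longer(c("gF", "gM"), names_to = "cell_type",
                        values_to = "rate") |>
    dplyr::mutate(cell_type = ifelse(.data$cell_type == "gF",
                                     "fibroblasts", "macrophages"))
  ggplot2::ggplot(fld, ggplot2::aes(x = .data$fF, y = .data$fM,
                                    fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "log(F + 1)", y = "log(M + 1)",
                  fill = "per-capita\nrate (1/day)") +
    ggplot2::theme_minimal()
}
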