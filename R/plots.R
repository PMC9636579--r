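#' Volcano plot of a differential result
#'
#' log2 fold change against -log10 p, with passing features highlighted.
#'
#' @param x A `parp_diff` tibble ([phospho_differential()] /
#'   [adpr_differential()]).
#' @param label_top Number of top passing features to label (default 10).
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, label_top = 10) {
  df <- dplyr::mutate(as_tibble(x), neg_log10_p = -log10(pmax(.data$p_value, 1e-300)))
  thr <- attr(x, "threshold")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passes), size = 0.8, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "passes") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = c(-1, 1) * thr$threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  top <- utils::head(dplyr::arrange(dplyr::filter(df, .data$passes), .data$p_value), label_top)
  if (nrow(top) && !all(is.na(top$gene_symbol))) {
    p <- p + ggplot2::geom_text(
      data = top,
      ggplot2::aes(label = .data$gene_symbol),
      size = 2.5, vjust = -0.6, check_overlap = TRUE
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.parp_diff <- function(object, ...) plot_volcano(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.parp_synergy <- function(object, ...) {
  ggplot2::ggplot(
    object$grid,
    ggplot2::aes(factor(.data$conc_a_um), factor(.data$conc_b_um),
                 fill = .data$delta_bliss)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(
      x = sprintf("%s (uM)", object$drug_a),
      y = sprintf("%s (uM)", object$drug_b),
      fill = "delta Bliss"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.parp_4pl <- function(object, ...) {
  pts <- object$data
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$conc_um, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("%s (uM, log scale)", object$drug),
                  y = "viability (fraction of vehicle)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    xs <- exp(seq(log(min(pts$conc_um)), log(max(pts$conc_um)), length.out = 100))
    curve <- tibble(conc_um = xs, response = predict(object, xs))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}
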