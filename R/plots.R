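#' Per-chromosome recombination-rate track
#'
#' Plots the per-window rate of each map as light tracks with the
#' cross-map mean overlaid, for one chromosome -- the classic
#' recombination-landscape figure.
#'
#' @param summary Cross-map summary from [summarize_across_maps()].
#' @param profiles Optional long tibble (or list) of per-map profiles
#'   from [window_rates()], drawn as thin background lines.
#' @param chromosome Chromosome to plot (default: first in the summary).
#' @return A ggplot object.
#' @export
plot_rate_track <- function(summary, profiles = NULL, chromosome = NULL) {
  chromosome <- chromosome %||% summary$chromosome[1]
  s <- summary[summary$chromosome == chromosome, ]
  p <- ggplot2::ggplot(s, ggplot2::aes(x = (.data$start + .data$end) / 2e6))
  if (!is.null(profiles)) {
    if (is.list(profiles) && !is.data.frame(profiles)) {
      profiles <- purrr::list_rbind(profiles)
    }
    pr <- profiles[profiles$chromosome == chromosome, ]
    p <- p + ggplot2::geom_line(
      data = pr,
      ggplot2::aes(y = .data$rate, group = .data$map_id),
      colour = "grey70", linewidth = 0.3, na.rm = TRUE)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rate),
                       colour = "#2166AC", linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = paste0(chromosome, " position (Mb)"),
                  y = "recombination rate (cM/Mb)") +
    ggplot2::theme_minimal()
}

#' Strongest feature-rate correlations
#'
#' Lollipop chart of the `top_n` features by absolute correlation, with
#' FDR-significant features highlighted.
#'
#' @param correlations Tibble from [correlate()].
#' @param top_n Number of features shown (default 20).
#' @param alpha FDR threshold used for highlighting (default 0.05).
#' @return A ggplot object.
#' @export
plot_correlations <- function(correlations, top_n = 20, alpha = 0.05) {
  d <- correlations[!is.na(correlations$r), ]
  d <- utils::head(d[order(-abs(d$r)), ], top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  d$significant <- !is.na(d$q) & d$q < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$feature,
                                  colour = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$r,
                                       yend = .data$feature)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#B2182B", `FALSE` = "grey60"),
      name = paste0("FDR < ", alpha)) +
    ggplot2::labs(x = "correlation with rate (r)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot k-mer PCA scores coloured by recombination rate
#'
#' Scatter of the first two PC scores with windows coloured by the
#' response quartile (low / mid / high recombination), plus group mean
#' ellipses -- the standard view of how base composition separates
#' rate classes.
#'
#' @param object A `recmap_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recmap_pca
#' @export
autoplot.recmap_pca <- function(object, ...) {
  sc <- object$scores
  qs <- stats::quantile(sc$.response, c(0.25, 0.75), na.rm = TRUE)
  sc$rate_class <- cut(sc$.response, c(-Inf, qs[1], qs[2], Inf),
                       labels = c("low", "mid", "high"))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$rate_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(
      title = paste0(object$k, "-mer composition PCA"),
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]),
      colour = "rate quartile") +
    ggplot2::theme_minimal()
}
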