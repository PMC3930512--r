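# ggplot2 visualisations and broom-style tidiers for the result types.

#' @export
tidy.qtl_scan <- function(x, ...) as_tibble(unclass(x))

#' Glance at a genome scan
#'
#' @param x A `"qtl_scan"`.
#' @param ... Unused.
#' @return One-row tibble: peak chromosome/position/LOD, method, covariate.
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$lod)
  tibble(method = attr(x, "method"),
         covariate = attr(x, "covariate") %||% NA_character_,
         n = attr(x, "n"),
         peak_chr = x$chr[i], peak_pos = x$pos[i], peak_lod = x$lod[i])
}

scan_facet_plot <- function(df, ycol, ylab) {
  df$chr <- factor(df$chr, levels = unique(df$chr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = ylab) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"),
                   axis.text.x = ggplot2::element_blank())
}

#' Plot a LOD profile
#'
#' @param object A `"qtl_scan"`.
#' @param threshold Optional `"perm_thresholds"` drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- scan_facet_plot(as_tibble(unclass(object)), "lod", "LOD")
  if (!is.null(threshold)) {
    thr <- tibble(chr = factor(unique(object$chr),
                               levels = unique(object$chr)),
                  thr = ifelse(unique(object$chr) %in%
                                 object$chr[object$kind == "X"],
                               threshold$x, threshold$autosome))
    p <- p + ggplot2::geom_hline(data = thr,
                                 ggplot2::aes(yintercept = .data$thr),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a conditional scan
#'
#' Full, additive, and interaction LOD profiles across the genome.
#'
#' @param object A `"cond_scan"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cond_scan <- function(object, ...) {
  df <- as_tibble(unclass(object)) |>
    tidyr::pivot_longer(c("lod_f", "lod_a", "lod_i"),
                        names_to = "model", values_to = "lod")
  df$chr <- factor(df$chr, levels = unique(df$chr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$lod,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  title = sprintf("conditional on %s",
                                  attr(object, "covariate"))) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"),
                   axis.text.x = ggplot2::element_blank())
}

#' Plot sliding-window trans-eQTL counts with called hotspots
#'
#' @param counts Tibble from [window_counts()].
#' @param hotspots Optional `"hotspot_set"` drawn as shaded regions.
#' @return A ggplot object.
#' @export
plot_window_counts <- function(counts, hotspots = NULL) {
  counts$chr <- factor(counts$chr, levels = unique(counts$chr))
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$start,
                                            y = .data$count)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "window start (cM)", y = "trans eQTL per window") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(hotspots) && nrow(hotspots)) {
    hs <- as_tibble(unclass(hotspots))
    hs$chr <- factor(hs$chr, levels = levels(counts$chr))
    p <- p + ggplot2::geom_rect(
      data = hs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf,
                   ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot the interaction network
#'
#' Nodes laid out on a circle, edges as segments; edge width encodes the
#' interaction-eQTL count and double-stroke edges are reciprocal.
#'
#' @param object An `"eqtl_network"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqtl_network <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  edges <- object$edges
  edges <- left_join(edges, nodes[, c("node", "x", "y")],
                     by = c(from = "node"))
  edges <- left_join(edges, nodes[, c("node", "x", "y")],
                     by = c(to = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to,
                                       linewidth = .data$count,
                                       linetype = .data$reciprocal),
                          colour = "grey55", alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$sterile_allele), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$node), size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::theme_void()
}
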