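#' Zi-Pi role plot
#'
#' The classic keystone scatter: participation coefficient on x, within-
#' module degree z-score on y, threshold lines at the role cutoffs, keystone
#' quadrants labelled by role.
#'
#' @param topology a [zi_pi()] tibble.
#' @param z_threshold,p_threshold cutoffs to draw (defaults 2.5, 0.62).
#' @return a ggplot object.
#' @export
plot_zipi <- function(topology, z_threshold = 2.5, p_threshold = 0.62) {
  ggplot2::ggplot(topology, ggplot2::aes(x = .data$pi, y = .data$zi,
                                         colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = p_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Participation coefficient (Pi)",
                  y = "Within-module degree (Zi)", colour = "Role") +
    ggplot2::theme_minimal()
}

#' Alpha-diversity group plot
#'
#' Boxplots of a diversity index by group, one panel per index when several
#' are given.
#'
#' @param diversity output of [alpha_diversity()] joined with group labels
#'   (a `group_label` column).
#' @param indices which index columns to show.
#' @return a ggplot object.
#' @export
plot_diversity <- function(diversity,
                           indices = c("shannon", "chao1", "richness", "evenness")) {
  long <- tidyr::pivot_longer(diversity, dplyr::all_of(indices),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_label, y = .data$value,
                                     fill = .data$group_label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn awcd_curve AWCD incubation curves per sample, coloured by
#'   sample, overall category only.
#' @param object an `awcd_result`.
#' @export
autoplot.awcd_result <- function(object, ...) {
  overall <- filter(object$curve, .data$category == "overall")
  ggplot2::ggplot(overall, ggplot2::aes(x = .data$time_h, y = .data$awcd,
                                        group = .data$sample_id,
                                        colour = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$reference_time, linetype = "dotted") +
    ggplot2::labs(x = "Incubation time (h)", y = "AWCD (OD590)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' @describeIn group_compare group means with Tukey letters.
#' @param object a `group_comparison`.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$letters,
                  ggplot2::aes(x = stats::reorder(.data$group, -.data$mean),
                               y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Group mean") +
    ggplot2::theme_minimal()
}

#' @describeIn detect_modules network layout coloured by module (requires
#'   the network the partition came from).
#' @param object a `module_partition`.
#' @param net the `co_network` the partition was detected on.
#' @export
autoplot.module_partition <- function(object, net, ...) {
  g <- as_igraph(net)
  xy <- withr::with_seed(1L, igraph::layout_with_fr(g))
  mem <- setNames(object$membership$module, object$membership$otu_id)
  nodes <- tibble(
    otu_id = igraph::V(g)$name,
    x = xy[, 1], y = xy[, 2],
    module = factor(mem[igraph::V(g)$name])
  )
  edges <- net$edges %>%
    left_join(select(nodes, "otu_id", x0 = "x", y0 = "y"),
              by = c(from = "otu_id")) %>%
    left_join(select(nodes, "otu_id", x1 = "x", y1 = "y"),
              by = c(to = "otu_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$module), size = 1.5) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Module")
}
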