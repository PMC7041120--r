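# ggplot2 displays of layer surveys, in the style of per-layer bar panels.

#' Plot a layer survey
#'
#' Four displays of a [survey_layers()] result, all with factor-graph layer
#' on the horizontal axis: `"em"` shows the proportion of parameter nodes
#' with a monostable epithelial or mesenchymal state; `"presence"` the
#' proportion where each state is present at all; `"k"` the stacked
#' k-stability spectrum; `"diagonal"` the stacked proportions of nodes with
#' a fixed point in each distance-from-E diagonal of the (Zeb1, Snail1,
#' Ovol2) projection.
#'
#' @param object A `layer_survey`.
#' @param type One of `"em"`, `"presence"`, `"k"`, `"diagonal"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot layer_survey
autoplot.layer_survey <- function(object, type = c("em", "presence", "k",
                                                   "diagonal"), ...) {
  type <- match.arg(type)
  gene <- attr(object, "gene")
  df <- as_tibble(object)
  if (type == "em") {
    long <- tidyr::pivot_longer(df[, c("layer", "mono_E", "mono_M")],
                                -"layer", names_to = "state",
                                values_to = "proportion")
    long$state <- ifelse(long$state == "mono_E", "monostable E", "monostable M")
    ggplot2::ggplot(long, ggplot2::aes(.data$layer, .data$proportion,
                                       fill = .data$state)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_fill_manual(values = c("monostable E" = "#1f3d7a",
                                            "monostable M" = "#e08214")) +
      ggplot2::labs(x = paste(gene, "factor-graph layer"),
                    y = "proportion of parameter nodes", fill = NULL)
  } else if (type == "presence") {
    long <- tidyr::pivot_longer(df[, c("layer", "E_present", "M_present")],
                                -"layer", names_to = "state",
                                values_to = "proportion")
    long$state <- ifelse(long$state == "E_present", "E present", "M present")
    ggplot2::ggplot(long, ggplot2::aes(.data$layer, .data$proportion,
                                       fill = .data$state)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_fill_manual(values = c("E present" = "#1f3d7a",
                                            "M present" = "#e08214")) +
      ggplot2::labs(x = paste(gene, "factor-graph layer"),
                    y = "proportion of parameter nodes", fill = NULL)
  } else if (type == "k") {
    long <- multistability_spectrum(object)
    ggplot2::ggplot(long, ggplot2::aes(.data$layer, .data$proportion,
                                       fill = factor(.data$k))) +
      ggplot2::geom_col() +
      ggplot2::labs(x = paste(gene, "factor-graph layer"),
                    y = "proportion of parameter nodes",
                    fill = "stable fixed points k")
  } else {
    cols <- paste0("diag_", 0:8)
    long <- tidyr::pivot_longer(df[, c("layer", cols)], -"layer",
                                names_to = "diagonal",
                                values_to = "proportion")
    long$diagonal <- factor(as.integer(sub("diag_", "", long$diagonal)),
                            levels = 0:8)
    ggplot2::ggplot(long, ggplot2::aes(.data$layer, .data$proportion,
                                       fill = .data$diagonal)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_viridis_d(option = "plasma") +
      ggplot2::labs(x = paste(gene, "factor-graph layer"),
                    y = "proportion of parameter nodes",
                    fill = "distance from E")
  }
}
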