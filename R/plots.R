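# The two classic result views: final-state pie chart and per-node
# activation lines over time windows.

#' Pie chart of the final-state distribution
#'
#' One slice per projected state occupied at the end of the simulation,
#' labeled by its active non-internal nodes (`"<nil>"` when none).
#'
#' @param result a `simulation_result`.
#' @return a ggplot object.
#' @export
plot_final_pie <- function(result) {
  df <- final_states(result)
  if (nrow(df) == 0) stop("empty final-state distribution")
  ggplot2::ggplot(
    df, ggplot2::aes(x = "", y = .data$probability, fill = .data$state)
  ) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "Final state")
}

#' Line chart of node activation over time windows
#'
#' One line per non-internal node: the probability that the node is
#' active in each window, drawn at window midpoints.
#'
#' @param result a `simulation_result`.
#' @return a ggplot object.
#' @export
plot_node_trajectories <- function(result) {
  act <- node_activation(result)
  if (ncol(act) < 2) stop("no non-internal nodes to plot")
  mid <- act$Time + result$config$time_tick / 2
  long <- do.call(rbind, lapply(names(act)[-1], function(nm) {
    data.frame(Time = mid, node = nm, probability = act[[nm]])
  }))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$Time, y = .data$probability,
                 color = .data$node)
  ) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time", y = "P(node active)", color = "Node") +
    ggplot2::theme_minimal()
}
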