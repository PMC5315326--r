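#' Plot the learning trajectory of a trained perceptron
#'
#' One curve per cue configuration: the network's response after each
#' recorded epoch, on a log-scaled epoch axis so the early-dense recording
#' schedule is readable. Curves (and the legend) are ordered by final
#' response, top to bottom, so the legend order matches the visual
#' stacking of the lines. A well-trained network's curves fan out from
#' ~0.5 to the sixteen reward probabilities within a few tens of epochs.
#'
#' @param trained A [train_perceptron()] result.
#' @param max_epoch Truncate the plotted trajectory (default: all
#'   recorded epochs).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trained, max_epoch = Inf) {
  stopifnot(inherits(trained, "trained_perceptron"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_trajectory needs the ggplot2 package", call. = FALSE)
  }
  traj <- trained$trajectory[trained$trajectory$epoch <= max_epoch, ]
  labels <- pattern_labels()
  long <- do.call(rbind, lapply(labels, function(lb) {
    data.frame(epoch = traj$epoch, pattern = lb, response = traj[[lb]])
  }))
  final <- vapply(labels, function(lb) traj[[lb]][nrow(traj)], numeric(1))
  long$pattern <- factor(long$pattern,
                         levels = labels[order(final, decreasing = TRUE)])
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = response,
                                     colour = pattern)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "training epoch (log scale)",
                  y = "response to configuration",
                  colour = "configuration") +
    ggplot2::theme_minimal()
}
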