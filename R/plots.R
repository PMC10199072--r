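# ggplot2 helpers for the main diagnostics: training curves, NP-score
# distribution overlap, and chemical-space density maps.

#' Plot the training / validation loss curve of a fitted model
#'
#' @param model An `npgen_lm` with a non-empty training log.
#' @return A ggplot object (loss in nats/token against minibatches seen),
#'   the best validation loss marked by a dashed line.
#' @export
plot_training_curve <- function(model) {
  stopifnot(inherits(model, "npgen_lm"))
  log <- model$training_log
  if (nrow(log) == 0) abort("model has no training log to plot")
  long <- tidyr::pivot_longer(log, c("train_loss", "validation_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$minibatch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = model$best_validation_loss,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(train_loss = "#4477AA", validation_loss = "#EE6677"),
      labels = c(train_loss = "training", validation_loss = "validation"),
      name = NULL) +
    ggplot2::labs(x = "minibatches", y = "cross-entropy (nats/token)",
                  title = "Language-model training curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npgen_lm <- function(object, ...) plot_training_curve(object)

#' Plot a reference/candidate distribution pair
#'
#' Overlaid probability histograms of the two samples behind a
#' [make_distribution()] pair, e.g. NP-score distributions of the training
#' corpus versus the generated library.
#'
#' @param pair An `npgen_distribution_pair`.
#' @param ref_label,cand_label Legend labels (defaults "reference",
#'   "candidate").
#' @return A ggplot object.
#' @export
plot_distribution_pair <- function(pair, ref_label = "reference",
                                   cand_label = "candidate") {
  stopifnot(inherits(pair, "npgen_distribution_pair"))
  bw <- attr(pair, "bin_width")
  df <- tibble(
    support = rep(pair$support, 2L),
    probability = c(pair$P, pair$Q),
    series = rep(c(ref_label, cand_label), each = nrow(pair))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$probability,
                                        fill = .data$series))
  if (is.na(bw)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(x = .data$support),
                               position = "dodge")
  } else {
    # continuous support: bins are [k*w, (k+1)*w), plotted at bin centres
    df$x <- (df$support + 0.5) * bw
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                          y = .data$probability,
                                          fill = .data$series)) +
      ggplot2::geom_col(position = "identity", alpha = 0.55, width = bw)
  }
  p + ggplot2::scale_fill_manual(
    values = stats::setNames(c("#4477AA", "#EE6677"),
                             c(ref_label, cand_label)), name = NULL) +
    ggplot2::labs(x = "value", y = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npgen_distribution_pair <- function(object, ...) {
  plot_distribution_pair(object, ...)
}

#' Plot a chemical-space density map
#'
#' Heat map of point counts on the [density_grid()] of a 2-D embedding;
#' empty cells are left blank.
#'
#' @param grid A tibble from [density_grid()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_density_map <- function(grid, title = "Chemical-space density") {
  stopifnot(all(c("x", "y", "count") %in% names(grid)))
  ggplot2::ggplot(dplyr::filter(grid, .data$count > 0),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "molecules") +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", title = title) +
    ggplot2::theme_minimal()
}
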