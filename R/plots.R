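#' Score plot of a fitted PLS-DA model
#'
#' Training samples on two latent variables, coloured by class; queries
#' projected into the same space can be overlaid with `query`.
#'
#' @param object a `bga_plsda` fitted with training data in memory.
#' @param comps which two LVs to plot.
#' @param query optional feature matrix of unknowns to overlay (black).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bga_plsda
#' @export
autoplot.bga_plsda <- function(object, comps = c(1, 2), query = NULL, ...) {
  if (is.null(object$scores)) {
    stop_strbga("model has no stored training scores (deserialised model?)")
  }
  stopifnot(length(comps) == 2, all(comps <= object$ncomp))
  sc <- plsda_scores(object)
  df <- tibble::tibble(x = sc[, comps[1]], y = sc[, comps[2]],
                       class = object$labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste0("LV", comps[1]), y = paste0("LV", comps[2]),
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(query)) {
    qs <- plsda_scores(object, query)
    qdf <- tibble::tibble(x = qs[, comps[1]], y = qs[, comps[2]],
                          label = rownames(qs) %||% as.character(seq_len(nrow(qs))))
    p <- p +
      ggplot2::geom_point(data = qdf, ggplot2::aes(x = .data$x, y = .data$y),
                          inherit.aes = FALSE, colour = "black", size = 2) +
      ggplot2::geom_text(data = qdf,
                         ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                         inherit.aes = FALSE, vjust = -0.8, size = 3)
  }
  p
}

#' Bar chart of per-class prediction values
#'
#' @param object a `bga_prediction` tibble.
#' @param ... unused.
#' @return a ggplot faceted by sample, with the reliability threshold
#'   marked.
#' @method autoplot bga_prediction
#' @export
autoplot.bga_prediction <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("pv_"),
                        names_to = "class", values_to = "prediction_value",
                        names_prefix = "pv_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$prediction_value,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "prediction value")
}

#' Heatmap of the pooled rdCV confusion matrix
#'
#' @param object a `bga_cv_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bga_cv_report
#' @export
autoplot.bga_cv_report <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "count")
  names(df)[1:2] <- c("truth", "prediction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("rdCV pooled confusion (accuracy %.3f)",
                                  object$accuracy))
}
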