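# ggplot2 visualization methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a band scalogram
#'
#' Band x time magnitude map for one channel.
#'
#' @param object a `scalogram`.
#' @param channel channel index to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scalogram <- function(object, channel = 1, ...) {
  v <- object$values[, channel, , drop = TRUE]
  bands <- vapply(object$band_edges,
                  function(b) sprintf("%g-%g Hz", b[1], b[2]), character(1))
  df <- tidyr::expand_grid(
    band = factor(bands, levels = rev(bands)),
    t = (seq_len(ncol(v)) - 1) / object$fs
  )
  df$magnitude <- as.numeric(t(v[rev(seq_len(nrow(v))), , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$band,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "|CWT|") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Train and validation loss per epoch, with the restored epoch marked.
#'
#' @param object a `spasm_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spasm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
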