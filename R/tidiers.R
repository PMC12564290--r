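# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-fold metrics of a cross-validation
#'
#' @param x A `popconn_cv`.
#' @param ... Unused.
#' @return Long tibble: `fold`, `metric`, `value`.
#' @export
tidy.popconn_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, c("ACC", "PRE", "RECALL", "F1", "AUC"),
                      names_to = "metric")[, c("fold", "metric", "value")]
}

#' One-row cross-validation summary
#'
#' @param x A `popconn_cv`.
#' @param ... Unused.
#' @return One-row tibble of `<metric>_mean` / `<metric>_sd` columns.
#' @export
glance.popconn_cv <- function(x, ...) {
  s <- x$summary
  wide <- c(stats::setNames(s$mean, paste0(s$metric, "_mean")),
            stats::setNames(s$sd, paste0(s$metric, "_sd")))
  tibble::as_tibble(as.list(wide))
}

#' Tidy the loss history of a fitted fold
#'
#' @param x A `popconn_fit`.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `component`, `value`.
#' @export
tidy.popconn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("loss", "lce", "lvc", "lcl", "val_loss"),
                      names_to = "component")
}

#' One-row fit summary
#'
#' @param x A `popconn_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch and final losses.
#' @export
glance.popconn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 final_loss = utils::tail(h$loss, 1),
                 final_lce = utils::tail(h$lce, 1))
}

#' Tidy region-importance table
#'
#' @param x A `popconn_importance`.
#' @param ... Unused.
#' @return The underlying tibble with the baseline accuracy as column.
#' @export
tidy.popconn_importance <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), baseline = attr(x, "baseline"))
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `popconn_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.popconn_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = "Cross-validated classification metrics") +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object A `popconn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.popconn_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training loss components") +
    ggplot2::theme_minimal()
}

#' Plot region importance
#'
#' @param object A `popconn_importance`.
#' @param k Highlight the top-k regions.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.popconn_importance <- function(object, k = 10, ...) {
  d <- tidy(object)
  d$top <- d$rank <= k
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(factor(.data$roi), -.data$dAcc),
                                  y = .data$dAcc, fill = .data$top)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    ggplot2::labs(x = "region", y = expression(Delta * "Acc"),
                  title = sprintf("Accuracy drop per masked region (atlas %s)",
                                  attr(object, "atlas"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
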