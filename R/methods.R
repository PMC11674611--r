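# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a cross-validation result
#'
#' @param x An `hbn_eval` from [evaluate_features()].
#' @param ... Unused.
#' @return A tibble with one row per (true class, predicted class) cell of
#'   the row-normalized confusion matrix.
#' @method tidy hbn_eval
#' @export
tidy.hbn_eval <- function(x, ...) {
  cm <- as.data.frame.table(x$confusion, responseName = "proportion")
  tibble::tibble(true = as.character(cm$true),
                 predicted = as.character(cm$predicted),
                 proportion = cm$proportion)
}

#' One-row summary of a cross-validation result
#'
#' @param x An `hbn_eval`.
#' @param ... Unused.
#' @return A one-row tibble: feature kind, classifier, accuracy mean/sd,
#'   protocol settings.
#' @method glance hbn_eval
#' @export
glance.hbn_eval <- function(x, ...) {
  tibble::tibble(feature_kind = x$feature_kind, classifier = x$classifier,
                 accuracy = x$accuracy_mean, accuracy_sd = x$accuracy_sd,
                 k_folds = x$k_folds, repeats = x$repeats,
                 n_samples = sum(x$counts))
}

.matrix_tile_plot <- function(m, xlab, ylab, fill_lab) {
  df <- as.data.frame.table(m, responseName = "value")
  names(df)[1:2] <- c("row", "col")
  df$row <- factor(df$row, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = fill_lab) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a causal matrix
#'
#' @param object A `causal_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map of directed Granger strengths (row drives column).
#' @method autoplot causal_matrix
#' @export
autoplot.causal_matrix <- function(object, ...) {
  g <- object$g
  dimnames(g) <- list(paste0("R", seq_len(nrow(g))), paste0("R", seq_len(ncol(g))))
  .matrix_tile_plot(g, "target region", "driving region", "F")
}

#' Plot a coupling matrix
#'
#' @param object A `coupling_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map of source-to-fNIRS coupling strengths.
#' @method autoplot coupling_matrix
#' @export
autoplot.coupling_matrix <- function(object, ...) {
  cs <- object$cs
  dimnames(cs) <- list(paste0("R", seq_len(nrow(cs))), paste0("F", seq_len(ncol(cs))))
  .matrix_tile_plot(cs, "fNIRS channel", "source region", "|beta|")
}

#' Plot a confusion matrix
#'
#' @param object An `hbn_eval`.
#' @param ... Unused.
#' @return A ggplot heat map of the row-normalized confusion matrix with the
#'   proportions printed in the cells.
#' @method autoplot hbn_eval
#' @export
autoplot.hbn_eval <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(sort(unique(df$true))))
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = true, fill = proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", proportion)),
                       color = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "proportion") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("%s on %s: %.1f%% +/- %.2f",
                                  object$classifier, object$feature_kind,
                                  100 * object$accuracy_mean,
                                  100 * object$accuracy_sd)) +
    ggplot2::theme_minimal()
}
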