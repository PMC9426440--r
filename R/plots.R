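# ggplot2 displays for the main result types.

#' @describeIn select_k Silhouette-by-k curve with the chosen k marked.
#' @param object The fitted object.
#' @export
autoplot.ms1_feature_clustering <- function(object, ...) {
  df <- object$silhouette_by_k
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "k (modules)", y = "mean silhouette",
                  title = paste0("Module count selection (k = ",
                                 object$chosen_k, ")")) +
    ggplot2::theme_minimal()
}

#' @describeIn correlate_eigenfeatures Module x condition correlation
#'   heatmap.
#' @param object The fitted object.
#' @param ... Unused.
#' @export
autoplot.ms1_correlation_profile <- function(object, ...) {
  df <- tidy(object)
  df$condition <- factor(df$condition, levels = object$conditions)
  df$module <- factor(df$module, levels = rev(object$modules))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Eigenfeature-condition correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn condition_tree Dendrogram with AU support at internal nodes
#'   (AU > 0.9 highlighted).
#' @param object The fitted object.
#' @export
autoplot.ms1_condition_tree <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  nodes <- dendrogram_nodes(object$hclust)
  nodes$au <- object$support$au
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = sprintf("%.2f", .data$au),
                                     color = .data$au > 0.9),
                        size = 2.6, label.size = 0) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "darkorange",
                                           `FALSE` = "grey40"),
                                guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq_along(object$hclust$labels),
                                labels = object$hclust$labels[object$hclust$order]) +
    ggplot2::labs(x = NULL, y = "average correlation distance",
                  title = "Condition clustering (AU support at nodes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @describeIn fit_lasso_loocv LOOCV deviance along the penalty path.
#' @param object The fitted object.
#' @export
autoplot.ms1_marker_model <- function(object, ...) {
  df <- object$cv_deviance
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_1se),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::geom_vline(xintercept = log(object$lambda_min),
                        linetype = "dotted") +
    ggplot2::labs(x = "log(lambda)", y = "LOOCV binomial deviance",
                  title = "Penalty selection (dashed = lambda.1se)") +
    ggplot2::theme_minimal()
}

# x-position of each leaf follows hclust$order; internal node x = mean of
# children's x, y = merge height.
dendrogram_nodes <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- match(seq_len(n), hc$order)
  x <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    kids <- hc$merge[i, ]
    xk <- vapply(kids, function(k) if (k < 0) leaf_x[-k] else x[k], numeric(1))
    x[i] <- mean(xk)
  }
  tibble(node = seq_len(n - 1), x = x, y = hc$height)
}

dendrogram_segments <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- match(seq_len(n), hc$order)
  nx <- dendrogram_nodes(hc)
  segs <- list()
  for (i in seq_len(n - 1)) {
    kids <- hc$merge[i, ]
    for (k in kids) {
      cx <- if (k < 0) leaf_x[-k] else nx$x[k]
      cy <- if (k < 0) 0 else nx$y[k]
      segs[[length(segs) + 1]] <- tibble(
        x = c(cx, cx), xend = c(cx, nx$x[i]),
        y = c(cy, nx$y[i]), yend = c(nx$y[i], nx$y[i])
      )
    }
  }
  dplyr::bind_rows(segs)
}
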