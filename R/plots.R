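#' Plot a model boundary polygon
#'
#' @param object A `boundary_polygon`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boundary_polygon
#' @export
autoplot.boundary_polygon <- function(object, ...) {
  df <- tibble(x = object[, 1], y = object[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "model_name"),
                  x = "x (model units)", y = "y (model units)") +
    ggplot2::theme_minimal()
}

#' Plot a silhouette mask
#'
#' @param object A `silhouette`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot silhouette
#' @export
autoplot.silhouette <- function(object, ...) {
  idx <- which(object$mask, arr.ind = TRUE)
  df <- tibble(x = idx[, 2], y = nrow(object$mask) - idx[, 1] + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "px", y = "px") +
    ggplot2::theme_minimal()
}

#' Plot the ranked model scores of a group assignment
#'
#' @param object A `group_assignment`.
#' @param ... Unused.
#' @return A ggplot bar chart of J per model, coloured by group.
#' @method autoplot group_assignment
#' @export
autoplot.group_assignment <- function(object, ...) {
  df <- object$ranked
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$J, y = .data$model,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::labs(x = "J index", y = NULL, fill = "group",
                  title = paste("assigned group:", object$group)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
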