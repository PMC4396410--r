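#' Map a per-cell value over the grid
#'
#' A tile map of any per-cell column, the standard way to eyeball gridded
#' diversity surfaces.
#'
#' @param data per-cell tibble with `col`, `row` and the mapped column.
#' @param value name of the column to map.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(data, value) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
}

#' @describeIn diversity_table autoplot method: tile map of one metric
#'   (default `pd`).
#' @param object a `diversity_table`.
#' @param metric column to map.
#' @param ... unused.
#' @export
autoplot.diversity_table <- function(object, metric = "pd", ...) {
  plot_cell_map(object, metric)
}

#' @describeIn randomization_test autoplot method: map of the high / low /
#'   ns significance codes (requires `row` and `col` columns joined in, or
#'   cell ids of the form `r<row>_c<col>` which are parsed).
#' @param object a `randomization_result`.
#' @param ... unused.
#' @export
autoplot.randomization_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!all(c("row", "col") %in% names(d))) {
    m <- regmatches(d$cell_id, regexec("^r(-?\\d+)_c(-?\\d+)$", d$cell_id))
    d$row <- as.integer(vapply(m, `[`, "", 2))
    d$col <- as.integer(vapply(m, `[`, "", 3))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(
      values = c(high = "#d73027", low = "#4575b4", ns = "grey85"),
      drop = FALSE
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PD code") +
    ggplot2::theme_minimal()
}

#' @describeIn build_model_set autoplot method: delta-AIC dot plot of the
#'   model set, with the AIC-within-3 equivalence window shaded.
#' @param object a `model_set` or report tibble with `model` and a delta
#'   AIC column.
#' @param ... unused.
#' @export
autoplot.model_set <- function(object, ...) {
  d <- tibble::as_tibble(object)
  dcol <- if ("delta_aic" %in% names(d)) "delta_aic" else "glm_delta_aic"
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[dcol]], y = .data$model)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 3, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}
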