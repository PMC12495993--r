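#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   geom_point scale_fill_gradient2 labs theme_minimal coord_flip ylim
NULL

#' Heatmap of a specificity matrix
#'
#' Genes x cell types gsc heatmap in hierarchically clustered order, the usual
#' visual check that a specific panel shows block structure.
#'
#' @param object a `specificity_matrix`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.specificity_matrix <- function(object, ...) {
  ent <- panel_entropy_score(object)
  v <- object$values[ent$row_order, ent$col_order, drop = FALSE]
  df <- tidy.specificity_matrix(structure(list(values = v, epsilon = object$epsilon),
                                          class = "specificity_matrix"))
  df$gene <- factor(df$gene, levels = rownames(v))
  df$cell_type <- factor(df$cell_type, levels = colnames(v))
  ggplot(df, aes(x = .data$cell_type, y = .data$gene, fill = .data$gsc)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "cell type", y = "gene", fill = "gsc") +
    theme_minimal()
}

#' Optimization trajectory plot
#'
#' Best and mean objective per iteration of a genetic-algorithm run.
#'
#' @param object a `ga_state`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ga_state <- function(object, ...) {
  df <- tidy.ga_state(object) |>
    tidyr::pivot_longer(c("best", "mean"), names_to = "series",
                        values_to = "objective")
  ggplot(df, aes(x = .data$iteration, y = .data$objective,
                 colour = .data$series)) +
    geom_line() +
    labs(x = "iteration", y = "objective", colour = NULL) +
    theme_minimal()
}

#' Category-score barplot for a panel report
#'
#' @param object a `panel_report`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.panel_report <- function(object, ...) {
  df <- tidy.category_scores(object$category_scores)
  ggplot(df, aes(x = .data$category, y = .data$score)) +
    geom_col(fill = "steelblue") +
    ylim(0, 1) +
    labs(title = object$panel, x = NULL, y = "category score") +
    theme_minimal()
}

#' Multi-panel standardized-score heatmap
#'
#' Given several panel reports, standardizes each category score across panels
#' (z-scores) and draws a panels x categories heatmap for side-by-side
#' comparison.
#'
#' @param reports list of `panel_report` objects (>= 2)
#' @return a ggplot
#' @export
plot_panel_comparison <- function(reports) {
  stopifnot(length(reports) >= 2)
  df <- standardized_scores(reports) |>
    tidyr::pivot_longer(-"panel", names_to = "metric", values_to = "z")
  ggplot(df, aes(x = .data$metric, y = .data$panel, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal()
}

#' Standardized category scores across panels
#'
#' @param reports list of `panel_report` objects
#' @return tibble: one row per panel, z-scored category and overall columns
#' @export
standardized_scores <- function(reports) {
  g <- purrr::map_dfr(reports, glance.panel_report)
  num <- dplyr::select(g, dplyr::where(is.numeric))
  z <- as.data.frame(scale(num))
  z[is.na(z)] <- 0     # constant column across panels
  tibble::tibble(panel = g$panel, tibble::as_tibble(z))
}
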