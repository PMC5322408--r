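#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_histogram geom_tile
#'   geom_text geom_vline labs scale_fill_viridis_c theme_minimal
#'   after_stat geom_point
#' @export
ggplot2::autoplot

#' Plot fitted selectivity curves
#'
#' Unit-scaled per-mesh retention curves and their sum over the SL grid,
#' the standard way to display multi-mesh gill-net selectivity.
#'
#' @param object a `selectivity_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.selectivity_model <- function(object, ...) {
  grid <- attr(object, "grid")
  curves <- attr(object, "curves")
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(sl = grid, tibble::as_tibble(curves)),
    -"sl", names_to = "mesh", values_to = "selectivity")
  tot <- tibble::tibble(sl = grid, mesh = "total",
                        selectivity = attr(object, "total_curve"))
  ggplot(dplyr::bind_rows(df, tot),
         aes(x = .data$sl, y = .data$selectivity,
             colour = .data$mesh, linetype = .data$mesh == "total")) +
    geom_line(show.legend = c(colour = TRUE, linetype = FALSE)) +
    labs(x = "standard length (mm)", y = "relative selectivity",
         colour = "mesh (mm)") +
    theme_minimal()
}

#' Plot a cluster solution as a labelled SL histogram
#'
#' @param object a `cluster_solution`.
#' @param binwidth histogram bin width (mm).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cluster_solution <- function(object, binwidth = 10, ...) {
  med <- attr(object, "medoids")
  ggplot(tibble::as_tibble(object),
         aes(x = .data$value, fill = factor(.data$cluster))) +
    geom_histogram(binwidth = binwidth, colour = "grey30") +
    geom_vline(xintercept = (med[-1] + med[-length(med)]) / 2,
               linetype = "dashed") +
    labs(x = "standard length (mm)", y = "fish", fill = "cluster") +
    theme_minimal()
}

#' Heatmap of pairwise F_ST with significance stars
#'
#' @param object an `fst_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fst_matrix <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- sprintf("%.3f%s", d$theta, ifelse(d$significant, "*", ""))
  ggplot(d, aes(x = .data$group1, y = .data$group2, fill = .data$theta)) +
    geom_tile() +
    geom_text(aes(label = .data$label), colour = "white") +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "F[ST]") +
    theme_minimal()
}

#' Cross-validation RMSE profile of a DAPC fit
#' @param object a `dapc_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dapc_result <- function(object, ...) {
  ggplot(object$rmse, aes(x = .data$n_pc, y = .data$rmse)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$n_pc, linetype = "dashed") +
    labs(x = "principal components retained", y = "cross-validated RMSE") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
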