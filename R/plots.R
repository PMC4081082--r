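#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_point
#'   scale_x_log10 scale_y_log10 scale_fill_viridis_c labs theme_minimal
#'   geom_line
#' @importFrom dplyr bind_cols any_of
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a steady-state repression surface
#'
#' Raster of the normalised steady-state target expression over the
#' miRNA expression-factor grid (1 = unrepressed, 0 = silenced), with
#' the repression gains in the subtitle.
#'
#' @param object A `repression_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.repression_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$tf1, y = .data$tf2, fill = .data$ss)) +
    geom_raster() +
    scale_x_log10() +
    scale_y_log10() +
    scale_fill_viridis_c(limits = c(0, 1), name = "SS") +
    labs(
      x = expression(TF[miRNA1]), y = expression(TF[miRNA2]),
      title = "Steady-state target expression",
      subtitle = sprintf("RG1 = %.3f, RG2 = %.3f, RG3 = %.3f (%s)",
                         object$gains$RG1, object$gains$RG2,
                         object$gains$RG3, object$synergy_class)
    ) +
    theme_minimal()
}

#' Plot equilibrium concentrations of an RNA triple
#'
#' @param object An `equilibrium_state`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.equilibrium_state <- function(object, ...) {
  df <- tidy(object)
  df$complex <- factor(df$complex, levels = df$complex[order(df$n_strands)])
  ggplot(df, aes(x = .data$complex, y = .data$conc_nM)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "equilibrium concentration (nM)",
         title = "Complex equilibrium distribution") +
    theme_minimal()
}

#' Plot the candidate funnel of a pipeline run
#'
#' Bar chart of surviving candidates after each workflow stage.
#'
#' @param funnel The `funnel` tibble from [run_triplex_pipeline()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  funnel$stage <- factor(funnel$stage, levels = funnel$stage)
  ggplot(funnel, aes(x = .data$stage, y = .data$n_out)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "surviving candidates",
         title = "Workflow candidate funnel") +
    theme_minimal()
}
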