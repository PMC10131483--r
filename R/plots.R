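#' Plot the screening funnel
#'
#' Horizontal bar chart of genes surviving each screening stage.
#'
#' @param funnel Funnel tibble from [run_pipeline()] (or the pipeline
#'   object itself).
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  if (inherits(funnel, "effector_pipeline")) funnel <- funnel$funnel
  df <- funnel %>%
    dplyr::mutate(stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_out, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.1,
                       size = 3) +
    ggplot2::labs(x = "genes surviving stage", y = NULL,
                  title = "Effector-gene screening funnel") +
    ggplot2::theme_minimal()
}

#' Plot zygotic onset counts by lineage occupancy
#'
#' Stacked bar chart of the number of effector genes with onset at each
#' sampled hour, colored by the number of lineages the gene occupies at
#' the early gastrula stage.
#'
#' @param records Record table (or `effector_pipeline`).
#' @return A ggplot object.
#' @export
plot_onset_histogram <- function(records) {
  counts <- onset_histogram(records, by = "n_lineages") %>%
    dplyr::mutate(n_lineages = factor(.data$n_lineages))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$onset_hpf, y = .data$n,
                               fill = .data$n_lineages)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "lineages") +
    ggplot2::labs(x = "zygotic expression onset (hpf)",
                  y = "effector genes") +
    ggplot2::theme_minimal()
}

#' Dot plot of single-lineage onset by lineage
#'
#' Onset hour against lineage for effectors restricted to one lineage,
#' dot size giving the gene count.
#'
#' @param records Record table (or `effector_pipeline`).
#' @return A ggplot object.
#' @export
plot_onset_by_lineage <- function(records) {
  counts <- onset_histogram(records, by = "lineage") %>%
    dplyr::mutate(lineage = factor(.data$lineage,
                                   levels = rev(lineage_levels())))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$onset_hpf, y = .data$lineage,
                               size = .data$n, color = .data$lineage)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "zygotic expression onset (hpf)", y = NULL,
                  size = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default plot for a pipeline run
#'
#' @param object An `effector_pipeline`.
#' @param type `"funnel"`, `"onset"` or `"lineage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effector_pipeline <- function(object,
                                       type = c("funnel", "onset", "lineage"),
                                       ...) {
  type <- match.arg(type)
  switch(type,
         funnel = plot_funnel(object),
         onset = plot_onset_histogram(object),
         lineage = plot_onset_by_lineage(object))
}
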