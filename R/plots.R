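#' Plot the three EDA indices over time
#'
#' One facet per index, with optional stimulus markers.
#'
#' @param indices Tibble from [eda_indices()] or [run_stream_simulation()].
#' @param events Optional events tibble (`subject_id`, `time_s`); stimulus
#'   times are drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_indices <- function(indices, events = NULL) {
  if ("emitted_at_s" %in% names(indices) && !"time_s" %in% names(indices)) {
    indices <- dplyr::rename(indices, time_s = "emitted_at_s")
  }
  df <- tidyr::pivot_longer(indices, c("tvsymp", "mtvsymp", "dpheda"),
                            names_to = "index", values_to = "value") %>%
    mutate(index = factor(.data$index, levels = c("tvsymp", "mtvsymp", "dpheda"),
                          labels = c("TVSymp", "MTVSymp", "dPhEDA (uS/s)")))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "EDA indices")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(xintercept = events$time_s,
                                 colour = "red", linetype = 2, alpha = 0.6)
  }
  p
}

#' Plot feature discriminability (AUROC with CIs)
#'
#' @param object A `feature_comparison` from [compare_segment_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$auroc,
                                   stats::reorder(.data$feature, .data$auroc))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "AUROC (95% CI)", y = NULL,
                  title = "Painless vs pain discriminability per feature")
}
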