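#' Bar chart of family exceedance probabilities
#'
#' @param bms a `bms_result` from [rfx_bms()].
#' @param threshold decisiveness threshold drawn as a reference line.
#' @return a ggplot object.
#' @export
plot_exceedance <- function(bms, threshold = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_exceedance needs ggplot2")
  d <- data.frame(family = names(bms$exceedance),
                  exceedance = as.numeric(bms$exceedance))
  ggplot2::ggplot(d, ggplot2::aes(x = family, y = exceedance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "exceedance probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of group-mean modulatory parameters with significance marks
#'
#' @param stats a `group_stats` table from [map_group_ttests()].
#' @return a ggplot object; Bonferroni-significant connections are
#'   marked with `*`.
#' @export
plot_map_estimates <- function(stats) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_map_estimates needs ggplot2")
  d <- as.data.frame(stats)
  d$label <- ifelse(d$significant, "*", "")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(parameter, -abs(t)),
                                  y = mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.3,
                       size = 6) +
    ggplot2::labs(x = NULL, y = "group mean modulatory weight (MAP)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
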