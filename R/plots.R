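#' Violin plot of per-individual ROH summaries
#'
#' Kernel-density violins (rule-of-thumb bandwidth) with an interquartile
#' bar and a median dot, one violin per channel/tolerance. Purely a
#' presentation utility: no numerical output depends on it. Requires
#' ggplot2.
#'
#' @param summaries Named list of data frames from
#'   [summarize_roh_individuals()] (e.g. the `"summaries"` attribute of
#'   [compare_channels()]).
#' @param statistic One of `"nroh"`, `"mean_size_mb"`, `"sroh_mb"`.
#' @return A ggplot object.
#' @export
plot_roh_violin <- function(summaries, statistic = c("nroh", "mean_size_mb",
                                                     "sroh_mb")) {
  statistic <- match.arg(statistic)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_roh_violin requires ggplot2")
  df <- do.call(rbind, lapply(names(summaries), function(nm)
    data.frame(channel = nm, value = summaries[[nm]][[statistic]])))
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = channel, y = value, fill = channel)) +
    ggplot2::geom_violin(trim = FALSE) +
    ggplot2::geom_boxplot(width = 0.08, outlier.shape = NA, fill = "black") +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          colour = "white", size = 2) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heat-map of channel-comparison statistics
#'
#' Renders the statistic-by-tolerance matrix attached to
#' [compare_channels()] output: Pearson correlations, or MWW p-values
#' coloured by significance at 0.05 (two-sided, no multiple-testing
#' correction). Requires ggplot2.
#'
#' @param comparison Output of [compare_channels()].
#' @param which `"mww"` or `"cor"`.
#' @param alpha Significance threshold used for the MWW colouring.
#' @return A ggplot object.
#' @export
plot_comparison_heatmap <- function(comparison, which = c("mww", "cor"),
                                    alpha = 0.05) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_comparison_heatmap requires ggplot2")
  m <- attr(comparison, if (which == "mww") "mww_matrix" else "cor_matrix")
  df <- expand.grid(statistic = rownames(m), h = colnames(m),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(m)
  df$significant <- df$value < alpha
  g <- ggplot2::ggplot(df, ggplot2::aes(x = h, y = statistic))
  if (which == "mww") {
    g <- g + ggplot2::geom_tile(ggplot2::aes(fill = significant)) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue"),
                                 name = paste0("p < ", alpha))
  } else {
    g <- g + ggplot2::geom_tile(ggplot2::aes(fill = value)) +
      ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                   high = "darkgreen", name = "r")
  }
  g + ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", value)),
                         size = 3) +
    ggplot2::theme_minimal()
}
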