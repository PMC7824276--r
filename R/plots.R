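#' Plot per-class AT and CG skews across genomes
#'
#' One panel per metric, site classes on the x axis, one point per genome,
#' strand coded by shape. Outlying genomes (from [skew_outliers()]) can be
#' highlighted.
#'
#' @param skews A skew table from [skew_table()].
#' @param outliers Optional outlier report from [skew_outliers()].
#' @return A ggplot object.
#' @export
plot_skew <- function(skews, outliers = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(skews, "genome_id", "class", "at_skew", "cg_skew"),
    c("at_skew", "cg_skew"),
    names_to = "metric", values_to = "value"
  )
  long$strand <- ifelse(grepl("J", long$class), "J", "N")
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$class, y = .data$value, shape = .data$strand)
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, ncol = 1,
      labeller = ggplot2::as_labeller(c(at_skew = "AT skew", cg_skew = "CG skew"))
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "site class", y = "skew") +
    ggplot2::theme_minimal()
  if (!is.null(outliers)) {
    flagged <- tidyr::unnest(
      dplyr::select(outliers, "class", "metric", "outliers"),
      "outliers"
    )
    names(flagged)[names(flagged) == "outliers"] <- "genome_id"
    hits <- dplyr::inner_join(long, flagged, by = c("class", "metric", "genome_id"))
    if (nrow(hits) > 0L) {
      p <- p + ggplot2::geom_point(
        data = hits, colour = "red", size = 2.5, na.rm = TRUE
      )
    }
  }
  p
}

#' Plot the AT% distribution of a genome set against a background
#'
#' @param at A tibble from [at_percent_distribution()].
#' @param background Optional second tibble of the same shape (e.g. a
#'   wider taxonomic set) drawn in grey behind the focal set.
#' @return A ggplot object.
#' @export
plot_at_percent <- function(at, background = NULL) {
  p <- ggplot2::ggplot(at, ggplot2::aes(x = .data$at_pct))
  if (!is.null(background)) {
    p <- p + ggplot2::geom_histogram(
      data = background, binwidth = 1, fill = "grey80", colour = NA
    )
  }
  p +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "AT%", y = "genomes") +
    ggplot2::theme_minimal()
}
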