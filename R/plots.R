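# ggplot2 views of the main result types.

#' Region-class distribution plot
#'
#' Bar chart of the genomic-region distribution of breakpoints (the
#' promoter / UTR / exon / intron / intergenic breakdown), optionally per
#' sample group when a `group` column is present.
#'
#' @param annotated An `annotated_breakpoints` tibble.
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(annotated) {
  a <- as_tibble(annotated)
  a$region_class <- factor(a$region_class, levels = REGION_LEVELS)
  p <- ggplot2::ggplot(a, ggplot2::aes(x = .data$region_class))
  if ("group" %in% names(a)) {
    p <- p + ggplot2::geom_bar(ggplot2::aes(fill = .data$group),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_bar(fill = "steelblue")
  }
  p + ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "genomic region", y = "breakpoints") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.annotated_breakpoints <- function(object, ...) {
  plot_region_distribution(object)
}

#' Per-chromosome breakpoint counts plot
#'
#' @param breakpoints A breakpoint (cluster) tibble with `chrom`.
#' @return A ggplot object.
#' @export
plot_chromosome_counts <- function(breakpoints) {
  as_tibble(breakpoints) |>
    count(.data$chrom) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$chrom, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "chromosome", y = "breakpoints") +
    ggplot2::theme_minimal()
}

#' Cluster support plot
#'
#' Support (reads of evidence) per breakpoint cluster along each
#' chromosome, split by evidence type.
#'
#' @param clusters A `breakpoint_clusters` tibble.
#' @return A ggplot object.
#' @export
plot_breakpoint_support <- function(clusters) {
  ggplot2::ggplot(as_tibble(clusters),
                  ggplot2::aes(x = .data$pos, y = .data$support,
                               colour = .data$evidence)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position", y = "supporting reads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.breakpoint_clusters <- function(object, ...) {
  plot_breakpoint_support(object)
}

#' Cohort comparison plot
#'
#' Per-sample breakpoint counts by group (the case-vs-control view the
#' count test is computed on).
#'
#' @param object A `cohort_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  ggplot2::ggplot(object$counts_by_sample,
                  ggplot2::aes(x = .data$group, y = .data$n_breakpoints)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "breakpoints per sample") +
    ggplot2::theme_minimal()
}
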