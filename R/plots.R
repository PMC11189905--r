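# ggplot2 visualizations of the main result types.

#' @export
autoplot.sample_scores <- function(object, sd_cut = 1, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = c(-sd_cut, sd_cut), linetype = "dashed") +
    ggplot2::labs(x = "scaled totalscore", y = "samples",
                  title = "Distribution of scaled totalscores") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_trait_cor <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r, .data$stars)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Module-trait correlation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_result <- function(object, ...) {
  df <- object$curves
  start <- dplyr::distinct(df, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start, df[, c("group", "time", "surv")])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability", color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$logrank)) {
    p <- p + ggplot2::labs(subtitle = sprintf("log-rank P = %.3g", object$logrank$p))
  }
  p
}

#' @export
autoplot.agreement_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier_1,
                                   y = .data$classifier_2, fill = .data$kappa)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.na(.data$kappa), "", sprintf("%.2f", .data$kappa))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(kappa),
                  title = "Classifier agreement (Cohen's kappa)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano plot of a differential-expression contrast
#'
#' @param dge A [differential_expression()] result.
#' @param fdr_threshold Genes below this q are highlighted.
#' @param highlight Optional gene set drawn in gold (e.g. module genes).
#' @return A ggplot object.
#' @export
plot_volcano <- function(dge, fdr_threshold = 0.05, highlight = NULL) {
  df <- tibble::as_tibble(dge) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$gene_id %in% highlight ~ "module",
        .data$q < fdr_threshold & .data$log2fc > 0 ~ "up",
        .data$q < fdr_threshold & .data$log2fc < 0 ~ "down",
        TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(up = "#B2182B", down = "#2166AC",
                                           module = "goldenrod", ns = "grey75")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = NULL) +
    ggplot2::theme_minimal()
}
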