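#' Scatter plot of per-status allelic proportions
#'
#' One point per tested gene: mean allelic proportion in one status against
#' the other, with genes called ASE highlighted. The diagonal marks equal
#' bias in both statuses; the dashed lines mark the call threshold.
#'
#' @param results Called ASE tibble from [call_ase()].
#' @param statuses The two status labels; defaults to those found in the
#'   `mean_prop_*` columns.
#' @param prop_threshold Threshold drawn as dashed lines (default 0.65).
#' @return A ggplot object.
#' @export
plot_ase_proportions <- function(results, statuses = NULL,
                                 prop_threshold = 0.65) {
  if (is.null(statuses)) {
    statuses <- sub("^mean_prop_", "",
                    grep("^mean_prop_", names(results), value = TRUE))
  }
  if (length(statuses) != 2) abort("need exactly two statuses to plot")
  xs <- paste0("mean_prop_", statuses[1])
  ys <- paste0("mean_prop_", statuses[2])
  df <- results |> mutate(called = .data$class != "none")
  ggplot2::ggplot(df, ggplot2::aes(.data[[xs]], .data[[ys]],
                                   colour = .data$called)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = prop_threshold, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = prop_threshold, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 name = "ASE call") +
    ggplot2::coord_fixed(xlim = c(0.5, 1), ylim = c(0.5, 1)) +
    ggplot2::labs(
      x = sprintf("mean allelic proportion (%s)", statuses[1]),
      y = sprintf("mean allelic proportion (%s)", statuses[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of AMR genomic features
#'
#' Counts of called regions by annotation category (exon / intron /
#' no annotation).
#'
#' @param regions Annotated region tibble from [annotate_amrs()].
#' @return A ggplot object.
#' @export
plot_amr_features <- function(regions) {
  check_columns(regions, "feature", "`regions`")
  ggplot2::ggplot(regions, ggplot2::aes(x = .data$feature)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "regions with allele-specific methylation") +
    ggplot2::theme_minimal()
}

#' Profile plot for a fitted window
#'
#' Per-CpG methylation rates of the shared profile and the two fitted
#' epiallele profiles of one window.
#'
#' @param object An `amr_fit` from [fit_two_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot amr_fit
#' @export
autoplot.amr_fit <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(-"cpg", names_to = "model", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$cpg, .data$rate,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "window CpG", y = "methylation rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
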