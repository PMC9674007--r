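#' Funnel plot of cascade survivor counts
#'
#' @param object An `imprint_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A ggplot: surviving loci after each ordered filter.
#' @export
autoplot.imprint_cascade <- function(object, ...) {
  d <- dplyr::mutate(object$counts,
                     stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$survivors)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$survivors),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "cascade filter", y = "surviving loci",
                  title = "H3K27me3-dependent imprinting cascade") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.imprintscan_run <- function(object, ...) {
  autoplot.imprint_cascade(object$cascade, ...)
}

#' Scatter plot of allelic DHS calls
#'
#' Maternal versus paternal mean RPKM (log10, pseudocount 0.1) coloured by
#' the allelic class.
#'
#' @param calls Output of [classify_allelic_dhs()].
#' @return A ggplot.
#' @export
plot_allelic_dhs <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = log10(.data$mat_mean + 0.1),
                               y = log10(.data$pat_mean + 0.1),
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "maternal mean RPKM (log10)",
                  y = "paternal mean RPKM (log10)",
                  colour = "allelic class") +
    ggplot2::theme_minimal()
}

#' Scatter plot of allelic H3K27me3 enrichment
#'
#' Maternal versus paternal RPM with the stage's maternal-bias criterion
#' (RPM gate and fold-change line) drawn in.
#'
#' @param chip Tibble with `mat_rpm`, `pat_rpm`.
#' @param stage `"icm"` or `"zygote"` (sets the fold-change cutoff).
#' @param rpm_min Maternal RPM gate (default 0.5).
#' @return A ggplot.
#' @export
plot_chip_bias <- function(chip, stage = c("icm", "zygote"), rpm_min = 0.5) {
  stage <- match.arg(stage)
  fc <- chip_stage_fc[[stage]]
  d <- dplyr::mutate(chip, biased = chip_allelic_bias(
    .data$mat_rpm, .data$pat_rpm, stage = stage, rpm_min = rpm_min))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pat_rpm, y = .data$mat_rpm,
                                  colour = .data$biased)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = fc, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = rpm_min, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "paternal RPM", y = "maternal RPM",
                  colour = sprintf("maternal-biased (%s)", stage)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
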