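# ggplot2 views of the main result types.

#' Plot per-window genomic coverage
#'
#' One point/line per genomic window; the horizontal line marks the overall
#' coverage.
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_report <- function(object, ...) {
  d <- object$by_window
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start / 1e6,
                                  y = .data$coverage)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$overall, linetype = 2,
                        colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Window start (Mb)", y = "Genomic coverage",
                  title = sprintf("Overall coverage %.1f%%",
                                  100 * object$overall)) +
    ggplot2::ylim(0, 1)
}

#' Plot the greedy tag-selection coverage trace
#'
#' Cumulative covered targets per selection step; the diminishing-returns
#' shape is the greedy guarantee made visible.
#'
#' @param object A `tag_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tag_selection <- function(object, ...) {
  d <- object$trace
  d$cumulative <- cumsum(d$newly_covered) / max(1, length(object$targets))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Tags selected", y = "Fraction of targets covered") +
    ggplot2::ylim(0, 1)
}

#' Plot validation-filter scatter
#'
#' Dosage r-squared against Fst for every screened variant, with the
#' validation thresholds drawn; validated variants sit in the upper-left
#' region.
#'
#' @param object A `validation_report`.
#' @param cfg A [threshold_config()] for the threshold lines.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, cfg = threshold_config(),
                                       ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fst, y = .data$dosage_r2,
                               colour = .data$validated)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cfg$dosage_r2_min, linetype = 2) +
    ggplot2::geom_vline(xintercept = cfg$fst_max, linetype = 2) +
    ggplot2::labs(x = "Cross-platform Fst", y = "Dosage r²")
}

#' LD decay curve of a panel
#'
#' Mean pairwise r-squared in distance bins; block-LD panels show high
#' short-range and low long-range LD.
#'
#' @param ld An [compute_pairwise_r2()] index.
#' @param bin_bp Distance bin width (default 10 kb).
#' @return A ggplot.
#' @export
plot_ld_decay <- function(ld, bin_bp = 10000) {
  stopifnot(inherits(ld, "ld_index"))
  d <- as_tibble(ld) |>
    dplyr::filter(.data$id_i < .data$id_j) |>
    dplyr::mutate(bin = (floor(.data$dist_bp / bin_bp) + 0.5) * bin_bp) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin / 1000, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Distance (kb)", y = "Mean r²")
}
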