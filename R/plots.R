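#' Quantile-quantile plot of scan p-values
#'
#' @param scan A `scan_summary` from [genome_scan()] (or a tibble of
#'   p-values with column `p`).
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  qq <- if (inherits(scan, "scan_summary")) scan$qq else
    qq_points(scan$p[!is.na(scan$p)])
  lab <- if (inherits(scan, "scan_summary"))
    sprintf("lambda = %.3f", scan$lambda) else NULL
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of scan results
#'
#' @param scan A `scan_summary` or results tibble with `snp_id`, `p`.
#' @param snp_meta Tibble with `snp_id`, `chr`, `pos` to place SNPs.
#' @param threshold Horizontal reference line on the p scale (default 1e-4).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, snp_meta, threshold = 1e-4) {
  res <- if (inherits(scan, "scan_summary")) scan$results else tibble::as_tibble(scan)
  d <- dplyr::inner_join(res, tibble::as_tibble(snp_meta), by = "snp_id") |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::arrange(.data$chr, .data$pos) |>
    dplyr::mutate(idx = dplyr::row_number(),
                  chr_f = factor(.data$chr, levels = unique(.data$chr)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = -log10(.data$p),
                                  colour = .data$chr_f)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::labs(x = "SNP (genome order)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for genome scans (QQ plot)
#'
#' @param object A `scan_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_summary <- function(object, ...) plot_qq(object)

#' Forest-style autoplot for hazard-ratio fits
#'
#' @param object An `hr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.15) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pair-sharing profile along the genome
#'
#' @param profile The `profile` tibble from [sharing_profile()].
#' @return A ggplot object.
#' @export
plot_sharing_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$cm, y = .data$proportion)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chr, scales = "free_x") +
    ggplot2::labs(x = "Genetic position (cM)", y = "Proportion of pairs sharing") +
    ggplot2::theme_minimal()
}
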