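#' Plot methods
#'
#' `autoplot()` methods for the package's result types, in ggplot2:
#' * `fpt_density`: survival probability and arrival-time density vs time.
#' * `conditional_stats`: splitting probability, conditional mean and
#'   variance against the inactivation rate (log-log).
#' * `mfpt_shell_summary`: histograms of per-shell-voxel MFPTs and of their
#'   variant ratio (default bin widths 0.01 s and 0.1).
#' * `signal_curve`: arrival rate at the nucleus vs time.
#'
#' @param object the result object.
#' @param ... unused.
#' @param binwidth_s,binwidth_ratio histogram bin widths for the MFPT (s)
#'   and ratio panels.
#' @return a ggplot object.
#' @name fptcell-autoplot
NULL

#' @rdname fptcell-autoplot
#' @export
autoplot.fpt_density <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("f", "survival"), names_to = "quantity") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
      f = "arrival density f(t) [1/s]", survival = "survival S(t)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fptcell-autoplot
#' @export
autoplot.conditional_stats <- function(object, ...) {
  df <- object |>
    dplyr::select("lambda", "Z", "mean_s", "var_s2") |>
    tidyr::pivot_longer(-"lambda", names_to = "quantity") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
      Z = "splitting probability Z", mean_s = "conditional mean [s]",
      var_s2 = "conditional variance [s^2]"))
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(lambda ~ "[1/s]"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fptcell-autoplot
#' @export
autoplot.mfpt_shell_summary <- function(object, binwidth_s = 0.01,
                                        binwidth_ratio = 0.1, ...) {
  long <- object |>
    dplyr::select("u_ref", "u_alt") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "variant",
                        values_to = "u_s")
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$u_s, fill = .data$variant)) +
    ggplot2::geom_histogram(binwidth = binwidth_s, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "MFPT from shell voxel [s]", y = "voxels") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(object, ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth_ratio) +
    ggplot2::labs(x = "MFPT ratio (reference / alternative)", y = "voxels") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE))
    return(patchwork::wrap_plots(p1, p2, ncol = 1L))
  p2
}

#' @rdname fptcell-autoplot
#' @export
autoplot.signal_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time [s]", y = "arrival rate [molecules/s]",
      subtitle = sprintf("lambda = %g 1/s, N = %g delivered (N0 = %.3g released)",
                         attr(object, "lambda"), attr(object, "N"),
                         attr(object, "N0"))) +
    ggplot2::theme_minimal()
}
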