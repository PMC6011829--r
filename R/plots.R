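# ggplot2 views of the result types.

#' Plot a guest RMSD series with the bound-state threshold
#'
#' @param rmsd_tbl Tibble from [guest_rmsd()].
#' @param threshold Bound-state cutoff drawn as a dashed line, Angstrom.
#' @return A ggplot object.
#' @export
plot_rmsd <- function(rmsd_tbl, threshold = 5) {
  ggplot2::ggplot(rmsd_tbl,
                  ggplot2::aes(x = .data$time_ps / 1000, y = .data$rmsd)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "time (ns)", y = "guest RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot depth-metric summaries (mean and standard deviation)
#'
#' @param depth_tbl Tibble from [depth_profile()].
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(depth_tbl) {
  ggplot2::ggplot(depth_tbl,
                  ggplot2::aes(x = .data$selection, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "signed depth along cavity axis (Å)") +
    ggplot2::theme_minimal()
}

#' @describeIn residence_summary Bound/unbound timeline of the underlying
#'   series.
#' @param object A `residence_series`.
#' @export
autoplot.residence_series <- function(object, ...) {
  df <- tibble::tibble(
    time_ns = (seq_along(object$bound) - 1) * object$frame_interval / 1000,
    bound = object$bound)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns,
                                   y = as.integer(.data$bound))) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("unbound", "bound")) +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn energy_decomposition Bar chart of the components.
#' @param object An `energy_decomposition`.
#' @export
autoplot.energy_decomposition <- function(object, ...) {
  df <- tidy.energy_decomposition(object)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$energy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "energy (kcal/mol)", title = object$label) +
    ggplot2::theme_minimal()
}

#' @describeIn thermo_result Entropy components bar chart.
#' @param object A `thermo_result`.
#' @export
autoplot.thermo_result <- function(object, ...) {
  df <- tidy.thermo_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$entropy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "entropy (cal mol⁻¹ K⁻¹)",
                  title = object$title) +
    ggplot2::theme_minimal()
}
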