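#' Group mean growth curves
#'
#' Mean log-scale tumor volume per group and day (days where the group has
#' data), with per-mouse curves in the background.
#'
#' @param ds a `study_dataset`.
#' @return a ggplot object.
#' @export
plot_growth_curves <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  x <- as_tibble(ds)
  means <- dplyr::summarise(dplyr::group_by(x, .data$group, .data$day),
                            tv = exp(mean(log(.data$tv))), .groups = "drop")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$day, y = .data$tv,
                                  colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$mouse), alpha = 0.25) +
    ggplot2::geom_line(data = means, linewidth = 1.1) +
    ggplot2::geom_point(data = means) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day since treatment start",
                  y = expression("tumor volume (mm"^3*")"),
                  colour = "group") +
    ggplot2::theme_bw()
}

#' Bootstrap distribution of CI or SS
#'
#' Histogram of the bootstrap replicates with the additivity null (dashed
#' line at CI = 1 or SS = 0), the observed estimate (triangle) and the BCa
#' interval (horizontal bar).
#'
#' @param inference a `synergy_inference` from [bootstrap_synergy()].
#' @param statistic `"ci"` or `"ss"`.
#' @return a ggplot object.
#' @export
plot_bootstrap <- function(inference, statistic = c("ci", "ss")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(inference, "synergy_inference"))
  vals <- inference$boot[[statistic]]
  int <- inference$intervals[inference$intervals$statistic == statistic, ]
  null_at <- if (statistic == "ci") 1 else 0
  df <- tibble(value = vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = null_at, linetype = "dashed",
                        colour = "red") +
    ggplot2::annotate("point", x = int$estimate, y = 0, shape = 17, size = 3) +
    ggplot2::annotate("segment", x = int$lower, xend = int$upper,
                      y = 0, yend = 0, colour = "blue", linewidth = 1.2) +
    ggplot2::labs(
      x = toupper(statistic),
      y = "bootstrap count",
      title = sprintf("%s, %s model: %s [%.0f%%: %s, %s], P = %s",
                      toupper(statistic), inference$observed$model,
                      format(int$estimate, digits = 3),
                      100 * inference$config$level,
                      format(int$lower, digits = 3),
                      format(int$upper, digits = 3),
                      format_p(inference$p[[statistic]]))
    ) +
    ggplot2::theme_bw()
}

#' Power curves over mice per group
#'
#' @param result a `power_result` from [power_grid()]; must include an
#'   `n_per_group` grid column. Any second grid column (e.g. `dt`, `t_obs`)
#'   is mapped to colour.
#' @return a ggplot object.
#' @export
plot_power_curves <- function(result) {
  stopifnot(inherits(result, "power_result"),
            "n_per_group" %in% names(result))
  other <- intersect(c("dt", "t_obs", "tv_max"), names(result))
  p <- ggplot2::ggplot(result,
                       ggplot2::aes(x = .data$n_per_group, y = .data$power))
  if (length(other) > 0) {
    p <- p + ggplot2::aes(colour = factor(.data[[other[1]]])) +
      ggplot2::labs(colour = other[1])
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "mice per group", y = "empirical power") +
    ggplot2::theme_bw()
}
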