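#' Plot methods
#'
#' `autoplot.km_curve()` draws the product-limit step function;
#' `plot_monthly_costs()` the per-interval (conditional-mean) cost series by
#' cohort; `plot_balance()` a love plot of standardized differences before
#' and after matching.
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1),
                  as_tibble(object)[c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days from index", y = "survival probability")
}

#' @rdname autoplot.km_curve
#' @param report A `study_report`.
#' @export
plot_monthly_costs <- function(report) {
  m <- report$monthly %>%
    tidyr::pivot_longer(c("cost_inpatient", "cost_outpatient"),
                        names_to = "setting", values_to = "cost") %>%
    mutate(setting = sub("cost_", "", .data$setting))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$interval, y = .data$cost,
                                  colour = .data$cohort,
                                  linetype = .data$setting)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(m$interval)) +
    ggplot2::labs(x = "post-index month", y = "mean cost among at-risk",
                  colour = "cohort", linetype = "setting")
}

#' @rdname autoplot.km_curve
#' @export
plot_balance <- function(report) {
  d <- bind_rows(
    report$balance_pre %>% mutate(stage = "pre-match"),
    report$balance_post %>% mutate(stage = "post-match"))
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$std_diff_raw),
                                  y = .data$covariate,
                                  colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardized difference|", y = NULL,
                  colour = NULL)
}
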