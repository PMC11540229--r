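#' Scatter plot of a cumulative-burden fit
#'
#' Observed per-chromosome values against their cumulative-score prediction,
#' with the OLS line and its 95% mean-response confidence band.
#'
#' @param fit A [fit_burden_model()] result.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_burden_fit <- function(fit, xlab = "predicted (cumulative score)",
                            ylab = "observed") {
  stopifnot(inherits(fit, "burden_fit"))
  ggplot2::ggplot(fit$data,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         color = "grey30", fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$chromosome),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("adj. R² = %.2f, p = %.2g",
                         fit$adj_r_squared, fit$f_p_value)) +
    ggplot2::theme_classic()
}

#' Bar plot of observed versus expected growth under NTC
#'
#' Observed rates as solid bars with the multiplicative-null expectation as
#' a dashed outline, one pair per strain, annotated with significance tiers.
#'
#' @param results List of `interaction_result` objects.
#' @param relative Plot rates relative to each strain's untreated control
#'   when available.
#' @return A ggplot object.
#' @export
plot_interaction <- function(results, relative = FALSE) {
  df <- do.call(rbind, lapply(results, function(r) {
    obs <- if (relative && !is.na(r$mean_observed_rel)) r$mean_observed_rel
           else r$mean_observed
    exp_ <- if (relative && !is.na(r$mean_expected_rel)) r$mean_expected_rel
            else r$mean_expected
    data.frame(strain = r$strain, observed = obs, expected = exp_,
               tier = r$tier, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$expected,
                                        ymax = .data$expected),
                           linetype = "dashed", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(y = pmax(.data$observed,
                                             .data$expected),
                                    label = ifelse(.data$tier == "ns", "",
                                                   .data$tier)),
                       vjust = -0.5) +
    ggplot2::labs(y = if (relative) "growth rate (relative to no NTC)"
                      else "growth rate (per hour)",
                  x = NULL) +
    ggplot2::theme_classic()
}

#' Density plot of fitness-score distributions per strain
#'
#' @param fitness Long fitness table (`gene`, `strain`, `score`).
#' @return A ggplot object.
#' @export
plot_fitness_distributions <- function(fitness) {
  ggplot2::ggplot(fitness, ggplot2::aes(x = .data$score,
                                        color = .data$strain)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "fitness score (log2 fold-change)", y = "density") +
    ggplot2::theme_classic()
}
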