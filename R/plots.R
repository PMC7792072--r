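# ggplot2 methods for the package's result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.gsd_plan <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$info_fraction, y = .data$z_bound)) +
    ggplot2::geom_step(direction = "vh", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p = %.4f", .data$nominal_p_two_sided)),
      vjust = -1, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "information fraction", y = "efficacy z boundary",
                  title = sprintf("O'Brien-Fleming boundaries (two-sided alpha %.3g)",
                                  attr(object, "alpha_two_sided"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.trial_run <- function(object, ...) {
  pat <- dplyr::arrange(object$patients, .data$entry_time)
  pat <- dplyr::group_by(pat, .data$arm)
  pat <- dplyr::mutate(pat, cum = dplyr::row_number())
  pat <- dplyr::ungroup(pat)
  starts <- object$stages$start_time
  ggplot2::ggplot(pat, ggplot2::aes(x = .data$entry_time, y = .data$cum,
                                    colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = starts[!is.na(starts)],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "years from trial start", y = "cumulative randomised",
                  colour = "arm",
                  title = "Staged recruitment (dashed lines: stage starts)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.oc_report <- function(object, ...) {
  df <- object$per_hypothesis
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - 2 * .data$mc_se,
                                        ymax = .data$rate + 2 * .data$mc_se),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "rejection rate",
                  title = sprintf("Operating characteristics (%d replicates)",
                                  object$reps)) +
    ggplot2::theme_minimal()
}

#' Plot an empirical power curve
#'
#' @param curve Output of [power_curve()].
#' @return A ggplot.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value, y = .data$rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - 2 * .data$mc_se,
                                      ymax = .data$rate + 2 * .data$mc_se),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "true effect size", y = "empirical power") +
    ggplot2::theme_minimal()
}
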