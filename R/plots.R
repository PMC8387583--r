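# ggplot2 views of the main result types.

#' @describeIn run_chain Plot the token-weighted mean reduction trajectory.
#' @param object A `chain_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.chain_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$generation, y = .data$mean_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Token-weighted mean reduction",
                  title = paste0("Chain outcome: ", object$outcome))
}

#' @describeIn run_ensemble Plot all chain trajectories, colored by
#'   outcome.
#' @param object An `ensemble_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_result <- function(object, ...) {
  traj <- purrr::imap(object$chains, function(ch, i) {
    dplyr::mutate(ch$trajectory, chain = i, outcome = ch$outcome)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(traj,
                  ggplot2::aes(x = .data$generation, y = .data$mean_p,
                               group = .data$chain,
                               colour = .data$outcome)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Token-weighted mean reduction",
                  colour = "Outcome")
}

#' @describeIn frequency_effect_curve Plot the binned frequency effect
#'   (median with interquartile ribbon over frequency rank bins).
#' @param object A `frequency_effect_curve`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_effect_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "red",
                       linewidth = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Frequency rank bin (low to high)",
                  y = "Reduction probability")
}

#' @describeIn probability_distribution Bar chart of mean type counts per
#'   probability bin (log-scaled counts).
#' @param object A `distribution_table`.
#' @exportS3Method ggplot2::autoplot
autoplot.distribution_table <- function(object, ...) {
  d <- dplyr::mutate(object, bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Reduction probability", y = "Mean word types") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
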