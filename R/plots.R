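severity_palette <- c(severe = "#C0392B", moderate = "#E67E22",
                      mild = "#27AE60", overall = "#2C3E50",
                      sham = "#7F8C8D")

#' Plot Kaplan-Meier curves per severity class
#'
#' @param object A `rob_km` object from [km_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rob_km
#' @export
autoplot.rob_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$severity)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$n_censor > 0),
                        shape = 3, size = 2) +
    ggplot2::scale_colour_manual(values = severity_palette) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "post-operative day", y = "survival probability",
                  colour = "severity") +
    ggplot2::theme_minimal()
}

#' Plot cumulative mortality over post-operative days
#'
#' @param mortality Output of [mortality_table()].
#' @return A ggplot.
#' @export
plot_mortality <- function(mortality) {
  ggplot2::ggplot(mortality,
                  ggplot2::aes(x = .data$day, y = .data$mortality_pct,
                               colour = .data$severity)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = severity_palette) +
    ggplot2::labs(x = "post-operative day", y = "cumulative mortality (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot daily ROB totals per animal
#'
#' One line per animal, coloured by day-1 severity class when a
#' `severity` column is present; the 3--15 range and the severity band
#' boundaries are marked.
#'
#' @param scores Data frame with `animal_id`, `day`, `total` and
#'   optionally `severity`.
#' @param criteria A [rob_criteria()] for the band boundaries.
#' @return A ggplot.
#' @export
plot_score_trends <- function(scores, criteria = rob_criteria()) {
  scores <- as_tibble(scores)
  mapping <- if ("severity" %in% names(scores))
    ggplot2::aes(x = .data$day, y = .data$total, group = .data$animal_id,
                 colour = .data$severity)
  else
    ggplot2::aes(x = .data$day, y = .data$total, group = .data$animal_id)
  p <- ggplot2::ggplot(scores, mapping) +
    ggplot2::geom_hline(yintercept = criteria$severity_cuts + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_continuous(limits = c(3, 15),
                                breaks = seq(3, 15, by = 2)) +
    ggplot2::labs(x = "post-operative day", y = "ROB total", colour = NULL) +
    ggplot2::theme_minimal()
  if ("severity" %in% names(scores))
    p <- p + ggplot2::scale_colour_manual(values = severity_palette)
  p
}
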