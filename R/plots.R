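# ggplot2 visualisations for the main result types.

#' Plot session performance across learning
#'
#' @param performance tibble with `correct_per_min`, `incorrect_per_min`
#'   (one row per session, chronological) and optionally `stage`.
#' @return a ggplot.
#' @export
plot_performance <- function(performance) {
  df <- performance
  df$session <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(
    df, c("correct_per_min", "incorrect_per_min"),
    names_to = "path_type", values_to = "rate"
  )
  long$path_type <- sub("_per_min$", "", long$path_type)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$session, y = .data$rate, colour = .data$path_type
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "session", y = "paths / min", colour = NULL)
  if ("stage" %in% names(df)) {
    breaks <- df$session[c(TRUE, diff(df$stage) > 0)]
    p <- p + ggplot2::geom_vline(xintercept = breaks, linetype = 3,
                                 colour = "grey50")
  }
  p
}

#' @describeIn population_curves plot the population z-score curves with
#'   their Bonferroni bands; dotted vertical lines separate the six task
#'   events.
#' @param object a `"population_curves"` tibble.
#' @param ... unused.
#' @method autoplot population_curves
#' @export
autoplot.population_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin_index, y = .data$mean_z,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_vline(xintercept = seq(5.5, 25.5, by = 5),
                        linetype = 3, colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(
      breaks = seq(3, 28, by = 5), labels = task_events()
    ) +
    ggplot2::labs(x = "task event (five 100 ms bins each)",
                  y = "mean z-score")
}

#' @describeIn classify_units scatter of the waveform feature space
#'   coloured by assigned type.
#' @param object a `"unit_classification"`.
#' @param ... unused.
#' @method autoplot unit_classification
#' @export
autoplot.unit_classification <- function(object, ...) {
  feats <- attr(object, "features")
  df <- dplyr::left_join(feats, tibble::as_tibble(object), by = "unit_id")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pv_us, y = .data$log_rate, colour = .data$type
  )) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w_us), alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "peak-valley distance", y = "log firing rate",
                  size = "width at half height", colour = NULL)
}

#' @describeIn fit_hawkes_network heat map of interaction strengths per
#'   condition.
#' @param object a `"hawkes_network"`.
#' @param ... unused.
#' @method autoplot hawkes_network
#' @export
autoplot.hawkes_network <- function(object, ...) {
  edges <- interaction_strengths(object)
  ggplot2::ggplot(edges, ggplot2::aes(
    x = factor(.data$source), y = factor(.data$target),
    fill = .data$strength
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "source unit", y = "target unit",
                  fill = "|h| (Hz)")
}

#' @describeIn session_decoding_power decoding power against the
#'   random-guess reference.
#' @param object a `"decoding_result"`.
#' @param ... unused.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tibble::tibble(
    what = c("decoding power", "random guess"),
    value = c(object$power, object$reference)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$value)) +
    ggplot2::geom_col(width = 0.5, fill = c("steelblue", "grey70")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "proportion of correct guesses",
                  title = sprintf("%s model", object$model))
}

#' Plot entropy stage contrasts with bootstrap intervals
#'
#' @param contrasts tibble from [entropy_stage_contrast()].
#' @return a ggplot.
#' @export
plot_entropy_contrast <- function(contrasts) {
  ggplot2::ggplot(contrasts, ggplot2::aes(
    x = factor(.data$stage), y = .data$delta, colour = .data$region
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "learning stage", y = "entropy difference vs stage 1")
}
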