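#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumsum learning curve with its detection geometry
#'
#' Shows the cumulative sum of the per-trial response, the final diagonal
#' used by the learned-trial detector, and the detected learned trial.
#'
#' @param object A [cumsum_change_point()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.learned_trial <- function(object, ...) {
  s <- object$cumsum
  df <- tibble::tibble(trial = seq_along(s), cumsum = s)
  anchor <- object$anchor
  diag_df <- tibble::tibble(
    trial = c(0, anchor),
    cumsum = c(0, s[anchor])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$cumsum)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = diag_df, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Trial", y = "Cumulative response",
                  title = "Cumsum learning curve") +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- p + ggplot2::geom_vline(xintercept = object$learned_trial,
                                 colour = "firebrick")
  }
  p
}

#' Plot a log-log IRI scaling fit
#'
#' @param object A [fit_loglog()] result.
#' @param ... Unused.
#' @return A ggplot with points (if available) and the fitted power law on
#'   log-log axes.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  rng <- if (is.null(object$points)) c(30, 4000) else
    range(object$points$iri_s) * c(0.8, 1.25)
  line_df <- tibble::tibble(
    iri_s = exp(seq(log(rng[1]), log(rng[2]), length.out = 50))
  )
  line_df$trials <- predict_trials(object, line_df$iri_s)
  p <- ggplot2::ggplot(line_df,
                       ggplot2::aes(x = .data$iri_s, y = .data$trials)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Inter-reward interval (s)", y = "Trials to learn",
                  title = sprintf("log10(trials) = %.2f log10(IRI) + %.2f",
                                  object$slope, object$intercept)) +
    ggplot2::theme_minimal()
  if (!is.null(object$points)) {
    p <- p + ggplot2::geom_point(data = object$points,
                                 ggplot2::aes(y = .data$trials))
  }
  p
}

#' Plot a simulated association quantity across trials
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot of the per-trial quantity with the behavior threshold
#'   and learned trial marked.
#' @export
autoplot.sim_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$per_trial,
                       ggplot2::aes(x = .data$trial_index, y = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Trial", y = "Association quantity",
                  title = paste("Model:", object$model)) +
    ggplot2::theme_minimal()
  if (!is.na(object$learned_trial)) {
    p <- p + ggplot2::geom_vline(xintercept = object$learned_trial,
                                 colour = "firebrick")
  }
  p
}

#' Lick raster around cue onsets
#'
#' @param licks A `lick_train`.
#' @param schedule An `event_schedule`.
#' @param window_s Plot window around cue onset (default c(-2, 5)).
#' @return A ggplot raster (trials by time from cue).
#' @export
plot_lick_raster <- function(licks, schedule, window_s = c(-2, 5)) {
  cues <- schedule[schedule$event_type == "cs_plus", ]
  rows <- purrr::map_dfr(seq_len(nrow(cues)), function(k) {
    rel <- licks$onset_s - cues$time_s[k]
    rel <- rel[rel >= window_s[1] & rel <= window_s[2]]
    if (length(rel) == 0) return(NULL)
    tibble::tibble(trial = cues$trial_index[k], t = rel)
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$t, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1.25, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time from cue onset (s)", y = "Trial") +
    ggplot2::theme_minimal()
}
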