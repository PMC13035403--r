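#' Per-trial cue-evoked licking
#'
#' For every trial, counts lick onsets in the 1.25-s window from cue onset
#' to reward delivery and subtracts the count in the 1.25-s baseline window
#' directly before cue onset. The difference ("cue-evoked licks"), divided
#' by the window length, is the delta lick rate to cue, the study's primary
#' behavioral measure of learning.
#'
#' @param licks A `lick_train` tibble (columns `onset_s`, `offset_s`).
#' @param schedule An `event_schedule` sharing the same session clock.
#' @return Tibble with one row per trial: `trial_index`, `session_index`,
#'   `cue_time_s`, `rewarded`, `licks_pre`, `licks_cue`, `delta_licks`,
#'   `delta_rate_hz`, and `flag_pre_session` for trials whose baseline
#'   window precedes the session start (these are excluded).
#' @export
cue_evoked_licks <- function(licks, schedule) {
  cues <- schedule[schedule$event_type == "cs_plus", ]
  spec <- attr(schedule, "spec")
  tp <- if (is.null(spec)) 1.25 else trial_period(spec)
  starts <- schedule$time_s[schedule$event_type == "session_start"]
  sess_start <- starts[cues$session_index]
  onsets <- licks$onset_s
  count_in <- function(lo, hi) {
    vapply(seq_along(lo), function(i) {
      sum(onsets >= lo[i] & onsets < hi[i])
    }, integer(1))
  }
  pre <- count_in(cues$time_s - tp, cues$time_s)
  post <- count_in(cues$time_s, cues$time_s + tp)
  bad <- cues$time_s - tp < sess_start
  out <- tibble::tibble(
    trial_index = cues$trial_index,
    session_index = cues$session_index,
    cue_time_s = cues$time_s,
    rewarded = cues$trial_index %in%
      schedule$trial_index[schedule$event_type == "reward"],
    licks_pre = pre,
    licks_cue = post,
    delta_licks = post - pre,
    delta_rate_hz = (post - pre) / tp,
    flag_pre_session = bad
  )
  out[!out$flag_pre_session, ]
}

#' Learned-trial detection from the cumulative sum of a per-trial response
#'
#' Takes the cumulative sum of a per-trial series (cue-evoked licks or
#' normalized dopamine responses), draws a diagonal from the origin to the
#' end of the cumsum curve, and finds the first trial whose vertical
#' distance to the diagonal is within 75% of the maximum distance. That
#' trial marks the inflection after which the conditioned response emerges
#' (the "learned trial"). If the diagonal lies below the curve at the
#' detected trial -- the response was decreasing there, which happens when
#' post-learning responding tapers off -- the diagonal endpoint is
#' re-anchored at that trial's cumsum point and the algorithm reruns until
#' the diagonal lies above the curve at the detected trial.
#'
#' The distance threshold is applied to the unsigned vertical distance; a
#' series whose cumsum never falls below the diagonal (no positive-going
#' inflection) is degenerate and yields no learned trial. Ties at the 75%
#' threshold resolve to the earliest trial.
#'
#' @param series Numeric per-trial values (length >= 3).
#' @param direction `"positive"` (default) to detect an upward inflection,
#'   `"negative"` to detect a downward one (the series is negated first, as
#'   for omission dips or cue responses that develop a dip).
#' @param threshold_frac Fraction of the maximum distance (default 0.75).
#' @param end_anchor Optional trial index at which to anchor the diagonal's
#'   endpoint instead of the final trial (used for dopamine learned trials,
#'   where the anchor is 1.5x the behavioral learned trial).
#' @param max_iter Cap on re-anchoring iterations (default: series length).
#' @return An object of class `learned_trial` (list): `learned_trial`
#'   (integer or `NA`), `degenerate`, `max_distance`, `threshold_distance`,
#'   `abruptness` (distance at the learned trial normalized so the top of
#'   the final diagonal equals 1), `direction`, `n_reanchor_iterations`,
#'   `anchor` (final endpoint), `cumsum` and the input length.
#' @export
#' @examples
#' res <- cumsum_change_point(c(rep(0, 20), rep(5, 20)))
#' res$learned_trial  # 15
#' res$abruptness     # 0.375
cumsum_change_point <- function(series,
                                direction = c("positive", "negative"),
                                threshold_frac = 0.75,
                                end_anchor = NULL,
                                max_iter = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(series), threshold_frac > 0, threshold_frac <= 1)
  if (length(series) < 3) {
    stop("series must have at least 3 trials", call. = FALSE)
  }
  x <- if (direction == "negative") -series else series
  n <- length(x)
  s <- c(0, cumsum(x))                # s[i + 1] = S_i, S_0 = 0
  anchor <- if (is.null(end_anchor)) n else min(as.integer(end_anchor), n)
  stopifnot(anchor >= 2)
  max_iter <- max_iter %||% n
  degenerate_result <- function(iter) {
    new_learned_trial(NA_integer_, TRUE, NA_real_, NA_real_, NA_real_,
                      direction, iter, anchor, s, n)
  }
  # scale-relative tolerance: rounding noise on a numerically flat cumsum
  # must not masquerade as an inflection
  tol <- 1e-10 * max(abs(s), 1)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    i <- seq_len(anchor)
    d <- s[anchor + 1] * i / anchor - s[i + 1]  # diagonal minus curve
    if (max(d) <= tol) return(degenerate_result(iter))
    dmax <- max(abs(d))
    learned <- which(abs(d) >= threshold_frac * dmax - 1e-12)[1]
    if (d[learned] >= 0) {
      return(new_learned_trial(
        learned, FALSE, dmax, threshold_frac * dmax,
        abruptness = d[learned] / s[anchor + 1],
        direction, iter, anchor, s, n
      ))
    }
    if (learned >= anchor || iter >= max_iter) return(degenerate_result(iter))
    anchor <- learned
  }
}

new_learned_trial <- function(learned, degenerate, max_distance,
                              threshold_distance, abruptness, direction,
                              iter, anchor, s, n) {
  structure(
    list(
      learned_trial = as.integer(learned),
      degenerate = degenerate,
      max_distance = max_distance,
      threshold_distance = threshold_distance,
      abruptness = abruptness,
      direction = direction,
      n_reanchor_iterations = iter,
      anchor = as.integer(anchor),
      cumsum = s[-1],
      n_trials = as.integer(n)
    ),
    class = "learned_trial"
  )
}

#' @export
print.learned_trial <- function(x, ...) {
  if (x$degenerate) {
    cat("<learned_trial> degenerate (no", x$direction, "inflection)\n")
  } else {
    cat(sprintf(
      "<learned_trial> trial %d of %d (%s direction, abruptness %.3f, %d iteration%s)\n",
      x$learned_trial, x$n_trials, x$direction, x$abruptness,
      x$n_reanchor_iterations, if (x$n_reanchor_iterations > 1) "s" else ""
    ))
  }
  invisible(x)
}

#' Abruptness of learning at the detected trial
#'
#' Distance from the cumsum curve to the diagonal at the learned trial, in
#' normalized units where the top of the (final) diagonal equals 1.
#'
#' @param result A [cumsum_change_point()] result.
#' @return Numeric in `[-1, 1]`, or `NA` for a degenerate result.
#' @export
abruptness <- function(result) {
  stopifnot(inherits(result, "learned_trial"))
  if (result$degenerate) NA_real_ else result$abruptness
}

#' Classify learner status from per-session delta lick rates
#'
#' A mouse counts as a learner if at least two sessions show an average
#' increase in lick rate to cue above 0.5 Hz; otherwise it is a non-learner
#' and excluded from learned-trial comparisons.
#'
#' @param per_session_delta_rates Session-mean delta lick rates, Hz
#'   (length >= 2).
#' @param min_rate_hz Threshold (default 0.5 Hz).
#' @param min_sessions Number of sessions required above threshold
#'   (default 2).
#' @return Logical flag.
#' @export
classify_learner <- function(per_session_delta_rates, min_rate_hz = 0.5,
                             min_sessions = 2) {
  stopifnot(length(per_session_delta_rates) >= 2)
  sum(per_session_delta_rates > min_rate_hz) >= min_sessions
}

#' Align trial 1 to the first consumed reward
#'
#' Because some mice do not initially consume reward, "trial 1" is defined
#' as the first rewarded trial on which the mouse licked within 5 s of
#' reward delivery; earlier trials are dropped before analysis. For partial
#' reinforcement protocols, where omission trials must be counted, use
#' `mode = "raw"`, which always returns 1.
#'
#' @param licks A `lick_train`.
#' @param schedule An `event_schedule`.
#' @param mode `"first_consumption"` (default) or `"raw"`.
#' @param window_s Consumption window after delivery (default 5 s).
#' @return Integer trial offset (the trial to re-index as trial 1).
#' @export
align_trial_one <- function(licks, schedule,
                            mode = c("first_consumption", "raw"),
                            window_s = 5) {
  mode <- match.arg(mode)
  if (mode == "raw") return(1L)
  rewards <- schedule[schedule$event_type == "reward", ]
  if (nrow(rewards) == 0) stop("schedule has no rewarded trials", call. = FALSE)
  onsets <- licks$onset_s
  for (i in seq_len(nrow(rewards))) {
    rt <- rewards$time_s[i]
    if (any(onsets >= rt & onsets <= rt + window_s)) {
      return(as.integer(rewards$trial_index[i]))
    }
  }
  stop("alignment failure: no reward was ever consumed within the window",
       call. = FALSE)
}

#' Count rewards delivered before a trial
#'
#' @param schedule An `event_schedule`.
#' @param trial_index 1-based trial number.
#' @return Integer count of reward events on trials before `trial_index`
#'   (used to convert trials-to-learn into rewards-to-learn under partial
#'   reinforcement).
#' @export
rewards_before_trial <- function(schedule, trial_index) {
  rw <- schedule[schedule$event_type == "reward", ]
  sum(rw$trial_index < trial_index)
}

#' Total conditioning time until learning
#'
#' Cumulative duration of all conditioning time (ITIs plus trial periods)
#' from conditioning start up to, but not including, the trial period
#' following the learned trial; under the leading-ITI convention this is
#' `L` trial blocks plus `L + 1` ITIs. If the learned trial is the final
#' trial, the sum runs through the end of the final session.
#'
#' @param schedule An `event_schedule`.
#' @param learned_trial Learned trial index (>= 1) or a `learned_trial`
#'   object.
#' @return Seconds.
#' @export
total_time_to_learn <- function(schedule, learned_trial) {
  if (inherits(learned_trial, "learned_trial")) {
    if (learned_trial$degenerate) {
      stop("no learned trial: detector result is degenerate", call. = FALSE)
    }
    learned_trial <- learned_trial$learned_trial
  }
  stopifnot(learned_trial >= 1)
  n <- sum(schedule$event_type == "cs_plus")
  if (learned_trial + 1 <= n) {
    elapsed_time_before_trial(schedule, learned_trial + 1)
  } else {
    total_conditioning_duration(schedule)
  }
}

#' Lick rate during intertrial intervals
#'
#' For each trial, the ITI window runs from the session start or the end of
#' the previous consumption bout (the run of licks starting with the first
#' lick after reward delivery in which consecutive contact-off to
#' contact-on gaps are at most 500 ms) to the onset of the next cue. The
#' rate is lick onsets per second of window; zero-length windows are
#' excluded.
#'
#' @param licks A `lick_train` with `onset_s` and `offset_s`.
#' @param schedule An `event_schedule`.
#' @param max_gap_s Within-bout gap criterion (default 0.5 s).
#' @return List with `per_iti` (tibble: `trial_index`, `window_start_s`,
#'   `window_end_s`, `n_licks`, `rate_hz`) and `median_rate_hz`.
#' @export
iti_lick_rate <- function(licks, schedule, max_gap_s = 0.5) {
  cues <- schedule[schedule$event_type == "cs_plus", ]
  rewards <- schedule[schedule$event_type == "reward", ]
  starts <- schedule$time_s[schedule$event_type == "session_start"]
  spec <- attr(schedule, "spec")
  tb <- if (is.null(spec)) 4.25 else trial_block(spec)
  onsets <- licks$onset_s
  offsets <- licks$offset_s

  bout_end_after <- function(reward_time) {
    i <- which(onsets >= reward_time)[1]
    if (is.na(i)) return(reward_time)
    end <- offsets[i]
    while (i < length(onsets) && onsets[i + 1] - offsets[i] <= max_gap_s) {
      i <- i + 1
      end <- offsets[i]
    }
    end
  }

  rows <- purrr::map_dfr(seq_len(nrow(cues)), function(k) {
    cue_t <- cues$time_s[k]
    sess <- cues$session_index[k]
    if (k == 1 || cues$session_index[k - 1] != sess) {
      w0 <- starts[sess]
    } else {
      prev_trial <- cues$trial_index[k - 1]
      prev_cue <- cues$time_s[k - 1]
      rw <- rewards$time_s[rewards$trial_index == prev_trial]
      w0 <- if (length(rw) == 1) {
        max(bout_end_after(rw), rw)
      } else {
        prev_cue + tb
      }
    }
    tibble::tibble(
      trial_index = cues$trial_index[k],
      window_start_s = w0,
      window_end_s = cue_t
    )
  })
  rows <- rows[rows$window_end_s > rows$window_start_s, ]
  rows$n_licks <- vapply(seq_len(nrow(rows)), function(i) {
    sum(onsets >= rows$window_start_s[i] & onsets < rows$window_end_s[i])
  }, numeric(1))
  rows$rate_hz <- rows$n_licks / (rows$window_end_s - rows$window_start_s)
  list(per_iti = rows, median_rate_hz = stats::median(rows$rate_hz))
}

#' Four-parameter logistic fit to a per-trial response
#'
#' Least-squares fit of `y = L / (1 + exp(-k (x - x0))) + b` to a per-trial
#' response series (e.g. normalized cue dopamine across omission trials),
#' reporting the half-rise trial (`x0`) and the 95%-rise trial
#' (`x0 + log(19) / k`).
#'
#' @param series Per-trial response values (length >= 5).
#' @param trials Optional trial indices (default `seq_along(series)`).
#' @return Object of class `sigmoid_fit`: list with `converged`,
#'   parameters `L`, `k`, `x0`, `b`, `half_rise_trial`,
#'   `rise95_trial`, `fitted` and the data. Non-convergence (including flat
#'   series) yields `converged = FALSE` with `NA` parameters.
#' @export
sigmoid_fit <- function(series, trials = seq_along(series)) {
  stopifnot(length(series) >= 5, length(trials) == length(series))
  df <- data.frame(x = trials, y = series)
  if (stats::sd(series) < 1e-12) {
    return(structure(
      list(converged = FALSE, L = NA_real_, k = NA_real_, x0 = NA_real_,
           b = NA_real_, half_rise_trial = NA_real_, rise95_trial = NA_real_,
           fitted = NULL, data = df),
      class = "sigmoid_fit"
    ))
  }
  start <- list(
    L = max(series) - min(series),
    k = 4 / max(diff(range(trials)), 1),
    x0 = trials[which.min(abs(series - stats::median(series)))],
    b = min(series)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - x0))) + b,
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::nls(y ~ L / (1 + exp(-k * (x - x0))) + b, data = df,
                 start = start, control = list(maxiter = 500, warnOnly = TRUE)),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    return(structure(
      list(converged = FALSE, L = NA_real_, k = NA_real_, x0 = NA_real_,
           b = NA_real_, half_rise_trial = NA_real_, rise95_trial = NA_real_,
           fitted = NULL, data = df),
      class = "sigmoid_fit"
    ))
  }
  p <- as.list(stats::coef(fit))
  structure(
    list(
      converged = TRUE, L = p$L, k = p$k, x0 = p$x0, b = p$b,
      half_rise_trial = p$x0,
      rise95_trial = p$x0 + log(19) / p$k,
      fitted = stats::fitted(fit), data = df, fit = fit
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> did not converge\n")
  } else {
    cat(sprintf(
      "<sigmoid_fit> L = %.4g, k = %.4g, x0 = %.4g, b = %.4g (half-rise %.1f, 95%% %.1f)\n",
      x$L, x$k, x$x0, x$b, x$half_rise_trial, x$rise95_trial
    ))
  }
  invisible(x)
}
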