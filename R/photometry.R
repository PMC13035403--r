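#' Isosbestic-corrected dF/F from a two-channel photometry trace
#'
#' Fits the 405-nm (isosbestic, dopamine-insensitive) channel to the 470-nm
#' channel with ordinary least squares over each session, then expresses the
#' session-wide dF/F as `100 * (f470 - fitted405) / fitted405`. The linear
#' fit scales and aligns the isosbestic channel so that shared motion or
#' bleaching artifacts cancel.
#'
#' @param trace A `photometry_trace` tibble (`session_index`, `time_s`,
#'   `f470`, `f405`).
#' @return Tibble of class `dff_trace` with columns `session_index`,
#'   `time_s`, `dff_percent`, plus a per-session `fits` attribute holding
#'   `fit_slope` and `fit_intercept`.
#' @export
fit_dff <- function(trace) {
  stopifnot(all(c("time_s", "f470", "f405") %in% names(trace)))
  sess <- trace$session_index %||% rep(1L, nrow(trace))
  if (is.null(trace$session_index)) trace$session_index <- sess
  fits <- list()
  dff <- numeric(nrow(trace))
  for (s in unique(sess)) {
    i <- which(sess == s)
    f405 <- trace$f405[i]
    f470 <- trace$f470[i]
    if (stats::sd(f405) < 1e-12) {
      stop("isosbestic channel is constant: singular dF/F fit", call. = FALSE)
    }
    cf <- stats::lsfit(f405, f470)$coefficients
    fitted <- cf[1] + cf[2] * f405
    dff[i] <- 100 * (f470 - fitted) / fitted
    fits[[as.character(s)]] <- tibble::tibble(
      session_index = s, fit_intercept = unname(cf[1]), fit_slope = unname(cf[2])
    )
  }
  out <- tibble::tibble(
    session_index = trace$session_index,
    time_s = trace$time_s,
    dff_percent = dff
  )
  structure(out, class = c("dff_trace", class(out)),
            fits = dplyr::bind_rows(fits))
}

# trapezoidal AUC of dff over [start, start + width), on the native grid
window_auc <- function(dff, start, width) {
  t <- dff$time_s
  y <- dff$dff_percent
  i <- which(t >= start & t < start + width)
  if (length(i) < 2) return(list(auc = NA_real_, truncated = TRUE))
  truncated <- start < t[1] || start + width > t[length(t)] + (t[2] - t[1])
  auc <- sum(diff(t[i]) * (y[i][-1] + y[i][-length(i)]) / 2)
  list(auc = auc, truncated = truncated)
}

window_peak <- function(dff, start, width, baseline_start, baseline_width) {
  t <- dff$time_s
  y <- dff$dff_percent
  i <- which(t >= start & t < start + width)
  j <- which(t >= baseline_start & t < baseline_start + baseline_width)
  if (length(i) == 0 || length(j) == 0) return(NA_real_)
  max(y[i]) - mean(y[j])
}

#' Cue-evoked dopamine response
#'
#' AUC of the dF/F signal for 0.5 s following cue onset minus the AUC of
#' the 0.5-s baseline directly preceding cue onset (trapezoid on the native
#' sampling grid, half-open windows).
#'
#' @param dff A [fit_dff()] `dff_trace`.
#' @param cue_onset Cue onset time, s.
#' @param window_s Response/baseline window width (default 0.5 s).
#' @return Baseline-subtracted AUC (a.u.); `NA` with a warning-free
#'   truncation if a window falls off the trace edge.
#' @export
cue_response <- function(dff, cue_onset, window_s = 0.5) {
  post <- window_auc(dff, cue_onset, window_s)
  pre <- window_auc(dff, cue_onset - window_s, window_s)
  structure(post$auc - pre$auc,
            truncated = post$truncated || pre$truncated)
}

#' Reward-evoked dopamine response
#'
#' AUC for 0.5 s following the first detected lick after reward delivery
#' minus the AUC of the trial's 0.5-s pre-cue baseline. If a lick contact
#' spans the delivery time, or no lick occurs within the consumption
#' horizon, the window is anchored at the delivery time instead.
#'
#' @param dff A `dff_trace`.
#' @param reward_time Reward delivery time, s.
#' @param cue_onset Cue onset of the same trial (baseline anchor), s.
#' @param licks A `lick_train` (may be `NULL`: anchor falls back to
#'   delivery).
#' @param window_s Window width (default 0.5 s; use 2 s for the
#'   omission-matched normalizer).
#' @param horizon_s How far after delivery to search for the first lick
#'   (default 3 s, the consumption period).
#' @return Baseline-subtracted AUC with attributes `anchor` (time used)
#'   and `fallback` (no lick found).
#' @export
reward_response <- function(dff, reward_time, cue_onset, licks = NULL,
                            window_s = 0.5, horizon_s = 3) {
  anchor <- reward_time
  fallback <- TRUE
  if (!is.null(licks) && nrow(licks) > 0) {
    spanning <- any(licks$onset_s <= reward_time & licks$offset_s >= reward_time)
    if (spanning) {
      anchor <- reward_time
      fallback <- FALSE
    } else {
      nxt <- licks$onset_s[licks$onset_s > reward_time &
                             licks$onset_s <= reward_time + horizon_s]
      if (length(nxt) > 0) {
        anchor <- nxt[1]
        fallback <- FALSE
      }
    }
  }
  post <- window_auc(dff, anchor, window_s)
  pre <- window_auc(dff, cue_onset - window_s, window_s)
  structure(post$auc - pre$auc,
            anchor = anchor, fallback = fallback,
            truncated = post$truncated || pre$truncated)
}

#' Omission-evoked dopamine response (dip)
#'
#' AUC of a 2-s window beginning 1.25 s after cue onset (the would-be
#' reward time) minus the AUC of the 2-s baseline directly preceding cue
#' onset. The longer window accommodates the slower, broader kinetics of
#' omission dips.
#'
#' @param dff A `dff_trace`.
#' @param cue_onset Cue onset time of the omission trial, s.
#' @param window_s Window width (default 2 s).
#' @param delay_s Cue-to-outcome delay (default 1.25 s).
#' @return Baseline-subtracted AUC (negative for a dip).
#' @export
omission_response <- function(dff, cue_onset, window_s = 2, delay_s = 1.25) {
  post <- window_auc(dff, cue_onset + delay_s, window_s)
  pre <- window_auc(dff, cue_onset - window_s, window_s)
  structure(post$auc - pre$auc,
            truncated = post$truncated || pre$truncated)
}

#' Per-trial dopamine responses for a session-aligned schedule
#'
#' Convenience wrapper computing, for every trial, the cue AUC and peak,
#' the reward AUC in both the 0.5-s window and the omission-matched 2-s
#' window, and the omission AUC for unrewarded trials.
#'
#' @param dff A `dff_trace`.
#' @param schedule An `event_schedule`.
#' @param licks Optional `lick_train` for reward-anchor detection.
#' @return Tibble with one row per trial.
#' @export
trial_dopamine_responses <- function(dff, schedule, licks = NULL) {
  cues <- schedule[schedule$event_type == "cs_plus", ]
  rewards <- schedule[schedule$event_type == "reward", ]
  spec <- attr(schedule, "spec")
  tp <- if (is.null(spec)) 1.25 else trial_period(spec)
  purrr::map_dfr(seq_len(nrow(cues)), function(k) {
    tr <- cues$trial_index[k]
    ct <- cues$time_s[k]
    rw <- rewards$time_s[rewards$trial_index == tr]
    rewarded <- length(rw) == 1
    cue_auc <- as.numeric(cue_response(dff, ct))
    cue_peak <- window_peak(dff, ct, 0.5, ct - 0.5, 0.5)
    if (rewarded) {
      r05 <- reward_response(dff, rw, ct, licks, window_s = 0.5)
      r2 <- reward_response(dff, rw, ct, licks, window_s = 2)
      reward_peak <- window_peak(dff, attr(r05, "anchor"), 0.5, ct - 0.5, 0.5)
      tibble::tibble(
        trial_index = tr, rewarded = TRUE,
        cue_auc = cue_auc, cue_peak = cue_peak,
        reward_auc = as.numeric(r05), reward_auc_2s = as.numeric(r2),
        reward_peak = reward_peak, omission_auc = NA_real_
      )
    } else {
      tibble::tibble(
        trial_index = tr, rewarded = FALSE,
        cue_auc = cue_auc, cue_peak = cue_peak,
        reward_auc = NA_real_, reward_auc_2s = NA_real_,
        reward_peak = NA_real_,
        omission_auc = as.numeric(omission_response(dff, ct, delay_s = tp))
      )
    }
  })
}

#' Normalize dopamine responses to each animal's maximum reward responses
#'
#' Cue and reward responses are divided by the mean of the three maximum
#' 0.5-s-window reward responses; omission responses are divided by the
#' mean of the three maximum reward responses measured in the 2-s
#' post-first-lick window, matching the dip-measurement window. Peak
#' responses use the same top-3 rule on peaks.
#'
#' @param responses A [trial_dopamine_responses()] tibble.
#' @param top_n How many maximum reward responses to average (default 3).
#' @return The input with `cue_norm`, `reward_norm`, `omission_norm` and
#'   `cue_peak_norm` columns plus attributes `normalizer_05s`,
#'   `normalizer_2s`, `normalizer_peak` and `nonpositive_normalizer`.
#' @export
normalize_responses <- function(responses, top_n = 3) {
  rw <- responses$reward_auc[responses$rewarded & !is.na(responses$reward_auc)]
  if (length(rw) < top_n) {
    stop("need at least ", top_n, " rewarded trials to normalize", call. = FALSE)
  }
  top_mean <- function(x) mean(sort(x, decreasing = TRUE)[seq_len(top_n)])
  norm05 <- top_mean(rw)
  rw2 <- responses$reward_auc_2s[responses$rewarded &
                                   !is.na(responses$reward_auc_2s)]
  norm2 <- top_mean(rw2)
  pk <- responses$reward_peak[responses$rewarded &
                                !is.na(responses$reward_peak)]
  normpk <- if (length(pk) >= top_n) top_mean(pk) else NA_real_
  out <- responses
  out$cue_norm <- out$cue_auc / norm05
  out$reward_norm <- out$reward_auc / norm05
  out$omission_norm <- out$omission_auc / norm2
  out$cue_peak_norm <- if (is.na(normpk)) NA_real_ else out$cue_peak / normpk
  structure(out,
            normalizer_05s = norm05, normalizer_2s = norm2,
            normalizer_peak = normpk,
            nonpositive_normalizer = (norm05 <= 0 || norm2 <= 0))
}

#' Dopamine learned trial from normalized cue responses
#'
#' Runs the cumsum learned-trial detector on the per-trial normalized cue
#' dopamine series, anchoring the diagonal endpoint at 1.5 times the
#' behavioral learned trial (clamped to the series length) to account for
#' cue responses that decrease with extended training.
#'
#' @param norm_cue Per-trial normalized cue responses.
#' @param behavior_learned_trial Behavioral learned trial (integer).
#' @param ... Passed to [cumsum_change_point()].
#' @return A `learned_trial` object (with `anchor_clamped` attribute when
#'   1.5x the behavioral trial exceeded the series).
#' @export
dopamine_learned_trial <- function(norm_cue, behavior_learned_trial, ...) {
  stopifnot(behavior_learned_trial >= 1)
  anchor <- ceiling(1.5 * behavior_learned_trial)
  clamped <- anchor > length(norm_cue)
  anchor <- min(anchor, length(norm_cue))
  res <- cumsum_change_point(norm_cue, direction = "positive",
                             end_anchor = anchor, ...)
  attr(res, "anchor_clamped") <- clamped
  res
}

#' Omission-dip learned trial
#'
#' Runs the learned-trial detector with negative direction on the
#' omission-trial-indexed dip responses to find the omission trial after
#' which dopamine dips to reward omission emerge.
#'
#' @param omission_responses Per-omission-trial (normalized) dip responses.
#' @param ... Passed to [cumsum_change_point()].
#' @return A `learned_trial` object.
#' @export
omission_dip_trial <- function(omission_responses, ...) {
  cumsum_change_point(omission_responses, direction = "negative", ...)
}
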