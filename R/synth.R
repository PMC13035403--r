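#' Parameters for synthetic lick-train generation
#'
#' Controls a ground-truth licking model: Poisson baseline licking
#' everywhere, an anticipatory-window (cue onset to reward) rate that steps
#' from baseline to `anticipatory_rate` at a planted change-point trial
#' (with an optional linear ramp), and a stereotyped consumption bout after
#' each rewarded delivery whose inter-contact gaps are below 500 ms by
#' construction, so it is excluded from ITI lick-rate windows.
#'
#' Defaults emulate the conditioned behavior reported for the study's
#' learner mice: low spontaneous licking (0.5 Hz) and ~4 Hz asymptotic
#' anticipatory licking, with an abrupt transition.
#'
#' @param baseline_lick_rate Spontaneous lick rate, Hz.
#' @param anticipatory_rate Post-learning lick rate inside the cue-to-reward
#'   window, Hz.
#' @param change_point_trial Trial at which anticipation emerges (>= 1).
#' @param ramp_trials Width of the linear baseline-to-anticipatory
#'   transition, in trials (0 = step).
#' @param consumption_latency,consumption_duration,consumption_rate Latency
#'   from reward delivery to the first consumption lick (s), bout duration
#'   (s) and within-bout lick rate (Hz).
#' @param lick_duration Spout-contact duration per lick, s.
#' @return Object of class `behavior_gen_params`.
#' @export
behavior_gen_params <- function(baseline_lick_rate = 0.5,
                                anticipatory_rate = 4,
                                change_point_trial = 20,
                                ramp_trials = 0,
                                consumption_latency = 0.15,
                                consumption_duration = 1.5,
                                consumption_rate = 8,
                                lick_duration = 0.05) {
  stopifnot(
    baseline_lick_rate >= 0, anticipatory_rate >= 0,
    change_point_trial >= 1, ramp_trials >= 0,
    consumption_latency >= 0, consumption_duration >= 0,
    consumption_rate >= 0, lick_duration > 0
  )
  structure(
    list(
      baseline_lick_rate = baseline_lick_rate,
      anticipatory_rate = anticipatory_rate,
      change_point_trial = as.integer(change_point_trial),
      ramp_trials = as.integer(ramp_trials),
      consumption_latency = consumption_latency,
      consumption_duration = consumption_duration,
      consumption_rate = consumption_rate,
      lick_duration = lick_duration
    ),
    class = "behavior_gen_params"
  )
}

# per-trial anticipatory rate under the planted change point + linear ramp
anticipatory_rate_at <- function(params, trial) {
  b <- params$baseline_lick_rate
  a <- params$anticipatory_rate
  cp <- params$change_point_trial
  w <- params$ramp_trials
  frac <- if (w == 0) {
    as.numeric(trial >= cp)
  } else {
    pmin(1, pmax(0, (trial - cp + 1) / w))
  }
  b + (a - b) * frac
}

#' Generate a synthetic lick train for an event schedule
#'
#' @param schedule An [build_schedule()] `event_schedule`.
#' @param params A [behavior_gen_params()].
#' @param seed Integer seed.
#' @return A list with `licks` (tibble: `session_index`, `onset_s`,
#'   `offset_s`, class `lick_train`) and `truth` (list: `change_point_trial`
#'   and a per-trial tibble with the generating anticipatory rate and the
#'   expected cue-minus-baseline lick count).
#' @export
#' @examples
#' sched <- build_schedule(protocol_spec("demo", 30, 10), seed = 1)
#' out <- gen_licks(sched, behavior_gen_params(change_point_trial = 5), seed = 2)
#' nrow(out$licks)
gen_licks <- function(schedule, params = behavior_gen_params(), seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "behavior_gen_params"))
  cues <- schedule[schedule$event_type == "cs_plus", ]
  if (nrow(cues) == 0) stop("schedule contains no trials", call. = FALSE)
  rewards <- schedule[schedule$event_type %in% c("reward", "background_reward"), ]
  spec <- attr(schedule, "spec")
  tp <- if (is.null(spec)) 1.25 else trial_period(spec)
  t_end <- max(schedule$time_s)

  withr_seed(seed, {
    # baseline Poisson over the whole timeline
    n_base <- stats::rpois(1, params$baseline_lick_rate * t_end)
    onsets <- sort(stats::runif(n_base, 0, t_end))

    # anticipatory windows replace the baseline process
    win_lo <- cues$time_s
    win_hi <- cues$time_s + tp
    in_aw <- in_any_window(onsets, win_lo, win_hi)
    onsets <- onsets[!in_aw]
    rate <- anticipatory_rate_at(params, cues$trial_index)
    n_aw <- stats::rpois(nrow(cues), rate * tp)
    aw_licks <- unlist(Map(function(lo, n, w) lo + sort(stats::runif(n, 0, w)),
                           win_lo, n_aw, win_hi - win_lo))

    # consumption bouts: regular contacts with gaps <= 450 ms by construction
    bout_licks <- numeric(0)
    suppress_lo <- numeric(0)
    suppress_hi <- numeric(0)
    if (nrow(rewards) > 0 && params$consumption_rate > 0 &&
        params$consumption_duration > 0) {
      step <- min(1 / params$consumption_rate,
                  0.45 + params$lick_duration)
      rel <- seq(0, params$consumption_duration, by = step)
      bout_licks <- as.numeric(outer(rel, rewards$time_s +
                                       params$consumption_latency, "+"))
      suppress_lo <- rewards$time_s
      suppress_hi <- rewards$time_s + params$consumption_latency +
        params$consumption_duration + 0.5
    }
    if (length(suppress_lo) > 0) {
      onsets <- onsets[!in_any_window(onsets, suppress_lo, suppress_hi)]
    }
    onsets <- sort(c(onsets, aw_licks, bout_licks))
    offsets <- pmin(onsets + params$lick_duration,
                    c(onsets[-1] - 1e-4, Inf))
    sess <- session_of(schedule, onsets)
    licks <- tibble::tibble(
      session_index = sess, onset_s = onsets, offset_s = offsets
    )
    class(licks) <- c("lick_train", class(licks))
    truth <- list(
      change_point_trial = params$change_point_trial,
      per_trial = tibble::tibble(
        trial_index = cues$trial_index,
        anticipatory_rate_hz = rate,
        expected_delta_licks = (rate - params$baseline_lick_rate) * tp
      )
    )
    list(licks = licks, truth = truth)
  })
}

in_any_window <- function(x, lo, hi) {
  if (length(lo) == 0) return(rep(FALSE, length(x)))
  idx <- findInterval(x, lo)
  idx > 0 & x < hi[pmax(idx, 1)]
}

session_of <- function(schedule, times) {
  starts <- schedule$time_s[schedule$event_type == "session_start"]
  pmax(1L, findInterval(times, starts))
}

#' Parameters for synthetic two-channel photometry generation
#'
#' The 470-nm channel is a constant baseline plus event-locked transients
#' (a difference-of-exponentials kernel scaled by caller-supplied per-trial
#' amplitude trajectories), a slow artifact shared with the isosbestic
#' channel, and independent Gaussian noise. The 405-nm channel is an affine
#' map of baseline plus shared artifact (no event transients), so an
#' isosbestic least-squares fit can remove the artifact.
#'
#' @param sampling_rate Hz (default 120, matching the downsampled
#'   acquisition rate the analyses assume).
#' @param kernel_rise,kernel_decay Transient kernel time constants, s. The
#'   defaults (0.05 and 0.5 s) concentrate most of the transient inside the
#'   0.5-s response windows.
#' @param cue_amp,reward_amp,omission_amp Per-trial transient amplitudes in
#'   dF/F percentage points (recycled to the trial count). `omission_amp`
#'   (usually negative) is applied at the would-be reward time of
#'   unrewarded trials.
#' @param noise_sd Independent per-channel noise, a.u.
#' @param baseline Raw fluorescence baseline, a.u.
#' @param iso_gain,iso_offset Affine map from the shared component to the
#'   405-nm channel.
#' @param artifact_sd Slow shared-artifact amplitude, a.u. (0 disables).
#' @return Object of class `photometry_gen_params`.
#' @export
photometry_gen_params <- function(sampling_rate = 120,
                                  kernel_rise = 0.05,
                                  kernel_decay = 0.5,
                                  cue_amp = 0,
                                  reward_amp = 5,
                                  omission_amp = 0,
                                  noise_sd = 0.05,
                                  baseline = 10,
                                  iso_gain = 0.8,
                                  iso_offset = 1,
                                  artifact_sd = 0) {
  stopifnot(sampling_rate > 0, kernel_rise > 0, kernel_decay > kernel_rise,
            all(is.finite(cue_amp)), all(is.finite(reward_amp)),
            noise_sd >= 0, baseline > 0, artifact_sd >= 0)
  structure(
    list(
      sampling_rate = sampling_rate,
      kernel_rise = kernel_rise,
      kernel_decay = kernel_decay,
      cue_amp = cue_amp,
      reward_amp = reward_amp,
      omission_amp = omission_amp,
      noise_sd = noise_sd,
      baseline = baseline,
      iso_gain = iso_gain,
      iso_offset = iso_offset,
      artifact_sd = artifact_sd
    ),
    class = "photometry_gen_params"
  )
}

# difference-of-exponentials transient, peak-normalized to 1
photometry_kernel <- function(t, rise, decay) {
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  out <- ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / peak, 0)
  out
}

#' Generate a synthetic two-channel photometry trace
#'
#' @param schedule An `event_schedule`.
#' @param params A [photometry_gen_params()].
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return List with `trace` (tibble: `session_index`, `time_s`, `f470`,
#'   `f405`, class `photometry_trace`) and `truth` (per-trial amplitude
#'   tibble plus the kernel parameters).
#' @export
gen_photometry <- function(schedule, params = photometry_gen_params(),
                           seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "photometry_gen_params"))
  cues <- schedule[schedule$event_type == "cs_plus", ]
  n_tr <- nrow(cues)
  spec <- attr(schedule, "spec")
  tp <- if (is.null(spec)) 1.25 else trial_period(spec)
  rewarded <- cues$trial_index %in%
    schedule$trial_index[schedule$event_type == "reward"]
  cue_amp <- rep_len(params$cue_amp, n_tr)
  reward_amp <- rep_len(params$reward_amp, n_tr)
  omission_amp <- rep_len(params$omission_amp, n_tr)

  fs <- params$sampling_rate
  t_end <- max(schedule$time_s)
  time_s <- seq(0, t_end, by = 1 / fs)
  n <- length(time_s)

  withr_seed(seed, {
    sig <- numeric(n)
    add_transient <- function(onset, amp) {
      if (amp == 0) return()
      i0 <- findInterval(onset, time_s) + 1L
      span <- ceiling(fs * (params$kernel_decay * 8))
      idx <- i0:min(n, i0 + span)
      sig[idx] <<- sig[idx] +
        amp * photometry_kernel(time_s[idx] - onset,
                                params$kernel_rise, params$kernel_decay)
    }
    for (k in seq_len(n_tr)) {
      add_transient(cues$time_s[k], cue_amp[k])
      if (rewarded[k]) {
        add_transient(cues$time_s[k] + tp, reward_amp[k])
      } else {
        add_transient(cues$time_s[k] + tp, omission_amp[k])
      }
    }
    # amplitudes are expressed in dF/F percentage points of baseline
    sig <- sig * params$baseline / 100

    artifact <- numeric(n)
    if (params$artifact_sd > 0) {
      knot_t <- seq(0, t_end + 2, by = 2)
      knots <- stats::rnorm(length(knot_t))
      a <- stats::approx(knot_t, knots, xout = time_s)$y
      artifact <- a / stats::sd(a) * params$artifact_sd
    }
    f470 <- params$baseline + sig + artifact +
      stats::rnorm(n, 0, params$noise_sd)
    f405 <- params$iso_gain * (params$baseline + artifact) +
      params$iso_offset + stats::rnorm(n, 0, params$noise_sd)
    trace <- tibble::tibble(
      session_index = session_of(schedule, time_s),
      time_s = time_s, f470 = f470, f405 = f405
    )
    class(trace) <- c("photometry_trace", class(trace))
    truth <- list(
      per_trial = tibble::tibble(
        trial_index = cues$trial_index, rewarded = rewarded,
        cue_amp = cue_amp, reward_amp = ifelse(rewarded, reward_amp, 0),
        omission_amp = ifelse(rewarded, 0, omission_amp)
      ),
      kernel_rise = params$kernel_rise,
      kernel_decay = params$kernel_decay
    )
    list(trace = trace, truth = truth)
  })
}

#' Write or read lick and photometry tables
#'
#' @param licks,trace Tibbles as produced by [gen_licks()] /
#'   [gen_photometry()].
#' @param path File path.
#' @return The reader functions return classed tibbles.
#' @export
write_licks <- function(licks, path) {
  utils::write.csv(as.data.frame(licks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_licks
#' @export
read_licks <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("lick_train", class(out))
  out
}

#' @rdname write_licks
#' @export
write_photometry <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_licks
#' @export
read_photometry <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("photometry_trace", class(out))
  out
}
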