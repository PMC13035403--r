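#' Protocol specification for a trace-conditioning schedule
#'
#' Describes one conditioning protocol: a brief auditory cue (default 0.25 s)
#' followed by a trace period (default 1 s) and, with probability
#' `reward_prob`, a reward, then a fixed consumption period (default 3 s).
#' Trials are separated by a variable intertrial interval (ITI) drawn
#' uniformly on `mean_iti * (1 - iti_jitter)` to `mean_iti * (1 + iti_jitter)`.
#' An ITI draw precedes every trial, including the first of each session.
#'
#' @param name Label for the protocol (e.g. `"iti60"`).
#' @param mean_iti Mean intertrial interval in seconds (> 0).
#' @param trials_per_session Number of cue presentations per session.
#' @param n_sessions Number of sessions.
#' @param iti_jitter Fraction of `mean_iti` for the uniform ITI range,
#'   in `[0, 1)`. The study protocols use 0.2 (e.g. 48-72 s for a 60-s ITI).
#' @param reward_prob Probability that a cue is followed by reward, in
#'   `[0, 1]`. 1 for continuous reinforcement; 0.5 and 0.1 for the partial
#'   reinforcement protocols.
#' @param cue_duration,trace_duration,consumption_period Trial timing in
#'   seconds. Cue onset to reward is `cue_duration + trace_duration`
#'   (1.25 s in all cue-reward protocols here); the consumption period is
#'   scheduled on every trial, rewarded or not, so partial reinforcement
#'   leaves the ITI and inter-cue interval unchanged.
#' @param distractor Optional list `list(mean = <s>, identity = <label>)`
#'   describing unrewarded distractor cues delivered as an exponential
#'   renewal process during the intervals between trials.
#' @param background_reward Optional list
#'   `list(identity = <label>, events_per_interval = <n>, mean_spacing = <s>,
#'   jitter = <fraction>)` describing uncued rewards of a second identity
#'   placed in each inter-trial gap, each spaced uniformly
#'   `mean_spacing * (1 +/- jitter)` from the previous reward delivery.
#' @param pre_session_delay Seconds between session start and the first ITI
#'   draw (default 0).
#'
#' @return An object of class `protocol_spec` (a named list).
#' @seealso [build_schedule()], [study_protocols()]
#' @export
#' @examples
#' protocol_spec("iti60", mean_iti = 60, trials_per_session = 50, n_sessions = 8)
protocol_spec <- function(name,
                          mean_iti,
                          trials_per_session,
                          n_sessions = 1,
                          iti_jitter = 0.2,
                          reward_prob = 1,
                          cue_duration = 0.25,
                          trace_duration = 1,
                          consumption_period = 3,
                          distractor = NULL,
                          background_reward = NULL,
                          pre_session_delay = 0) {
  stopifnot(
    is.character(name), length(name) == 1L,
    is.numeric(mean_iti), mean_iti > 0,
    iti_jitter >= 0, iti_jitter < 1,
    reward_prob >= 0, reward_prob <= 1,
    trials_per_session >= 1, n_sessions >= 1,
    cue_duration > 0, trace_duration >= 0, consumption_period >= 0,
    pre_session_delay >= 0
  )
  if (!is.null(distractor)) {
    stopifnot(is.list(distractor), distractor$mean > 0)
    distractor$identity <- distractor$identity %||% "cs_minus"
  }
  if (!is.null(background_reward)) {
    stopifnot(
      is.list(background_reward),
      background_reward$events_per_interval >= 1,
      background_reward$mean_spacing > 0
    )
    background_reward$identity <- background_reward$identity %||% "background"
    background_reward$jitter <- background_reward$jitter %||% 0.2
  }
  structure(
    list(
      name = name,
      mean_iti = mean_iti,
      iti_jitter = iti_jitter,
      trials_per_session = as.integer(trials_per_session),
      n_sessions = as.integer(n_sessions),
      reward_prob = reward_prob,
      cue_duration = cue_duration,
      trace_duration = trace_duration,
      consumption_period = consumption_period,
      distractor = distractor,
      background_reward = background_reward,
      pre_session_delay = pre_session_delay
    ),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol_spec '%s'> mean ITI %g s (+/-%g%%), %d trials x %d sessions, p(reward) = %g\n",
    x$name, x$mean_iti, 100 * x$iti_jitter,
    x$trials_per_session, x$n_sessions, x$reward_prob
  ))
  invisible(x)
}

# cue onset -> reward delay plus consumption; the "trial block"
trial_period <- function(spec) spec$cue_duration + spec$trace_duration

trial_block <- function(spec) trial_period(spec) + spec$consumption_period

#' Conditioning protocols used across the study's experimental groups
#'
#' Returns the named list of `protocol_spec` objects for the main ITI groups
#' (30, 60, 300, 600 and 3,600 s), the trials-per-day and auditory-rate
#' controls, the background-reward group and the partial-reinforcement
#' groups. Trial counts per session and session numbers follow the
#' experimental design (e.g. 50 trials/day for 60-s ITI, 6/day for 600-s
#' ITI, 2/day for 3,600-s ITI which also used a fixed ITI).
#'
#' @return Named list of [protocol_spec()] objects.
#' @export
study_protocols <- function() {
  list(
    iti30 = protocol_spec("iti30", 30, 100, 8),
    iti60 = protocol_spec("iti60", 60, 50, 8),
    iti300 = protocol_spec("iti300", 300, 11, 8),
    iti600 = protocol_spec("iti600", 600, 6, 8),
    iti3600 = protocol_spec("iti3600", 3600, 2, 8, iti_jitter = 0),
    iti60_few = protocol_spec("iti60_few", 60, 6, 8),
    iti60_cs_minus = protocol_spec(
      "iti60_cs_minus", 600, 6, 8,
      distractor = list(mean = 60, identity = "cs_minus")
    ),
    iti600_bg_milk = protocol_spec(
      "iti600_bg_milk", 600, 6, 8,
      background_reward = list(
        identity = "chocolate_milk", events_per_interval = 2,
        mean_spacing = 180, jitter = 0.2
      )
    ),
    iti60_p50 = protocol_spec("iti60_p50", 60, 50, 12, reward_prob = 0.5),
    iti60_p10 = protocol_spec("iti60_p10", 60, 50, 32, reward_prob = 0.1)
  )
}

#' Build an event schedule from a protocol specification
#'
#' Draws the full conditioning timeline for a protocol: per-trial ITIs
#' (i.i.d. uniform), cue onsets, Bernoulli reward deliveries at cue onset +
#' cue/trace delay, optional exponential-renewal distractor cues and
#' background rewards inside the inter-trial gaps, and session boundaries.
#' Times are in seconds of cumulative conditioning time: sessions are
#' concatenated with no modeled between-session gap, so elapsed-time
#' computations sum conditioning time only.
#'
#' @param spec A [protocol_spec()].
#' @param seed Integer seed; the schedule is reproducible given `spec` and
#'   `seed`.
#'
#' @return A tibble of class `event_schedule` with columns `time_s`,
#'   `session_index`, `trial_index` (1-based across sessions, `NA` for
#'   non-trial events), `event_type` (one of `session_start`, `cs_plus`,
#'   `reward`, `cs_minus`, `background_reward`, `session_end`) and
#'   `identity`. The protocol is attached as attribute `spec`.
#' @export
#' @examples
#' sched <- build_schedule(study_protocols()$iti60, seed = 1)
#' dplyr::count(sched, event_type)
build_schedule <- function(spec, seed) {
  stopifnot(inherits(spec, "protocol_spec"), is.numeric(seed))
  withr_seed(seed, {
    time_s <- numeric(0)
    session_index <- integer(0)
    trial_index <- integer(0)
    event_type <- character(0)
    identity <- character(0)
    add <- function(t, s, tr, type, id) {
      n <- length(t)
      time_s <<- c(time_s, t)
      session_index <<- c(session_index, rep_len(as.integer(s), n))
      trial_index <<- c(trial_index, rep_len(as.integer(tr), n))
      event_type <<- c(event_type, rep_len(type, n))
      identity <<- c(identity, rep_len(id, n))
    }
    t0 <- 0
    trial0 <- 0L
    last_reward_time <- NA_real_
    tp <- trial_period(spec)
    tb <- trial_block(spec)
    for (s in seq_len(spec$n_sessions)) {
      add(t0, s, NA, "session_start", "session")
      nt <- spec$trials_per_session
      itis <- stats::runif(nt, spec$mean_iti * (1 - spec$iti_jitter),
                           spec$mean_iti * (1 + spec$iti_jitter))
      rewarded <- stats::runif(nt) < spec$reward_prob
      # cue k onset = session start + pre-delay + k ITIs + (k-1) trial blocks
      cue_on <- t0 + spec$pre_session_delay + cumsum(itis) +
        tb * (seq_len(nt) - 1)
      trials <- trial0 + seq_len(nt)
      if (!is.null(spec$distractor) || !is.null(spec$background_reward)) {
        gap_starts <- c(t0 + spec$pre_session_delay, cue_on[-nt] + tb)
        for (k in seq_len(nt)) {
          gap <- fill_gap(spec, gap_start = gap_starts[k], cue_on = cue_on[k],
                          session = s, last_reward_time = last_reward_time)
          for (e in gap$events) add(e$t, s, NA, e$type, e$id)
          if (!is.na(gap$last_reward_time)) {
            last_reward_time <- gap$last_reward_time
          }
          if (rewarded[k]) last_reward_time <- cue_on[k] + tp
        }
      } else if (any(rewarded)) {
        last_reward_time <- max(cue_on[rewarded]) + tp
      }
      add(cue_on, s, trials, "cs_plus", "cs_plus")
      if (any(rewarded)) {
        add(cue_on[rewarded] + tp, s, trials[rewarded], "reward", "sucrose")
      }
      t0 <- cue_on[nt] + tb
      add(t0, s, NA, "session_end", "session")
      trial0 <- trial0 + nt
    }
    out <- tibble::tibble(
      time_s = time_s, session_index = session_index,
      trial_index = trial_index, event_type = event_type, identity = identity
    )
    out <- out[order(out$time_s, out$event_type), ]
    structure(out, class = c("event_schedule", class(out)), spec = spec)
  })
}

# distractor cues and background rewards inside one inter-trial gap
fill_gap <- function(spec, gap_start, cue_on, session, last_reward_time) {
  events <- list()
  last_rt <- NA_real_
  if (!is.null(spec$distractor)) {
    t <- gap_start
    repeat {
      t <- t + stats::rexp(1, rate = 1 / spec$distractor$mean)
      if (t >= cue_on) break
      events <- c(events, list(
        list(t = t, type = "cs_minus", id = spec$distractor$identity)
      ))
    }
  }
  bg <- spec$background_reward
  if (!is.null(bg)) {
    anchor0 <- if (is.na(last_reward_time)) gap_start else last_reward_time
    min_spacing <- bg$mean_spacing * (1 - bg$jitter)
    if (anchor0 + bg$events_per_interval * min_spacing >= cue_on &&
        gap_start + bg$events_per_interval * min_spacing >= cue_on) {
      stop("schedule infeasible: background-reward spacing exceeds the inter-trial gap",
           call. = FALSE)
    }
    for (try in 1:100) {
      anchor <- anchor0
      times <- numeric(bg$events_per_interval)
      ok <- TRUE
      for (i in seq_len(bg$events_per_interval)) {
        anchor <- anchor + stats::runif(
          1, bg$mean_spacing * (1 - bg$jitter), bg$mean_spacing * (1 + bg$jitter)
        )
        if (anchor <= gap_start || anchor >= cue_on) {
          ok <- FALSE
          break
        }
        times[i] <- anchor
      }
      if (ok) {
        for (tt in times) {
          events <- c(events, list(
            list(t = tt, type = "background_reward", id = bg$identity)
          ))
        }
        last_rt <- times[length(times)]
        break
      }
      if (try == 100) {
        stop("schedule infeasible: could not place background rewards in gap",
             call. = FALSE)
      }
    }
  }
  list(events = events, last_reward_time = last_rt)
}

#' Nominal inter-reward interval for a protocol
#'
#' The nominal IRI is the mean ITI plus the 4.25-s trial block (1.25-s
#' cue-to-reward period plus the 3-s consummatory period), divided by the
#' reward probability. Under continuous reinforcement the IRI equals the
#' inter-cue interval; partial reinforcement lengthens the IRI without
#' changing the ITI or ICI. When background rewards of another identity are
#' delivered, the identity-specific IRI counts only the cue-paired identity
#' while the general IRI divides by all rewards per cycle.
#'
#' @param mean_iti Mean ITI in seconds.
#' @param reward_prob Reward probability in `(0, 1]`.
#' @param trial_block Cue-to-reward period plus consumption, seconds
#'   (default 4.25).
#' @param n_background Background rewards (other identity) per inter-trial
#'   interval; only used when `identity_specific = FALSE`.
#' @param identity_specific If `TRUE` (default), count only the cue-paired
#'   reward identity.
#'
#' @return IRI in seconds.
#' @export
#' @examples
#' nominal_iri(60)        # 64.25
#' nominal_iri(60, 0.5)   # 128.5
#' nominal_iri(60, 0.1)   # 642.5
nominal_iri <- function(mean_iti, reward_prob = 1, trial_block = 4.25,
                        n_background = 0, identity_specific = TRUE) {
  stopifnot(mean_iti > 0, reward_prob >= 0, reward_prob <= 1)
  if (reward_prob == 0) {
    stop("IRI is undefined when reward_prob is 0", call. = FALSE)
  }
  base <- (mean_iti + trial_block) / reward_prob
  if (identity_specific || n_background == 0) {
    base
  } else {
    base / (1 + n_background / reward_prob)
  }
}

#' Conditioning time elapsed before a trial
#'
#' Seconds of conditioning time from the first session start to the cue
#' onset of the given trial, summing across sessions and excluding any
#' between-session time (which carries no modeled duration here).
#'
#' @param schedule An `event_schedule`.
#' @param trial_index 1-based trial number (across sessions).
#' @return Seconds.
#' @export
elapsed_time_before_trial <- function(schedule, trial_index) {
  cues <- schedule[schedule$event_type == "cs_plus", , drop = FALSE]
  hit <- match(as.integer(trial_index), cues$trial_index)
  if (anyNA(hit)) {
    stop("trial_index out of range for this schedule", call. = FALSE)
  }
  start <- schedule$time_s[schedule$event_type == "session_start"][1]
  cues$time_s[hit] - start
}

# total conditioning duration (start of session 1 to final session end)
total_conditioning_duration <- function(schedule) {
  max(schedule$time_s) - min(schedule$time_s)
}

#' Write or read an events table
#'
#' Plain-CSV persistence for event schedules: columns `session_index`,
#' `trial_index`, `time_s`, `event_type`, `identity`; UTF-8, '.' decimal.
#'
#' @param schedule An `event_schedule` tibble.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` a
#'   tibble of class `event_schedule`.
#' @export
write_events <- function(schedule, path) {
  utils::write.csv(
    as.data.frame(schedule)[, c("session_index", "trial_index", "time_s",
                                "event_type", "identity")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- tibble::as_tibble(df)
  out$session_index <- as.integer(out$session_index)
  out$trial_index <- as.integer(out$trial_index)
  structure(out[order(out$time_s), ],
            class = c("event_schedule", class(tibble::tibble())))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
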