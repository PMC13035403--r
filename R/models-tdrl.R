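#' Parameters for the microstimulus TDRL simulator
#'
#' The microstimulus representation launches, at each event (cue or
#' reward), a memory trace decaying by `d` per time step; `m` Gaussian
#' basis functions of width `sigma`, centered evenly on the trace height in
#' `(0, 1]` and amplitude-weighted by the trace, encode time since the
#' event. Because traces run through the intertrial interval, ITI states
#' can acquire value, giving the model a potential mechanism for trial
#' spacing effects. Value is a linear function of the features, updated by
#' temporal-difference errors with accumulating eligibility traces.
#'
#' Defaults are the best-fitting combination from the model comparison:
#' `threshold = 0.3`, `alpha = 0.1`, `gamma = 0.99`, `m = 3`, `d = 0.9`,
#' with fixed `dt = 0.25` s (the cue duration), `lambda = 0.99` and
#' `sigma = 0.08`.
#'
#' @param dt Time step, s.
#' @param lambda Eligibility-trace decay.
#' @param sigma Microstimulus width.
#' @param threshold Behavior-generation threshold on trial value.
#' @param d Memory-trace decay per step.
#' @param gamma Temporal discount per step.
#' @param m Microstimuli per event (integer >= 1).
#' @param alpha Learning rate.
#' @param reward_magnitude Reward size (1).
#' @return Object of class `tdrl_params`.
#' @export
tdrl_params <- function(dt = 0.25, lambda = 0.99, sigma = 0.08,
                        threshold = 0.3, d = 0.9, gamma = 0.99,
                        m = 3, alpha = 0.1, reward_magnitude = 1) {
  stopifnot(
    dt > 0, lambda >= 0, lambda <= 1, sigma > 0,
    threshold > 0, d > 0, d <= 1, gamma > 0, gamma <= 1,
    m >= 1, alpha >= 0, alpha <= 1
  )
  structure(
    list(dt = dt, lambda = lambda, sigma = sigma, threshold = threshold,
         d = d, gamma = gamma, m = as.integer(m), alpha = alpha,
         reward_magnitude = reward_magnitude),
    class = "tdrl_params"
  )
}

# map schedule events onto the dt grid (conditioning-time axis)
discretize_schedule <- function(schedule, dt) {
  t0 <- min(schedule$time_s)
  n_steps <- ceiling((max(schedule$time_s) - t0) / dt) + 1L
  step_of <- function(times) pmin(n_steps, round((times - t0) / dt) + 1L)
  cues <- schedule[schedule$event_type == "cs_plus", ]
  rewards <- schedule[schedule$event_type %in%
                        c("reward", "background_reward"), ]
  list(
    n_steps = n_steps,
    cue_steps = step_of(cues$time_s),
    trial_index = cues$trial_index,
    reward_steps = step_of(rewards$time_s),
    reward_trials = rewards$trial_index,
    window_end_steps = step_of(cues$time_s + 1.25)
  )
}

#' Simulate microstimulus TDRL on an event schedule
#'
#' Runs discrete-time TD(lambda) learning with the microstimulus state
#' representation over the full conditioning timeline (ITIs included) of a
#' schedule. The per-trial association quantity is the maximum value
#' between cue onset and reward time, and the learned trial is the first
#' trial on which it exceeds the behavior threshold. The TD error at cue
#' and reward steps is reported as the model's dopamine proxy.
#'
#' @param schedule An `event_schedule` (its ITIs carry the randomness; the
#'   model itself is deterministic).
#' @param params A [tdrl_params()].
#' @return Object of class `sim_result`: `per_trial` tibble
#'   (`trial_index`, `quantity`), `da` tibble (`trial_index`, `event`,
#'   `value` = TD error), `learned_trial` (`NA` when the threshold is never
#'   crossed), `threshold`, `model`, `params`.
#' @export
simulate_tdrl_microstimulus <- function(schedule, params = tdrl_params()) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "tdrl_params"))
  disc <- discretize_schedule(schedule, params$dt)
  run_tdrl(disc, params)
}

run_tdrl <- function(disc, params) {
  n <- disc$n_steps
  m <- params$m
  mu <- seq_len(m) / m
  two_sig2 <- 2 * params$sigma^2
  n_trials <- length(disc$cue_steps)

  cue_at <- logical(n)
  cue_at[disc$cue_steps] <- TRUE
  rew_at <- logical(n)
  rew_at[disc$reward_steps] <- TRUE
  # trial window membership: trial k active on steps cue_k .. cue_k + 1.25 s
  trial_at <- integer(n)
  for (k in seq_len(n_trials)) {
    trial_at[disc$cue_steps[k]:disc$window_end_steps[k]] <- k
  }
  cue_trial <- integer(n)
  cue_trial[disc$cue_steps] <- seq_len(n_trials)
  rew_trial <- integer(n)
  rew_trial[disc$reward_steps] <- match(disc$reward_trials, disc$trial_index)

  w <- numeric(2 * m)
  e <- numeric(2 * m)
  x_prev <- numeric(2 * m)
  y_c <- 0
  y_r <- 0
  quantity <- rep(-Inf, n_trials)
  da_cue <- rep(NA_real_, n_trials)
  da_rew <- rep(NA_real_, n_trials)
  alpha <- params$alpha
  gamma <- params$gamma
  gl <- params$gamma * params$lambda
  d <- params$d
  rmag <- params$reward_magnitude

  for (t in seq_len(n)) {
    y_c <- if (cue_at[t]) 1 else y_c * d
    y_r <- if (rew_at[t]) 1 else y_r * d
    x <- c(y_c * exp(-(y_c - mu)^2 / two_sig2),
           y_r * exp(-(y_r - mu)^2 / two_sig2))
    r <- if (rew_at[t]) rmag else 0
    v <- sum(w * x)
    delta <- r + gamma * v - sum(w * x_prev)
    e <- gl * e + x_prev
    w <- w + alpha * delta * e
    tr <- trial_at[t]
    if (tr > 0) {
      v_post <- sum(w * x)
      if (v_post > quantity[tr]) quantity[tr] <- v_post
    }
    if (cue_at[t]) da_cue[cue_trial[t]] <- delta
    if (rew_at[t]) da_rew[rew_trial[t]] <- delta
    x_prev <- x
  }
  learned <- which(quantity > params$threshold)[1]
  new_sim_result(
    model = "tdrl_ms",
    per_trial = tibble::tibble(trial_index = disc$trial_index,
                               quantity = quantity),
    da = tibble::tibble(
      trial_index = rep(disc$trial_index, 2),
      event = rep(c("cue", "reward"), each = n_trials),
      value = c(da_cue, da_rew)
    ),
    learned_trial = if (is.na(learned)) NA_integer_ else
      disc$trial_index[learned],
    threshold = params$threshold,
    params = params
  )
}

#' Simulate TDRL with an IRI-scaled learning rate
#'
#' Identical to [simulate_tdrl_microstimulus()] but with the learning rate
#' replaced by `alpha = 1 - exp(-k_scale * IRI)`, the ad hoc rule derived
#' from the retrospective model's proportional scaling. The sweep over the
#' experimentally plausible range found `k_scale = 3e-4` to fit behavior
#' best.
#'
#' @param schedule An `event_schedule`.
#' @param params A [tdrl_params()] (its `alpha` is ignored).
#' @param k_scale Scaling constant (1/s).
#' @param iri_s Nominal IRI; by default computed from the schedule's
#'   protocol spec.
#' @return A `sim_result`.
#' @export
simulate_tdrl_scaled <- function(schedule, params = tdrl_params(),
                                 k_scale = 3e-4, iri_s = NULL) {
  if (is.null(iri_s)) {
    spec <- attr(schedule, "spec")
    if (is.null(spec)) {
      stop("schedule has no protocol spec; supply iri_s", call. = FALSE)
    }
    iri_s <- nominal_iri(spec$mean_iti, spec$reward_prob)
  }
  params$alpha <- 1 - exp(-k_scale * iri_s)
  res <- simulate_tdrl_microstimulus(schedule, params)
  res$model <- "tdrl_scaled"
  res
}

new_sim_result <- function(model, per_trial, da, learned_trial, threshold,
                           params) {
  structure(
    list(model = model, per_trial = per_trial, da = da,
         learned_trial = learned_trial, threshold = threshold,
         params = params),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  lt <- if (is.na(x$learned_trial)) "never crossed threshold" else
    paste("learned trial", x$learned_trial)
  cat(sprintf("<sim_result %s> %d trials, threshold %g: %s\n",
              x$model, nrow(x$per_trial), x$threshold, lt))
  invisible(x)
}
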