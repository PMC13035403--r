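#' IRI-scaled retrospective learning rate
#'
#' The retrospective cue-reward association updates only at reward times,
#' while the baseline event rates entering its Bayes'-rule normalization
#' update every time step `dt` with rate `alpha0`. Equating the timescales
#' of history of the two delta rules gives the associative learning rate
#' `alpha = 1 - (1 - alpha0)^(IRI / dt)`, which for small rates reduces to
#' `alpha0 * IRI / dt` -- i.e. learning per reward proportional to the
#' inter-reward interval.
#'
#' @param alpha0 Baseline per-step learning rate, in `(0, 1)`.
#' @param iri_s Inter-reward interval, s.
#' @param dt_s Baseline update interval, s.
#' @param approx If `TRUE`, return the small-rate approximation
#'   `alpha0 * IRI / dt` instead of the exact expression.
#' @return Learning rate(s), vectorized over `iri_s`.
#' @export
#' @examples
#' alpha_from_iri(4e-5, 64.25, 0.2)   # ~0.01277
#' alpha_from_iri(4e-5, 0.2, 0.2)     # alpha0 exactly
alpha_from_iri <- function(alpha0, iri_s, dt_s, approx = FALSE) {
  stopifnot(alpha0 > 0, alpha0 < 1, all(iri_s > 0), dt_s > 0)
  if (approx) {
    alpha0 * iri_s / dt_s
  } else {
    1 - (1 - alpha0)^(iri_s / dt_s)
  }
}

#' Parameters for the ANCCR simulator
#'
#' ANCCR learns retrospectively whether a cue precedes reward: the
#' predecessor representation `M_<-cr` (average cue eligibility at reward
#' times) is updated at each reward with the IRI-scaled learning rate of
#' [alpha_from_iri()], while baseline representations `M_<-x-` (average
#' eligibility of each event type) update every `dt` with rate `alpha0`.
#' The prospective association follows from a Bayes'-rule normalization,
#' `M_->cr = M_<-cr * M_<-r- / M_<-c-`, and the net contingency combines
#' prospective and retrospective contingencies with weight `w`:
#' `NC = w * (M_->cr - M_<-r-) + (1 - w) * (M_<-cr - M_<-c-)`.
#' Eligibility traces decay exponentially with time constant `T = k * IRI`.
#'
#' Defaults are the best-fitting sweep combination: `threshold = 0.4`,
#' `alpha0 = 4e-5`, `k = 0.5`, with fixed `w = 0.5` and `dt = 0.2` s. An
#' innate meaningfulness of 1 is added to the dopamine reward response.
#'
#' @param alpha0 Baseline learning rate per `dt`.
#' @param k Eligibility time-constant scale (`T = k * IRI`).
#' @param w Prospective-retrospective weighting.
#' @param dt Baseline update interval, s.
#' @param threshold Behavior-generation threshold on net contingency.
#' @param innate_meaningfulness Added to the dopamine reward response.
#' @param rate_floor Numerical floor on the baseline cue rate in the
#'   Bayes'-rule division.
#' @return Object of class `anccr_params`.
#' @export
anccr_params <- function(alpha0 = 4e-5, k = 0.5, w = 0.5, dt = 0.2,
                         threshold = 0.4, innate_meaningfulness = 1,
                         rate_floor = 1e-6) {
  stopifnot(alpha0 > 0, alpha0 < 1, k > 0, w >= 0, w <= 1, dt > 0,
            threshold > 0, rate_floor > 0)
  structure(
    list(alpha0 = alpha0, k = k, w = w, dt = dt, threshold = threshold,
         innate_meaningfulness = innate_meaningfulness,
         rate_floor = rate_floor),
    class = "anccr_params"
  )
}

# closed-form n-step baseline update while the eligibility trace decays:
#   E_j = E_0 * beta^j;  M_j = (1 - a0) M_{j-1} + a0 E_j
# equals a literal per-dt loop exactly (geometric sums)
baseline_update_n <- function(m0, e0, n, a0, beta) {
  if (n <= 0) return(m0)
  a <- 1 - a0
  s <- if (abs(a - beta) < 1e-12) {
    n * a^(n - 1)
  } else {
    (a^n - beta^n) / (a - beta)
  }
  a^n * m0 + a0 * e0 * beta * s
}

#' Simulate ANCCR on an event schedule
#'
#' Event-driven simulation of the retrospective contingency model over a
#' conditioning schedule. Eligibility traces and baseline representations
#' evolve on a `dt` grid (baseline updates between events are computed in
#' closed form); the cue-reward predecessor representation updates at each
#' reward of the cue-paired identity with the IRI-scaled learning rate. The
#' per-trial quantity is the net contingency `NC_cue<->reward` evaluated at
#' cue onset, and the learned trial is its first threshold crossing. The
#' dopamine proxy is the net contingency at cue and reward events, plus the
#' innate meaningfulness at rewards.
#'
#' @param schedule An `event_schedule`.
#' @param params An [anccr_params()].
#' @param iri_s Nominal cue-paired IRI; by default the empirical mean
#'   inter-reward interval of the cue-paired identity in the schedule.
#' @return A `sim_result`.
#' @export
simulate_anccr <- function(schedule, params = anccr_params(), iri_s = NULL) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "anccr_params"))
  ev <- schedule[schedule$event_type %in%
                   c("cs_plus", "reward", "cs_minus", "background_reward"), ]
  ev <- ev[order(ev$time_s), ]
  if (nrow(ev) == 0) stop("schedule contains no events", call. = FALSE)
  t0 <- min(schedule$time_s)

  if (is.null(iri_s)) {
    rt <- ev$time_s[ev$event_type == "reward"]
    iri_s <- if (length(rt) >= 2) {
      mean(diff(rt))
    } else {
      spec <- attr(schedule, "spec")
      if (is.null(spec)) stop("cannot infer IRI; supply iri_s", call. = FALSE)
      nominal_iri(spec$mean_iti, spec$reward_prob)
    }
  }
  p <- params
  alpha <- alpha_from_iri(p$alpha0, iri_s, p$dt)
  bigT <- p$k * iri_s
  beta <- exp(-p$dt / bigT)

  types <- unique(ev$event_type)
  elig <- stats::setNames(numeric(length(types)), types)
  base <- stats::setNames(numeric(length(types)), types)
  m_cr <- 0
  step_at <- round((ev$time_s - t0) / p$dt)
  n_ev <- nrow(ev)

  nc_at <- function() {
    m_c <- max(base[["cs_plus"]], p$rate_floor)
    m_r <- base[["reward"]]
    prospective <- m_cr * m_r / m_c
    p$w * (prospective - m_r) + (1 - p$w) * (m_cr - base[["cs_plus"]])
  }

  cue_rows <- which(ev$event_type == "cs_plus")
  n_trials <- length(cue_rows)
  quantity <- numeric(n_trials)
  da_trial <- integer(0)
  da_event <- character(0)
  da_value <- numeric(0)
  prev_step <- 0
  cue_i <- 0L
  for (i in seq_len(n_ev)) {
    n_steps <- step_at[i] - prev_step
    if (n_steps > 0) {
      decay <- beta^n_steps
      for (ty in types) {
        base[[ty]] <- baseline_update_n(base[[ty]], elig[[ty]], n_steps,
                                        p$alpha0, beta)
        elig[[ty]] <- elig[[ty]] * decay
      }
      prev_step <- step_at[i]
    }
    ty <- ev$event_type[i]
    if (ty == "reward") {
      m_cr <- (1 - alpha) * m_cr + alpha * elig[["cs_plus"]]
    }
    nc <- nc_at()
    if (ty == "cs_plus") {
      cue_i <- cue_i + 1L
      quantity[cue_i] <- nc
      da_trial <- c(da_trial, ev$trial_index[i])
      da_event <- c(da_event, "cue")
      da_value <- c(da_value, nc)
    } else if (ty == "reward") {
      da_trial <- c(da_trial, ev$trial_index[i])
      da_event <- c(da_event, "reward")
      da_value <- c(da_value, nc + p$innate_meaningfulness)
    }
    elig[[ty]] <- elig[[ty]] + 1
  }
  learned <- which(quantity > p$threshold)[1]
  trial_ids <- ev$trial_index[cue_rows]
  new_sim_result(
    model = "anccr",
    per_trial = tibble::tibble(trial_index = trial_ids, quantity = quantity),
    da = tibble::tibble(trial_index = da_trial, event = da_event,
                        value = da_value),
    learned_trial = if (is.na(learned)) NA_integer_ else trial_ids[learned],
    threshold = p$threshold,
    params = p
  )
}
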