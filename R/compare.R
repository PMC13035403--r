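#' Simulated ITI conditions matching the experimental groups
#'
#' One row per ITI condition with the number of trials experimental animals
#' experienced over eight days of conditioning (30 s: 800, 60 s: 400,
#' 300 s: 88, 600 s: 48, 3,600 s: 16), the default 20 iterations per
#' condition, and the nominal IRI.
#'
#' @param labels Subset of conditions to return (default all five).
#' @param n_iterations Iterations per condition (default 20).
#' @return Tibble with `label`, `mean_iti`, `n_trials`, `n_iterations`,
#'   `iri_s`.
#' @export
study_conditions <- function(labels = c("30", "60", "300", "600", "3600"),
                             n_iterations = 20) {
  all <- tibble::tibble(
    label = c("30", "60", "300", "600", "3600"),
    mean_iti = c(30, 60, 300, 600, 3600),
    n_trials = c(800L, 400L, 88L, 48L, 16L)
  )
  out <- all[all$label %in% labels, ]
  out$n_iterations <- as.integer(n_iterations)
  out$iri_s <- nominal_iri(out$mean_iti)
  out
}

#' Observed group-mean trials-to-learn
#'
#' The reported group means used as the experimental reference for model
#' scoring: 176 (30-s ITI), 94 (60-s), 16.7 (300-s), 8.8 (600-s) and 3.6
#' (3,600-s) trials.
#'
#' @return Tibble with `label`, `mean_iti`, `iri_s`, `trials_to_learn`.
#' @export
observed_trials_to_learn <- function() {
  tibble::tibble(
    label = c("30", "60", "300", "600", "3600"),
    mean_iti = c(30, 60, 300, 600, 3600),
    iri_s = nominal_iri(c(30, 60, 300, 600, 3600)),
    trials_to_learn = c(176, 94, 16.7, 8.8, 3.6)
  )
}

#' Run one model over one ITI condition
#'
#' Builds a fresh schedule per iteration (single session carrying all
#' trials; session splits carry no modeled time) and records each
#' iteration's learned trial. Iterations that never cross the threshold
#' are censored and, for scoring, assigned the simulated trial count plus
#' one.
#'
#' @param simulate Simulator: a function `(schedule, params) -> sim_result`
#'   such as [simulate_anccr()].
#' @param params Model parameter object passed through.
#' @param condition One row of [study_conditions()].
#' @param seeds Integer seeds, one per iteration.
#' @param iti_jitter ITI jitter fraction (default 0.2; the 3,600-s group
#'   used a fixed ITI).
#' @return Tibble with `label`, `iteration`, `seed`, `learned_trial`
#'   (censor-substituted), `censored`.
#' @export
run_condition <- function(simulate, params, condition, seeds,
                          iti_jitter = if (condition$mean_iti >= 3600) 0 else 0.2) {
  stopifnot(nrow(condition) == 1)
  spec <- protocol_spec(
    paste0("iti", condition$label), condition$mean_iti,
    trials_per_session = condition$n_trials, n_sessions = 1,
    iti_jitter = iti_jitter
  )
  purrr::map_dfr(seq_along(seeds), function(i) {
    sched <- build_schedule(spec, seed = seeds[i])
    res <- simulate(sched, params)
    censored <- is.na(res$learned_trial)
    tibble::tibble(
      label = condition$label,
      iteration = i,
      seed = seeds[i],
      learned_trial = if (censored) condition$n_trials + 1L else
        res$learned_trial,
      censored = censored
    )
  })
}

#' Residual sum of squares on log-transformed trials-to-learn
#'
#' `sum((log10(sim) - log10(exp))^2)` over matched conditions; the log
#' transform accounts for the wide variation in trials to learn across
#' IRIs.
#'
#' @param sim_trials,exp_trials Positive trials-to-learn vectors of equal
#'   length (matched condition order).
#' @return RSS (scalar).
#' @export
rss_log <- function(sim_trials, exp_trials) {
  stopifnot(length(sim_trials) == length(exp_trials))
  if (any(sim_trials <= 0) || any(exp_trials <= 0)) {
    stop("trials-to-learn must be positive for log RSS", call. = FALSE)
  }
  sum((log10(sim_trials) - log10(exp_trials))^2)
}

#' Mean log-RSS of simulated against observed trials-to-learn
#'
#' Aggregates [rss_log()] over iterations: either each iteration's
#' simulated trials are scored against the observed condition means and the
#' RSS averaged over iterations (`"per_iteration"`, default) or the
#' per-condition iteration means are scored once (`"means"`).
#'
#' @param runs Output of [run_condition()] (rows for several conditions).
#' @param observed Tibble with `label` and `trials_to_learn` (default
#'   [observed_trials_to_learn()]).
#' @param strategy Aggregation strategy.
#' @return Mean RSS (scalar).
#' @export
mean_rss_log <- function(runs, observed = observed_trials_to_learn(),
                         strategy = c("per_iteration", "means")) {
  strategy <- match.arg(strategy)
  obs <- observed$trials_to_learn[match(runs$label, observed$label)]
  if (anyNA(obs)) stop("unmatched condition labels", call. = FALSE)
  runs$observed <- obs
  if (strategy == "per_iteration") {
    per_iter <- dplyr::summarise(
      dplyr::group_by(runs, .data$iteration),
      rss = rss_log(.data$learned_trial, .data$observed),
      .groups = "drop"
    )
    mean(per_iter$rss)
  } else {
    per_cond <- dplyr::summarise(
      dplyr::group_by(runs, .data$label),
      sim = mean(.data$learned_trial),
      observed = .data$observed[1],
      .groups = "drop"
    )
    rss_log(per_cond$sim, per_cond$observed)
  }
}

#' Akaike information criterion from a mean RSS
#'
#' `AIC = 2k + n * ln(meanRSS)`. Model comparisons here report the
#' conservative `k = 0` variant (no parameter penalty), under which the
#' formula reduces to `n * ln(meanRSS)`.
#'
#' @param mean_rss Mean residual sum of squares (> 0).
#' @param n Sample size (number of animals in the compared groups).
#' @param k Number of model parameters (default 0).
#' @return AIC value.
#' @export
aic <- function(mean_rss, n, k = 0) {
  if (mean_rss <= 0) stop("mean RSS must be positive", call. = FALSE)
  2 * k + n * log(mean_rss)
}

#' Relative model weights from AIC values
#'
#' `weight_m = exp(-0.5 * (AIC_m - min(AIC)))`; the best model's weight
#' is 1.
#'
#' @param aics Named or unnamed numeric AIC vector.
#' @return Weights, same names.
#' @export
#' @examples
#' model_weights(c(sop = 373.5, anccr = 347.2))
model_weights <- function(aics) {
  stopifnot(length(aics) >= 1)
  exp(-0.5 * (aics - min(aics)))
}

#' Simulated total conditioning time to learn
#'
#' `L` trial blocks plus `L + 1` mean ITIs (leading-ITI convention),
#' mirroring the behavioral total-time-to-learn computed on realized
#' schedules.
#'
#' @param mean_iti Mean ITI, s (or a [study_conditions()] row).
#' @param learned_trial Learned trial `L` (>= 1).
#' @param trial_block Trial duration incl. consumption (default 4.25 s).
#' @return Seconds.
#' @export
sim_time_to_learn <- function(mean_iti, learned_trial, trial_block = 4.25) {
  if (is.data.frame(mean_iti)) mean_iti <- mean_iti$mean_iti
  stopifnot(all(learned_trial >= 1))
  learned_trial * trial_block + (learned_trial + 1) * mean_iti
}

#' Sweep a parameter grid for one model over the ITI conditions
#'
#' Evaluates every row of a parameter grid with [run_condition()] across
#' the supplied conditions, scores each against the observed
#' trials-to-learn with [mean_rss_log()], and ranks by mean RSS.
#'
#' @param simulate Simulator function `(schedule, params) -> sim_result`.
#' @param grid Data frame of parameter combinations (one column per
#'   argument of `make_params`).
#' @param make_params Function turning one grid row (as a list) into the
#'   simulator's parameter object.
#' @param conditions [study_conditions()] subset.
#' @param observed Observed reference (default printed group means).
#' @param seed Integer master seed (per-iteration seeds derive from it).
#' @param n_iterations Iterations per condition per combination.
#' @param constraint Optional predicate on a grid row (as a list); rows
#'   failing it are dropped (e.g. the SOP `pd1 > pd2` rule).
#' @param strategy Passed to [mean_rss_log()].
#' @return Tibble: the grid columns plus `mean_rss` and `rank`, ordered
#'   best first, with per-combination runs in the `runs` list-column.
#' @export
sweep_grid <- function(simulate, grid, make_params, conditions,
                       observed = observed_trials_to_learn(),
                       seed = 1, n_iterations = 5,
                       constraint = NULL,
                       strategy = "per_iteration") {
  stopifnot(nrow(grid) >= 1)
  if (!is.null(constraint)) {
    keep <- vapply(seq_len(nrow(grid)),
                   function(i) isTRUE(constraint(as.list(grid[i, , drop = FALSE]))),
                   logical(1))
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0) stop("constraint removed every combination",
                              call. = FALSE)
  }
  seeds <- matrix(
    seq_len(nrow(conditions) * n_iterations) + as.integer(seed) * 1000L,
    nrow = nrow(conditions)
  )
  results <- purrr::map(seq_len(nrow(grid)), function(g) {
    params <- make_params(as.list(grid[g, , drop = FALSE]))
    runs <- purrr::map_dfr(seq_len(nrow(conditions)), function(ci) {
      run_condition(simulate, params, conditions[ci, ], seeds[ci, ])
    })
    list(runs = runs, mean_rss = mean_rss_log(runs, observed, strategy))
  })
  out <- tibble::as_tibble(grid)
  out$mean_rss <- vapply(results, `[[`, numeric(1), "mean_rss")
  out$runs <- purrr::map(results, "runs")
  out <- out[order(out$mean_rss), ]
  out$rank <- seq_len(nrow(out))
  out
}
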