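#' Parameters for the SOP associative-learning simulator
#'
#' In SOP, cue and reward each evoke a processing node whose elements
#' occupy an inactive state (I), a primary active state (A1) or a
#' secondary/refractory active state (A2). Stimulus presentation moves a
#' proportion `p1` of inactive elements into A1; every step, `pd1` of A1
#' decays into A2 and `pd2` of A2 decays back to I. Association strength
#' grows when cue A1 and reward A1 overlap (weighted `L_plus * r1`) and
#' shrinks when cue A1 overlaps reward A2 (weighted `L_minus * r2`). After
#' learning, cue presentation drives reward elements directly into A2 in
#' proportion to the association (the conditioned-response pathway), which
#' is one route by which longer ITIs -- letting elements drain from the
#' refractory A2 pool back to I -- can speed learning.
#'
#' Defaults are the best-fitting combination under the `pd1 > pd2`
#' constraint: `threshold = 0.1`, `pd1_us = 0.25`, `pd2_us = 0.1`,
#' `pd1_cs = 0.1`, `pd2_cs = 1e-4`, with fixed `dt = 0.25` s, `r1 = 1`,
#' `r2 = 0.5`, `L_plus = 0.2`, `L_minus = 0.1`, `p1_cs = 0.1`,
#' `p1_us = 0.6`.
#'
#' @param dt Time step, s.
#' @param r1,r2 Reward magnitudes weighting the A1/A1 and A1/A2 overlaps.
#' @param L_plus,L_minus Excitatory/inhibitory learning scale factors.
#' @param p1_cs,p1_us I -> A1 activation proportions on presentation.
#' @param pd1_cs,pd2_cs,pd1_us,pd2_us Per-step A1 -> A2 and A2 -> I decay
#'   proportions for each node.
#' @param threshold Behavior-generation threshold on trial value.
#' @param enforce_pd1_gt_pd2 Validate `pd1 > pd2` per node (default TRUE,
#'   the constraint under which the sweep was run).
#' @return Object of class `sop_params`.
#' @export
sop_params <- function(dt = 0.25, r1 = 1, r2 = 0.5,
                       L_plus = 0.2, L_minus = 0.1,
                       p1_cs = 0.1, p1_us = 0.6,
                       pd1_cs = 0.1, pd2_cs = 1e-4,
                       pd1_us = 0.25, pd2_us = 0.1,
                       threshold = 0.1,
                       enforce_pd1_gt_pd2 = TRUE) {
  probs <- c(p1_cs, p1_us, pd1_cs, pd2_cs, pd1_us, pd2_us)
  if (any(probs < 0 | probs > 1)) {
    stop("SOP transition proportions must lie in [0, 1]", call. = FALSE)
  }
  if (enforce_pd1_gt_pd2 && (pd1_cs <= pd2_cs || pd1_us <= pd2_us)) {
    stop("SOP constraint violated: pd1 must exceed pd2 for each node",
         call. = FALSE)
  }
  structure(
    list(dt = dt, r1 = r1, r2 = r2, L_plus = L_plus, L_minus = L_minus,
         p1_cs = p1_cs, p1_us = p1_us, pd1_cs = pd1_cs, pd2_cs = pd2_cs,
         pd1_us = pd1_us, pd2_us = pd2_us, threshold = threshold),
    class = "sop_params"
  )
}

#' Simulate SOP on an event schedule
#'
#' Evolves the cue and reward element-state fractions over the full
#' conditioning timeline and accumulates the cue-reward association
#' (value). The per-trial quantity is the maximum value between cue onset
#' and reward time; the learned trial is its first threshold crossing.
#'
#' @param schedule An `event_schedule`.
#' @param params A [sop_params()].
#' @return A `sim_result` (see [simulate_tdrl_microstimulus()]); its `da`
#'   element is `NULL` (SOP is not a dopamine model).
#' @export
simulate_sop <- function(schedule, params = sop_params()) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(params, "sop_params"))
  disc <- discretize_schedule(schedule, params$dt)
  n <- disc$n_steps
  n_trials <- length(disc$cue_steps)
  cue_at <- logical(n)
  cue_at[disc$cue_steps] <- TRUE
  rew_at <- logical(n)
  rew_at[disc$reward_steps] <- TRUE
  trial_at <- integer(n)
  for (k in seq_len(n_trials)) {
    trial_at[disc$cue_steps[k]:disc$window_end_steps[k]] <- k
  }

  # state fractions: [I, A1, A2] per node
  cs <- c(1, 0, 0)
  us <- c(1, 0, 0)
  v <- 0
  quantity <- rep(-Inf, n_trials)
  p <- params
  gain <- p$L_plus * p$r1
  loss <- p$L_minus * p$r2

  for (t in seq_len(n)) {
    if (cue_at[t]) {
      dx <- p$p1_cs * cs[1]
      cs[1] <- cs[1] - dx
      cs[2] <- cs[2] + dx
      # conditioned-response pathway: cue drives US elements I -> A2
      cr <- min(1, max(0, v)) * us[1]
      us[1] <- us[1] - cr
      us[3] <- us[3] + cr
    }
    if (rew_at[t]) {
      dx <- p$p1_us * us[1]
      us[1] <- us[1] - dx
      us[2] <- us[2] + dx
    }
    d1 <- p$pd1_cs * cs[2]
    d2 <- p$pd2_cs * cs[3]
    cs[2] <- cs[2] - d1
    cs[3] <- cs[3] + d1 - d2
    cs[1] <- cs[1] + d2
    d1 <- p$pd1_us * us[2]
    d2 <- p$pd2_us * us[3]
    us[2] <- us[2] - d1
    us[3] <- us[3] + d1 - d2
    us[1] <- us[1] + d2
    v <- v + cs[2] * (gain * us[2] - loss * us[3])
    tr <- trial_at[t]
    if (tr > 0 && v > quantity[tr]) quantity[tr] <- v
  }
  learned <- which(quantity > p$threshold)[1]
  new_sim_result(
    model = "sop",
    per_trial = tibble::tibble(trial_index = disc$trial_index,
                               quantity = quantity),
    da = NULL,
    learned_trial = if (is.na(learned)) NA_integer_ else
      disc$trial_index[learned],
    threshold = p$threshold,
    params = p
  )
}
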