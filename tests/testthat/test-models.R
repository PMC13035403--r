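paired_sched <- function(n = 30, iti = 20, seed = 1) {
  build_schedule(protocol_spec("m", iti, n, 1), seed = seed)
}

test_that("TDRL with zero learning rate never learns", {
  sch <- paired_sched(n = 10)
  res <- simulate_tdrl_microstimulus(sch, tdrl_params(alpha = 0))
  expect_true(all(res$per_trial$quantity == 0))
  expect_true(is.na(res$learned_trial))
})

test_that("a one-state TDRL run matches the tabular TD recursion oracle", {
  # cue and reward on adjacent steps; a fast-dying trace with one
  # microstimulus centered at 1 makes the feature one-hot per event
  dt <- 0.25
  n_tr <- 40
  cue_t <- seq(10, by = 10, length.out = n_tr)
  sch <- manual_schedule(cue_times = cue_t, reward_times = cue_t + dt)
  p <- tdrl_params(m = 1, lambda = 0, d = 1e-6, sigma = 0.05,
                   gamma = 0.05, alpha = 0.1)
  res <- simulate_tdrl_microstimulus(sch, p)
  # oracle recursion: the trial-k window reads V(cue) before the update at
  # the reward step; reward-state weights receive no reward credit (the
  # reward is attributed to the cue state), so w_r stays 0 and
  # V(cue) follows the tabular TD(0) saturation 1 - (1 - alpha)^(k-1)
  w_c <- w_r <- 0
  v_cue <- numeric(n_tr)
  for (k in seq_len(n_tr)) {
    v_cue[k] <- w_c
    w_c <- w_c + p$alpha * (1 + p$gamma * w_r - w_c)
    w_r <- (1 - p$alpha) * w_r
  }
  expect_equal(res$per_trial$quantity, v_cue, tolerance = 1e-9)
  expect_equal(res$per_trial$quantity,
               1 - (1 - p$alpha)^(seq_len(n_tr) - 1), tolerance = 1e-9)
})

test_that("the IRI-scaled learning rate follows 1 - exp(-k IRI)", {
  sch <- paired_sched(n = 5, iti = 60)
  res <- simulate_tdrl_scaled(sch, k_scale = 3e-4, iri_s = 64.25)
  expect_equal(res$params$alpha, 1 - exp(-3e-4 * 64.25))
  expect_equal(res$params$alpha, 0.01909, tolerance = 1e-4)
  # k = 0 disables learning entirely
  res0 <- simulate_tdrl_scaled(sch, k_scale = 0, iri_s = 64.25)
  expect_true(is.na(res0$learned_trial))
  # monotone, saturating map
  a <- 1 - exp(-3e-4 * c(10, 100, 1000, 1e5))
  expect_true(all(diff(a) > 0))
  expect_lt(abs(a[4] - 1), 1e-12)
})

test_that("alpha_from_iri satisfies its closed-form identities", {
  expect_equal(alpha_from_iri(4e-5, 0.2, 0.2), 4e-5)
  expect_equal(alpha_from_iri(4e-5, 64.25, 0.2),
               1 - (1 - 4e-5)^321.25)
  expect_equal(alpha_from_iri(4e-5, 64.25, 0.2),
               -expm1(321.25 * log1p(-4e-5)), tolerance = 1e-12)
  expect_equal(alpha_from_iri(4e-5, 64.25, 0.2), 0.012768, tolerance = 1e-4)
  # small-rate proportionality: alpha(2 IRI) / alpha(IRI) -> 2
  r <- alpha_from_iri(1e-8, 128.5, 0.2) / alpha_from_iri(1e-8, 64.25, 0.2)
  expect_equal(r, 2, tolerance = 1e-4)
  # exact and approximate agree within 1% in the small-alpha regime
  iris <- c(1, 10, 50, 75)
  exact <- alpha_from_iri(4e-5, iris, 0.2)
  approx <- alpha_from_iri(4e-5, iris, 0.2, approx = TRUE)
  expect_true(all(exact <= 0.02))
  expect_true(all(abs(exact - approx) / exact < 0.01))
  # increasing in IRI, saturating at 1 (to machine precision for huge IRI)
  a <- alpha_from_iri(1e-3, c(1, 10, 100, 1000, 1e6), 0.2)
  expect_true(all(diff(a[1:4]) > 0))
  expect_lt(abs(a[5] - 1), 1e-9)
})

test_that("SOP conserves element fractions and matches a step-by-step oracle", {
  dt <- 0.25
  cue_t <- seq(5, by = 12, length.out = 8)
  sch <- manual_schedule(cue_times = cue_t, reward_times = cue_t + 1.25)
  p <- sop_params()
  res <- simulate_sop(sch, p)
  n_steps <- ceiling((max(sch$time_s)) / dt) + 1
  cue_steps <- round(cue_t / dt) + 1
  rew_steps <- round((cue_t + 1.25) / dt) + 1
  v_path <- oracle_sop(n_steps, cue_steps, rew_steps, p)
  # per-trial max V between cue and reward
  want <- vapply(seq_along(cue_steps), function(k) {
    max(v_path[cue_steps[k]:(cue_steps[k] + 5)])
  }, numeric(1))
  expect_equal(res$per_trial$quantity, want, tolerance = 1e-12)
})

test_that("SOP with no stimuli stays inactive, and pairing beats unpairing", {
  sch <- manual_schedule(cue_times = numeric(0), reward_times = numeric(0),
                         t_end = 100)
  res <- simulate_sop(sch, sop_params())
  expect_equal(nrow(res$per_trial), 0)
  # paired: reward at cue + 1.25 s; unpaired: reward mid-ITI (max separation)
  cue_t <- seq(20, by = 40, length.out = 12)
  paired <- manual_schedule(cue_times = cue_t, reward_times = cue_t + 1.25)
  unpaired <- manual_schedule(cue_times = cue_t, reward_times = cue_t + 20)
  vp <- max(simulate_sop(paired, sop_params())$per_trial$quantity)
  vu <- max(simulate_sop(unpaired, sop_params())$per_trial$quantity)
  expect_gt(vp, vu)
})

test_that("SOP rejects invalid transition probabilities", {
  expect_error(sop_params(pd1_cs = 1.2), "\\[0, 1\\]")
  expect_error(sop_params(pd1_us = 0.1, pd2_us = 0.2), "pd1")
  expect_silent(sop_params(pd1_us = 0.1, pd2_us = 0.2,
                           enforce_pd1_gt_pd2 = FALSE))
})

test_that("closed-form ANCCR baseline updates equal the literal per-dt loop", {
  set.seed(3)
  for (i in 1:20) {
    m0 <- stats::runif(1)
    e0 <- stats::runif(1, 0, 3)
    n <- sample(1:500, 1)
    a0 <- stats::runif(1, 1e-6, 0.05)
    beta <- stats::runif(1, 0.5, 0.999)
    expect_equal(
      irilearn:::baseline_update_n(m0, e0, n, a0, beta),
      oracle_baseline_loop(m0, e0, n, a0, beta),
      tolerance = 1e-10
    )
  }
  # degenerate branch: beta == 1 - a0
  expect_equal(irilearn:::baseline_update_n(0.5, 1, 50, 0.01, 0.99),
               oracle_baseline_loop(0.5, 1, 50, 0.01, 0.99),
               tolerance = 1e-10)
})

test_that("ANCCR crosses threshold for paired streams but not independent ones", {
  sch <- build_schedule(protocol_spec("a", 60, 120, 1), seed = 2)
  res <- simulate_anccr(sch)
  expect_false(is.na(res$learned_trial))
  # independent Poisson cue and reward streams: contingency hovers near 0
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    cue_t <- sort(stats::runif(400, 0, 400 * 64.25))
    rew_t <- sort(stats::runif(400, 0, 400 * 64.25))
    null_sch <- manual_schedule(cue_times = cue_t, reward_times = rew_t,
                                reward_trials = rep(NA_integer_, 400))
    nres <- simulate_anccr(null_sch, anccr_params())
    if (is.na(nres$learned_trial)) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("ANCCR trials-to-learn scale ~10x between 60-s and 600-s conditions", {
  conds <- study_conditions(c("60", "600"))
  lt <- purrr::map_dbl(1:2, function(i) {
    runs <- run_condition(simulate_anccr, anccr_params(), conds[i, ],
                          seeds = 1:5)
    mean(runs$learned_trial)
  })
  ratio <- lt[1] / lt[2]
  expect_gte(ratio, 5)
  expect_lte(ratio, 20)
})

test_that("an infinite threshold never yields a learned trial", {
  sch <- paired_sched(n = 20)
  res <- simulate_anccr(sch, anccr_params(threshold = Inf))
  expect_true(is.na(res$learned_trial))
})

test_that("simulators are reproducible given the schedule seed", {
  sp <- protocol_spec("r", 30, 15, 1)
  r1 <- simulate_anccr(build_schedule(sp, seed = 5))
  r2 <- simulate_anccr(build_schedule(sp, seed = 5))
  expect_identical(r1$per_trial, r2$per_trial)
  t1 <- simulate_tdrl_microstimulus(build_schedule(sp, seed = 5))
  t2 <- simulate_tdrl_microstimulus(build_schedule(sp, seed = 5))
  expect_identical(t1$per_trial, t2$per_trial)
})

test_that("TDRL value stays bounded with bounded rewards and gamma < 1", {
  sch <- paired_sched(n = 80, iti = 10)
  res <- simulate_tdrl_microstimulus(sch, tdrl_params())
  expect_true(all(is.finite(res$per_trial$quantity)))
  expect_lt(max(res$per_trial$quantity), 20)
})
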