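plant_licks <- function(times) {
  structure(
    tibble::tibble(session_index = 1L, onset_s = sort(times),
                   offset_s = sort(times) + 0.05),
    class = c("lick_train", class(tibble::tibble()))
  )
}

test_that("cue-evoked licks count the cue window minus the baseline window", {
  sch <- manual_schedule(cue_times = c(100, 200),
                         reward_times = c(101.25, 201.25))
  # no licks at all
  m0 <- cue_evoked_licks(plant_licks(numeric(0)), sch)
  expect_equal(m0$delta_licks, c(0L, 0L))
  # 4 onsets only inside the first cue window
  m1 <- cue_evoked_licks(plant_licks(c(100.1, 100.4, 100.8, 101.2)), sch)
  expect_equal(m1$delta_licks[1], 4L)
  expect_equal(m1$delta_rate_hz[1], 3.2)
  # 3 onsets in each window cancel
  m2 <- cue_evoked_licks(
    plant_licks(c(198.8, 199.0, 199.5, 200.1, 200.5, 201.0)), sch
  )
  expect_equal(m2$delta_licks[2], 0L)
})

test_that("the cumsum detector reproduces the hand-computed step geometry", {
  series <- c(rep(0, 20), rep(5, 20))
  res <- cumsum_change_point(series)
  expect_equal(res$learned_trial, 15L)
  expect_equal(res$max_distance, 50)
  expect_equal(res$threshold_distance, 37.5)
  expect_equal(abruptness(res), 0.375)
  expect_equal(res$n_reanchor_iterations, 1L)
})

test_that("degenerate and invalid series are flagged", {
  expect_true(cumsum_change_point(rep(2, 10))$degenerate)
  expect_true(is.na(cumsum_change_point(rep(2, 10))$learned_trial))
  expect_true(cumsum_change_point(rep(3.3, 25))$degenerate)
  expect_error(cumsum_change_point(c(1, 2)), "at least 3")
  # strictly decreasing series has no positive-going inflection
  expect_true(cumsum_change_point(seq(10, 1))$degenerate)
})

test_that("negative direction detects the mirrored inflection", {
  series <- c(rep(0, 20), rep(5, 20))
  pos <- cumsum_change_point(series, direction = "positive")
  neg <- cumsum_change_point(-series, direction = "negative")
  expect_equal(neg$learned_trial, pos$learned_trial)
  # a positive-going series yields nothing under negative direction
  expect_true(cumsum_change_point(series, direction = "negative")$degenerate)
})

test_that("detector matches the brute-force oracle on 1,000 random series", {
  set.seed(20260101)
  for (rep in seq_len(1000)) {
    n <- sample(3:60, 1)
    x <- random_series(n)
    got <- cumsum_change_point(x)
    want <- oracle_change_point(x)
    expect_identical(got$degenerate, want$degenerate)
    if (!want$degenerate) {
      expect_identical(got$learned_trial, want$learned)
    }
  }
})

test_that("appending post-learning trials barely moves the learned trial", {
  base <- c(rep(0, 20), rep(5, 20))
  l0 <- cumsum_change_point(base)$learned_trial
  for (extra in c(5, 10, 20)) {
    l1 <- cumsum_change_point(c(base, rep(5, extra)))$learned_trial
    expect_lte(abs(l1 - l0), 1)
  }
})

test_that("planted change points are recovered within two trials in >= 90% of cohorts", {
  sp <- protocol_spec("rec", 20, 60, 1)
  hits <- 0
  for (seed in 1:50) {
    sch <- build_schedule(sp, seed = seed)
    out <- gen_licks(sch, behavior_gen_params(baseline_lick_rate = 0.5,
                                             anticipatory_rate = 4,
                                             change_point_trial = 25),
                     seed = seed + 1000)
    m <- cue_evoked_licks(out$licks, sch)
    # the max-distance reading estimates the change point itself; the 75%
    # default deliberately marks the earlier onset of the rise
    det <- cumsum_change_point(m$delta_licks, threshold_frac = 1)
    if (!det$degenerate && abs(det$learned_trial - 25) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("learner classification needs two sessions above 0.5 Hz", {
  expect_false(classify_learner(c(0, 0, 0)))
  expect_true(classify_learner(c(0.2, 0.6, 0.7)))
  expect_false(classify_learner(c(0.6, 0.4, 0.4)))
})

test_that("trial-1 alignment finds the first consumed reward", {
  sch <- manual_schedule(cue_times = c(10, 30, 50),
                         reward_times = c(11.25, 31.25, 51.25))
  expect_equal(align_trial_one(plant_licks(12), sch), 1L)
  expect_equal(align_trial_one(plant_licks(52), sch), 3L)
  expect_equal(align_trial_one(plant_licks(52), sch, mode = "raw"), 1L)
  expect_error(align_trial_one(plant_licks(numeric(0)), sch), "alignment failure")
})

test_that("rewards before a trial are counted under partial reinforcement", {
  sch100 <- manual_schedule(cue_times = seq(10, 100, by = 10),
                            reward_times = seq(10, 100, by = 10) + 1.25)
  expect_equal(rewards_before_trial(sch100, 9), 8)
  expect_equal(rewards_before_trial(sch100, 1), 0)
  # alternating reward pattern: trials 1,3,5,7 rewarded before trial 9
  cue <- seq(10, 100, by = 10)
  alt <- manual_schedule(cue_times = cue,
                         reward_times = cue[c(1, 3, 5, 7, 9)] + 1.25,
                         reward_trials = c(1, 3, 5, 7, 9))
  expect_equal(rewards_before_trial(alt, 9), 4)
})

test_that("total time to learn matches the closed form on jitter-0 schedules", {
  s60 <- build_schedule(protocol_spec("a", 60, 12, 1, iti_jitter = 0), seed = 1)
  expect_equal(total_time_to_learn(s60, 10), 10 * 4.25 + 11 * 60)
  s600 <- build_schedule(protocol_spec("b", 600, 3, 1, iti_jitter = 0), seed = 1)
  expect_equal(total_time_to_learn(s600, 1), 4.25 + 2 * 600)
  expect_error(total_time_to_learn(s60, 0))
  # learned on the final trial: sums through the end of the session
  expect_equal(total_time_to_learn(s60, 12), 12 * 64.25)
})

test_that("ITI lick rate excludes consumption bouts", {
  sch <- manual_schedule(cue_times = c(60, 130),
                         reward_times = c(61.25, 131.25))
  # no licks -> 0 Hz everywhere
  r0 <- iti_lick_rate(plant_licks(numeric(0)), sch)
  expect_true(all(r0$per_iti$rate_hz == 0))
  # all licks inside a <= 500-ms-gap bout right after reward
  bout <- 61.4 + seq(0, 2, by = 0.3)
  r1 <- iti_lick_rate(plant_licks(bout), sch)
  expect_equal(r1$per_iti$rate_hz[r1$per_iti$trial_index == 2], 0)
  # 6 onsets spread over the post-bout window
  spread <- c(bout, seq(70, 120, by = 10))
  r2 <- iti_lick_rate(plant_licks(spread), sch)
  row <- r2$per_iti[r2$per_iti$trial_index == 2, ]
  expect_equal(row$n_licks, 6)
  expect_equal(row$rate_hz, 6 / (130 - row$window_start_s))
})

test_that("sigmoid fits recover planted parameters and flag flat series", {
  x <- 1:80
  y <- 1 / (1 + exp(-0.5 * (x - 40)))
  fit <- sigmoid_fit(y, x)
  expect_true(fit$converged)
  expect_equal(fit$L, 1, tolerance = 1e-6)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_equal(fit$half_rise_trial, 40, tolerance = 1e-6)
  expect_equal(fit$rise95_trial, 40 + log(19) / 0.5, tolerance = 1e-5)
  flat <- sigmoid_fit(rep(1, 10))
  expect_false(flat$converged)
  y41 <- 2 / (1 + exp(-0.3 * (x - 41))) + 0.5
  fit41 <- sigmoid_fit(y41, x)
  expect_equal(fit41$half_rise_trial, 41, tolerance = 1e-5)
})

test_that("analyze_behavior wires generation, detection and summaries together", {
  sch <- build_schedule(protocol_spec("e2e", 30, 50, 2), seed = 5)
  res <- analyze_behavior(sch,
                          behavior_gen_params(change_point_trial = 30),
                          seed = 6, threshold_frac = 1)
  expect_false(res$detection$degenerate)
  expect_lte(abs(res$learned_trial - 30), 3)
  expect_true(res$learner)
  expect_equal(res$rewards_to_learn, res$learned_trial - 1)
  expect_gt(res$time_to_learn_s, 0)
})
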