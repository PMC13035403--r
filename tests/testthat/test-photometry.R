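flat_trace <- function(t_end = 60, fs = 120, f470 = NULL) {
  t <- seq(0, t_end, by = 1 / fs)
  base <- 10 + 0.001 * sin(t / 7)
  structure(
    tibble::tibble(session_index = 1L, time_s = t,
                   f470 = if (is.null(f470)) base else f470,
                   f405 = base),
    class = c("photometry_trace", class(tibble::tibble()))
  )
}

test_that("dF/F of an exactly affine channel pair is identically zero", {
  tr <- flat_trace()
  tr$f470 <- 2 * tr$f405 + 1
  dff <- fit_dff(tr)
  expect_lt(max(abs(dff$dff_percent)), 1e-9)
  fits <- attr(dff, "fits")
  expect_equal(fits$fit_slope, 2, tolerance = 1e-9)
  expect_equal(fits$fit_intercept, 1, tolerance = 1e-9)
})

test_that("a constant isosbestic channel is a singular fit", {
  tr <- flat_trace()
  tr$f405 <- rep(3, nrow(tr))
  expect_error(fit_dff(tr), "singular")
})

test_that("window responses are zero on a flat trace and match the quadrature oracle", {
  tr <- flat_trace()
  tr$f470 <- tr$f405  # dff identically 0
  dff <- fit_dff(tr)
  expect_equal(as.numeric(cue_response(dff, 30)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(omission_response(dff, 30)), 0, tolerance = 1e-12)

  # plant an arbitrary bump directly in a dff trace
  t <- seq(0, 60, by = 1 / 120)
  bump <- function(t0) 3 * exp(-((t - t0) / 0.12)^2)
  dff2 <- structure(
    tibble::tibble(session_index = 1L, time_s = t, dff_percent = bump(30.2)),
    class = c("dff_trace", class(tibble::tibble()))
  )
  got <- as.numeric(cue_response(dff2, 30))
  want <- oracle_auc(t, dff2$dff_percent, 30, 0.5) -
    oracle_auc(t, dff2$dff_percent, 29.5, 0.5)
  expect_equal(got, want, tolerance = 1e-9)
  # bump planted in the baseline window flips the sign
  dff3 <- dff2
  dff3$dff_percent <- bump(29.75)
  want3 <- oracle_auc(t, dff3$dff_percent, 30, 0.5) -
    oracle_auc(t, dff3$dff_percent, 29.5, 0.5)
  expect_equal(as.numeric(cue_response(dff3, 30)), want3, tolerance = 1e-9)
  expect_lt(as.numeric(cue_response(dff3, 30)), 0)
})

test_that("AUC operators are linear in the trace", {
  set.seed(1)
  t <- seq(0, 20, by = 1 / 120)
  x <- stats::rnorm(length(t))
  y <- stats::rnorm(length(t))
  mk <- function(v) structure(
    tibble::tibble(session_index = 1L, time_s = t, dff_percent = v),
    class = c("dff_trace", class(tibble::tibble()))
  )
  a <- 2.5
  b <- -1.3
  for (f in list(function(d) as.numeric(cue_response(d, 10)),
                 function(d) as.numeric(omission_response(d, 8)))) {
    expect_equal(f(mk(a * x + b * y)), a * f(mk(x)) + b * f(mk(y)),
                 tolerance = 1e-9)
  }
})

test_that("the reward anchor follows the first lick unless a contact spans delivery", {
  t <- seq(0, 60, by = 1 / 120)
  dff <- structure(
    tibble::tibble(session_index = 1L, time_s = t,
                   dff_percent = 5 * exp(-((t - 31.0) / 0.1)^2)),
    class = c("dff_trace", class(tibble::tibble()))
  )
  licks_span <- tibble::tibble(session_index = 1L, onset_s = 29.9,
                               offset_s = 30.1)
  r1 <- reward_response(dff, 30, 28, licks_span)
  expect_equal(attr(r1, "anchor"), 30)
  licks_after <- tibble::tibble(session_index = 1L, onset_s = 30.8,
                                offset_s = 30.85)
  r2 <- reward_response(dff, 30, 28, licks_after)
  expect_equal(attr(r2, "anchor"), 30.8)
  r3 <- reward_response(dff, 30, 28, NULL)
  expect_true(attr(r3, "fallback"))
  expect_equal(attr(r3, "anchor"), 30)
})

test_that("normalization uses the top-3 reward responses and is scale invariant", {
  resp <- tibble::tibble(
    trial_index = 1:6,
    rewarded = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    cue_auc = c(0.5, 1, 1.5, 2, 2.5, 3),
    cue_peak = c(0.5, 1, 1.5, 2, 2.5, 3),
    reward_auc = c(1, 2, 3, 4, 5, NA),
    reward_auc_2s = c(2, 4, 6, 8, 10, NA),
    reward_peak = c(1, 2, 3, 4, 5, NA),
    omission_auc = c(NA, NA, NA, NA, NA, -4)
  )
  norm <- normalize_responses(resp)
  expect_equal(attr(norm, "normalizer_05s"), 4)  # mean of 3, 4, 5
  expect_equal(attr(norm, "normalizer_2s"), 8)
  expect_equal(norm$cue_norm, resp$cue_auc / 4)
  expect_equal(norm$omission_norm[6], -0.5)
  scaled <- resp
  for (cl in c("cue_auc", "cue_peak", "reward_auc", "reward_auc_2s",
               "reward_peak", "omission_auc")) {
    scaled[[cl]] <- scaled[[cl]] * 7
  }
  norm2 <- normalize_responses(scaled)
  expect_equal(norm2$cue_norm, norm$cue_norm)
  expect_equal(norm2$omission_norm, norm$omission_norm)
  expect_error(normalize_responses(resp[resp$trial_index < 3, ]), "at least")
})

test_that("the dopamine learned trial uses the 1.5x behavioral anchor", {
  series <- c(rep(0, 4), rep(1, 26))
  res <- dopamine_learned_trial(series, behavior_learned_trial = 10)
  expect_equal(res$anchor <= 15, TRUE)
  want <- oracle_change_point(series, end_anchor = 15)
  expect_equal(res$learned_trial, want$learned)
  # flat zeros give nothing
  expect_true(dopamine_learned_trial(rep(0, 30), 10)$degenerate)
  # clamping when 1.5x exceeds the series
  short <- dopamine_learned_trial(series, behavior_learned_trial = 25)
  expect_true(attr(short, "anchor_clamped"))
})

test_that("omission dips are detected with the negative-direction detector", {
  set.seed(99)
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    dips <- c(stats::rnorm(29, 0, 0.1), stats::rnorm(31, -1, 0.1))
    det <- omission_dip_trial(dips, threshold_frac = 1)
    if (!det$degenerate && abs(det$learned_trial - 30) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 45)
  expect_true(omission_dip_trial(rep(0, 20))$degenerate)
  expect_true(omission_dip_trial(c(rep(0, 10), rep(1, 10)))$degenerate)
})

test_that("noisy dopamine-cue steps are recovered within two trials in >= 90% of runs", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed + 500)
    series <- c(stats::rnorm(19, 0, 0.1), stats::rnorm(41, 1, 0.1))
    det <- dopamine_learned_trial(series, behavior_learned_trial = 30,
                                  threshold_frac = 1)
    if (!det$degenerate && abs(det$learned_trial - 20) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("an early dopamine step yields a dopamine learned trial before behavior", {
  sch <- build_schedule(protocol_spec("lead", 20, 40, 1), seed = 3)
  # cue dopamine rises at trial 8; licking rises at trial 20
  ph <- gen_photometry(
    sch,
    photometry_gen_params(cue_amp = c(rep(0, 7), rep(4, 33)),
                          reward_amp = 6, noise_sd = 0.02),
    seed = 4
  )
  lk <- gen_licks(sch, behavior_gen_params(change_point_trial = 20), seed = 5)
  dff <- fit_dff(ph$trace)
  m <- cue_evoked_licks(lk$licks, sch)
  beh <- cumsum_change_point(m$delta_licks)
  resp <- trial_dopamine_responses(dff, sch, lk$licks)
  norm <- normalize_responses(resp)
  da <- dopamine_learned_trial(norm$cue_norm, beh$learned_trial,
                               threshold_frac = 1)
  expect_false(da$degenerate)
  expect_lt(da$learned_trial, beh$learned_trial)
  expect_lte(abs(da$learned_trial - 8), 2)
})
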