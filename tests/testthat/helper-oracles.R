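# Independent brute-force oracles. These deliberately re-derive each
# quantity with explicit element-wise loops, separate from the package's
# vectorized implementations.

# exhaustive-scan learned-trial detector with an explicit re-anchoring loop
oracle_change_point <- function(series, direction = "positive",
                                threshold_frac = 0.75, end_anchor = NULL) {
  x <- if (direction == "negative") -series else series
  n <- length(x)
  s <- numeric(n + 1)
  for (i in seq_len(n)) s[i + 1] <- s[i] + x[i]
  anchor <- if (is.null(end_anchor)) n else min(end_anchor, n)
  tol <- 1e-10 * max(abs(s), 1)
  for (iter in seq_len(n)) {
    d <- numeric(anchor)
    for (i in seq_len(anchor)) {
      d[i] <- s[anchor + 1] * i / anchor - s[i + 1]
    }
    if (max(d) <= tol) return(list(learned = NA_integer_, degenerate = TRUE))
    dmax <- 0
    for (i in seq_len(anchor)) if (abs(d[i]) > dmax) dmax <- abs(d[i])
    learned <- NA_integer_
    for (i in seq_len(anchor)) {
      if (abs(d[i]) >= threshold_frac * dmax - 1e-12) {
        learned <- i
        break
      }
    }
    if (d[learned] >= 0) {
      return(list(learned = learned, degenerate = FALSE,
                  abruptness = d[learned] / s[anchor + 1]))
    }
    if (learned >= anchor) return(list(learned = NA_integer_, degenerate = TRUE))
    anchor <- learned
  }
  list(learned = NA_integer_, degenerate = TRUE)
}

# trapezoid AUC of a sampled trace over [start, start + width), via pracma
oracle_auc <- function(time_s, y, start, width) {
  i <- which(time_s >= start & time_s < start + width)
  pracma::trapz(time_s[i], y[i])
}

# literal per-dt loop for the ANCCR baseline update (decay, then update)
oracle_baseline_loop <- function(m0, e0, n, a0, beta) {
  m <- m0
  e <- e0
  for (j in seq_len(n)) {
    e <- e * beta
    m <- (1 - a0) * m + a0 * e
  }
  m
}

# step-by-step SOP recursion on explicit event step lists
oracle_sop <- function(n_steps, cue_steps, reward_steps, p) {
  cs <- c(1, 0, 0)
  us <- c(1, 0, 0)
  v <- 0
  v_path <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    if (t %in% cue_steps) {
      dx <- p$p1_cs * cs[1]
      cs <- cs + c(-dx, dx, 0)
      cr <- min(1, max(0, v)) * us[1]
      us <- us + c(-cr, 0, cr)
    }
    if (t %in% reward_steps) {
      dx <- p$p1_us * us[1]
      us <- us + c(-dx, dx, 0)
    }
    d1 <- p$pd1_cs * cs[2]; d2 <- p$pd2_cs * cs[3]
    cs <- cs + c(d2, -d1, d1 - d2)
    d1 <- p$pd1_us * us[2]; d2 <- p$pd2_us * us[3]
    us <- us + c(d2, -d1, d1 - d2)
    v <- v + cs[2] * (p$L_plus * us[2] * p$r1 - p$L_minus * us[3] * p$r2)
    v_path[t] <- v
  }
  v_path
}

# hand-build an event_schedule tibble from explicit event vectors
manual_schedule <- function(cue_times, reward_times,
                            reward_trials = seq_along(reward_times),
                            t_end = NULL) {
  t_end <- t_end %||% (max(c(cue_times, reward_times, 0)) + 10)
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, session_index = 1L, trial_index = NA_integer_,
                   event_type = "session_start", identity = "session"),
    tibble::tibble(time_s = cue_times, session_index = 1L,
                   trial_index = seq_along(cue_times),
                   event_type = "cs_plus", identity = "cs_plus"),
    tibble::tibble(time_s = reward_times, session_index = 1L,
                   trial_index = as.integer(reward_trials),
                   event_type = "reward", identity = "sucrose"),
    tibble::tibble(time_s = t_end, session_index = 1L,
                   trial_index = NA_integer_,
                   event_type = "session_end", identity = "session")
  )
  df <- df[order(df$time_s), ]
  structure(df, class = c("event_schedule", class(tibble::tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random per-trial series generator used for detector equivalence checks
random_series <- function(n) {
  kind <- sample(3, 1)
  if (kind == 1) {
    stats::rnorm(n)
  } else if (kind == 2) {
    cp <- sample(seq(2, n - 1), 1)
    c(stats::rpois(cp, 0.5), stats::rpois(n - cp, 4))
  } else {
    cumsum(stats::rnorm(n, 0.1))
  }
}
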