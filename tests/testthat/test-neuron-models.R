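make_counts <- function(tr, f_rate, id = "m1", period = "delay") {
  ok <- filter(tr, !error)
  tibble(
    neuron_id = id, session_id = ok$session_id, trial_index = ok$trial_index,
    period = period, count = as.integer(round(f_rate(ok))), duration = 1,
    rate = f_rate(ok)
  )
}

test_that("task-relatedness screening flags genuinely modulated periods", {
  cfg <- small_config(n_sequences = 25, seed = 41)
  tr <- generate_behavior(cfg)
  # seeded neuron: control 5 Hz, strong cue response
  spec <- neuron_spec("tr1", "nonadaptive_progress", baseline_rate = 5,
                      gain = 15, target_periods = "cue")
  wc <- simulate_window_counts(spec, tr, seed = 11, include_errors = FALSE)
  sel <- select_task_related(wc, min_trials = 20)
  expect_true(sel$task_related[sel$period == "cue"])
  expect_false("pre_fixation" %in% sel$period)
  # zero spikes everywhere: never task-related
  wc0 <- mutate(wc, count = 0L, rate = 0)
  sel0 <- select_task_related(wc0)
  expect_false(any(sel0$task_related))
  # strict < threshold: a response at exactly alpha is not flagged
  p_cue <- sel$p_value[sel$period == "cue"]
  sel_eq <- select_task_related(wc, alpha = p_cue)
  expect_false(sel_eq$task_related[sel_eq$period == "cue"])
  # too few trials: neuron excluded with a message
  expect_message(
    out <- select_task_related(filter(wc, trial_index < 10), min_trials = 20),
    "excluding"
  )
  expect_equal(nrow(out), 0)
})

test_that("single-model fits agree with the normal-equations oracle", {
  cfg <- small_config(n_sequences = 30, seed = 43)
  tr <- generate_behavior(cfg)
  # noiseless line: rate = 2 * step + 1 -> slope 2, R^2 = 1
  wc_line <- make_counts(tr, function(d) 2 * d$step + 1)
  f <- fit_model(wc_line, tr, "eq2")
  expect_equal(f$estimate, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # constant counts: slope 0, R^2 = 0
  fc <- fit_model(make_counts(tr, function(d) rep(7, nrow(d))), tr, "eq2")
  expect_equal(fc$estimate, 0)
  expect_equal(fc$r_squared, 0)
  # 10-trial instance vs normal equations, all reported quantities
  set.seed(99)
  tr10 <- filter(tr, trial_index %in% (filter(tr, !error)$trial_index[1:10]))
  y <- rpois(10, 6 + 1.3 * filter(tr10, !error)$step)
  wc10 <- make_counts(tr10, function(d) y)
  f10 <- fit_model(wc10, tr10, "eq2")
  X <- cbind(1, filter(tr10, !error)$step)
  oracle <- normal_equations(X, y)
  expect_equal(f10$estimate, oracle$beta[2], tolerance = 1e-10)
  expect_equal(f10$p_value, oracle$p[2], tolerance = 1e-10)
  expect_equal(f10$r_squared, oracle$r2, tolerance = 1e-10)
  # eq3 slope recovers the generating gain across simulated neurons
  cfg2 <- generator_config(interest_rates = 1,
                           length_probs = list(c(`2` = 0.4, `4` = 0.3, `6` = 0.3)),
                           n_sequences = 60, error_rate = 0,
                           neurons = default_roster(2), seed = 45)
  tr2 <- generate_behavior(cfg2)
  gains <- purrr::map_dbl(1:60, function(i) {
    spec <- neuron_spec(paste0("g", i), "adaptive_progress", gain = 12,
                        target_periods = "delay")
    wc <- simulate_window_counts(spec, tr2, seed = 100 + i,
                                 include_errors = FALSE)
    fit_model(filter(wc, period == "delay"), tr2, "eq3")$estimate
  })
  ci <- mean(gains) + c(-1, 1) * qt(0.975, 59) * sd(gains) / sqrt(60)
  expect_gt(12, ci[1])
  expect_lt(12, ci[2])
  # degenerate design: single sequence length makes eq3 collinear with eq2
  cfg1 <- generator_config(interest_rates = 1, length_probs = list(c(`3` = 1)),
                           n_sequences = 20, error_rate = 0,
                           neurons = default_roster(2), seed = 47)
  tr1 <- generate_behavior(cfg1)
  f8 <- fit_model(make_counts(tr1, function(d) d$step + 1), tr1, "eq8")
  expect_true(all(f8$degenerate))
})

test_that("stepwise selection keeps generating regressors and drops noise", {
  cfg <- small_config(n_sequences = 50, seed = 51)
  tr <- generate_behavior(cfg)
  ok <- filter(tr, !error)
  reps <- 40
  kept_prog <- kept_val <- logical(reps)
  set.seed(7)
  for (i in seq_len(reps)) {
    y <- rpois(nrow(ok), 5 + 2 * ok$step)
    wc <- make_counts(tr, function(d) y)
    fs <- fit_stepwise(wc, tr)
    kept_prog[i] <- "progress" %in% fs$term
    kept_val[i] <- any(c("sv_spend", "sv_save", "seq_sv") %in% fs$term)
  }
  expect_gte(mean(kept_prog), 0.9)
  expect_lte(mean(kept_val), 0.35)
  # neuron generated from sequence length only: progress rarely retained
  set.seed(8)
  false_prog <- purrr::map_lgl(seq_len(reps), function(i) {
    y <- rpois(nrow(ok), 4 + 2 * ok$sequence_length)
    "progress" %in% fit_stepwise(make_counts(tr, function(d) y), tr)$term
  })
  expect_lte(mean(false_prog), 0.2)
  # all-zero counts: empty (intercept-only) model
  f0 <- fit_stepwise(make_counts(tr, function(d) rep(0, nrow(d))), tr)
  expect_true(is.na(f0$term))
  expect_equal(f0$r_squared, 0)
  # simultaneous estimation returns every regressor
  fs_all <- fit_stepwise(make_counts(tr, function(d) rpois(nrow(d), 6)), tr,
                         method = "simultaneous")
  expect_true(all(c("choice_spend", "progress", "seq_length") %in% fs_all$term))
})

test_that("model contests count wins and discordant pairs correctly", {
  mk <- function(model, r2, p) {
    tibble(neuron_id = paste0("n", seq_along(r2)), period = "delay",
           model = model, term = "x", estimate = 1, std_estimate = 1,
           p_value = p, r_squared = r2, adj_r_squared = r2,
           model_p_value = p, n_trials = 50, degenerate = FALSE)
  }
  # identical fits: no wins either way, z = 0, p = 1
  a <- mk("eq3", rep(0.3, 10), rep(0.01, 10))
  cmp0 <- compare_models(a, mutate(a, model = "eq2"))
  expect_equal(cmp0$wins_a, 0)
  expect_equal(cmp0$wins_b, 0)
  expect_equal(cmp0$discordant_z, 0)
  expect_equal(cmp0$discordant_p, 1)
  # discordant counts (30, 10): z = 20 / sqrt(40)
  pa <- c(rep(0.01, 30), rep(0.5, 10))
  pb <- c(rep(0.5, 30), rep(0.01, 10))
  cmp1 <- compare_models(mk("eq3", rep(0.2, 40), pa), mk("eq2", rep(0.2, 40), pb))
  expect_equal(cmp1$discordant_z, 20 / sqrt(40), tolerance = 1e-12)
  expect_equal(cmp1$discordant_p, 2 * pnorm(-20 / sqrt(40)), tolerance = 1e-12)
  # adaptive-tuned data: eq3 beats eq2; nonadaptive data: reversed
  cfg <- generator_config(interest_rates = 1,
                          length_probs = list(c(`2` = 0.4, `4` = 0.3, `6` = 0.3)),
                          n_sequences = 80, error_rate = 0,
                          neurons = default_roster(2), seed = 53)
  tr <- generate_behavior(cfg)
  contest <- function(tuning, gain) {
    wcs <- purrr::map_dfr(1:30, function(i) {
      spec <- neuron_spec(sprintf("%s%02d", tuning, i), tuning, gain = gain,
                          target_periods = "delay")
      simulate_window_counts(spec, tr, seed = 200 + i, include_errors = FALSE)
    }) %>% filter(period == "delay")
    compare_models(fit_model(wcs, tr, "eq3"), fit_model(wcs, tr, "eq2"))
  }
  ad <- contest("adaptive_progress", 12)
  expect_gt(ad$wins_a, ad$wins_b)
  na <- contest("nonadaptive_progress", 3)
  expect_gt(na$wins_b, na$wins_a)
})

test_that("slope-sign summaries use the exact binomial distribution", {
  mk_fit <- function(est, p) {
    tibble(neuron_id = paste0("n", seq_along(est)), period = "cue",
           model = "eq2", term = "progress", estimate = est,
           std_estimate = est, p_value = p, r_squared = 0.2,
           adj_r_squared = 0.2, model_p_value = p, n_trials = 50,
           degenerate = FALSE)
  }
  # all positive: p = 2 * 0.5^n (capped at 1)
  s <- summarize_slope_signs(mk_fit(rep(1, 12), rep(0.001, 12)))
  expect_equal(s$p_value, min(1, 2 * 0.5^12), tolerance = 1e-12)
  # published-scale split checked against an explicit tail-sum oracle
  est <- c(rep(1, 294), rep(-1, 114))
  s2 <- summarize_slope_signs(mk_fit(est, rep(0.001, 408)))
  tail_one <- sum(dbinom(294:408, 408, 0.5))
  expect_equal(s2$p_value, min(1, 2 * tail_one), tolerance = 1e-6)
  expect_lt(s2$p_value, 1e-18)
  # balanced split: p in the "no effect" region
  s3 <- summarize_slope_signs(mk_fit(rep(c(1, -1), 25), rep(0.001, 50)))
  expect_gt(s3$p_value, 0.5)
  # non-significant responses are ignored entirely
  expect_equal(nrow(summarize_slope_signs(mk_fit(rep(1, 5), rep(0.5, 5)))), 0)
})

test_that("sliding windows tile segments and localize tuned periods", {
  # window arithmetic: 200 ms window, 25 ms steps on a 1 s segment -> 33
  seg <- tibble(segment = "unit", anchor_event = "t_fix_on", from = 0, to = 1)
  cfg <- small_config(n_sequences = 30, seed = 57)
  tr <- generate_behavior(cfg)
  spec <- neuron_spec("sw1", "nonadaptive_progress", gain = 6,
                      target_periods = "cue")
  sp <- generate_spikes(spec, tr, seed = 12)
  sw_unit <- sliding_window_regression(sp, tr, segments = seg)
  expect_equal(nrow(sw_unit), floor((1.0 - 0.2) / 0.025) + 1)
  # cue-tuned neuron: a significant run overlapping the cue, none pre-fixation
  sw <- sliding_window_regression(sp, tr)
  runs <- sw %>% group_by(segment) %>%
    summarise(run = max(rle(c(p_value < 0.05, FALSE))$lengths[
      c(rle(c(p_value < 0.05, FALSE))$values, FALSE)] %||% 0))
  cue_run <- sw %>% filter(segment == "cue", window_start > -0.05,
                           window_start < 0.35)
  expect_gt(sum(cue_run$p_value < 0.05), 5)
  prefix <- sw %>% filter(segment == "fixation", window_start < -0.3)
  expect_lt(mean(prefix$p_value < 0.05), 0.3)
  # zero-variance windows report p = 1 (pre-trial gap has no spikes)
  sp_empty <- filter(sp, time > 2)
  sw0 <- sliding_window_regression(sp_empty, tr,
                                   segments = tibble(segment = "pre",
                                                     anchor_event = "t_fix_on",
                                                     from = -1, to = -0.5))
  expect_true(all(sw0$p_value == 1))
})

test_that("run-length calibration matches the independent-window null", {
  # non-overlapping windows (step = window) make window significances
  # independent Bernoulli(alpha) draws; the max-run null then follows a
  # Markov-chain recursion, used here as the analytic oracle
  prob_run_gt <- function(L, n, p) {
    # probability that a Bernoulli(p) sequence of length n has a success
    # run longer than L (dynamic program over run-ending states)
    state <- c(1, rep(0, L)) # state k = current trailing run length k
    done <- 0
    for (i in seq_len(n)) {
      new <- rep(0, L + 1)
      for (k in 0:(L - 1)) {
        new[1] <- new[1] + state[k + 1] * (1 - p)
        new[k + 2] <- new[k + 2] + state[k + 1] * p
      }
      new[1] <- new[1] + state[L + 1] * (1 - p)
      done <- done + state[L + 1] * p
      state <- new
    }
    done
  }
  cfg <- small_config(n_sequences = 25, seed = 61)
  tr <- generate_behavior(cfg)
  spec <- neuron_spec("cal1", "null", gain = 0, baseline_rate = 12)
  sp <- generate_spikes(spec, tr, seed = 13)
  seg <- tibble(segment = "fix", anchor_event = "t_fix_on", from = -1, to = 1.8)
  suppressWarnings(
    cal <- calibrate_run_threshold(sp, tr, n_shuffles = 400, window = 0.2,
                                   step = 0.2, segments = seg, seed = 3)
  )
  n_win <- floor((2.8 - 0.2) / 0.2) + 1
  for (L in 1:2) {
    expect_lt(abs(mean(cal$runs > L) - prob_run_gt(L, n_win, 0.05)), 0.04)
  }
  # the calibrated criterion controls false positives by construction
  expect_lt(cal$exceed_fraction, 0.05)
  expect_error(calibrate_run_threshold(sp, tr, n_shuffles = 0), "positive")
})
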