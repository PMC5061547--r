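test_that("behavior generator honors sequence bookkeeping and determinism", {
  cfg3 <- generator_config(interest_rates = 1.5,
                           length_probs = list(c(`3` = 1)),
                           n_sequences = 10, error_rate = 0,
                           neurons = default_roster(2), seed = 5)
  tr <- generate_behavior(cfg3)
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$choice[tr$step == 3] == "spend"))
  expect_true(all(tr$choice[tr$step < 3] == "save"))
  expect_silent(validate_trials(tr))
  # same config and seed -> identical table
  expect_identical(tr, generate_behavior(cfg3))
  expect_error(
    generator_config(length_probs = list(c(`2` = 0)), interest_rates = 1),
    "zero mass"
  )
})

test_that("realized sequence lengths follow the configured distribution", {
  cfg <- generator_config(interest_rates = 1,
                          length_probs = list(c(`2` = 0.3, `4` = 0.5, `6` = 0.2)),
                          n_sequences = 1000, error_rate = 0.05,
                          neurons = default_roster(2), seed = 13)
  tr <- generate_behavior(cfg)
  lens <- tr %>% filter(!error) %>% distinct(sequence_id, sequence_length) %>%
    pull(sequence_length)
  # mean within 3 SE of 3.8 (multinomial SE of the mean)
  mu <- sum(c(2, 4, 6) * c(0.3, 0.5, 0.2))
  sde <- sqrt(sum(c(2, 4, 6)^2 * c(0.3, 0.5, 0.2)) - mu^2) / sqrt(1000)
  expect_lt(abs(mean(lens) - mu), 3 * sde)
  # chi-square goodness of fit not rejected at alpha = 0.01
  obs <- table(factor(lens, levels = c(2, 4, 6)))
  expect_gt(chisq.test(obs, p = c(0.3, 0.5, 0.2))$p.value, 0.01)
  # error trials carry no choice and do not advance the step
  errs <- filter(tr, error)
  expect_gt(nrow(errs), 0)
  expect_true(all(is.na(errs$choice)))
  expect_true(all(is.na(errs$rt_key)))
})

test_that("untuned neurons fire at baseline in every period", {
  cfg <- small_config(n_sequences = 70, seed = 21)
  tr <- generate_behavior(cfg)
  spec <- spec_of("null", gain = 0, id = "nullneuron", periods = "delay")
  sp <- generate_spikes(spec, tr, seed = 2)
  wc <- extract_window_counts(sp, tr)
  agg <- wc %>% group_by(period) %>%
    summarise(total = sum(count), tt = sum(duration), n = dplyr::n())
  # mean rate within 3 Poisson SE of baseline in each period (>200 trials)
  expect_true(all(agg$n >= 200))
  for (i in seq_len(nrow(agg))) {
    lam <- spec$baseline_rate * agg$tt[i]
    expect_lt(abs(agg$total[i] - lam), 3 * sqrt(lam))
  }
})

test_that("adaptive tuning scales progress slopes by inverse length", {
  cfg <- generator_config(interest_rates = 1,
                          length_probs = list(c(`2` = 0.5, `5` = 0.5)),
                          n_sequences = 400, error_rate = 0,
                          neurons = default_roster(2), seed = 8)
  tr <- generate_behavior(cfg)
  spec <- spec_of("adaptive_progress", gain = 15, id = "ad1")
  wc <- simulate_window_counts(spec, tr, seed = 3)
  dat <- wc %>% filter(period == "delay") %>%
    left_join(select(tr, trial_index, step, sequence_length, error),
              by = "trial_index") %>%
    filter(!error)
  s2 <- coef(lm(rate ~ step, data = filter(dat, sequence_length == 2)))[2]
  s5 <- coef(lm(rate ~ step, data = filter(dat, sequence_length == 5)))[2]
  # slope ratio approx 5/2 for a fully adaptive neuron
  expect_lt(abs(s2 / s5 - 2.5), 0.5)
})

test_that("window-count shortcut matches the spike-time path in distribution", {
  cfg <- small_config(n_sequences = 60, seed = 31)
  tr <- generate_behavior(cfg)
  spec <- spec_of("nonadaptive_progress", gain = 3, id = "cmp1",
                  periods = c("cue", "delay"))
  wc_direct <- simulate_window_counts(spec, tr, seed = 5, include_errors = FALSE)
  wc_spikes <- extract_window_counts(generate_spikes(spec, tr, seed = 6), tr)
  cmp <- wc_direct %>%
    group_by(period) %>% summarise(m1 = mean(rate)) %>%
    left_join(wc_spikes %>% group_by(period) %>% summarise(m2 = mean(rate)),
              by = "period")
  # per-period mean rates agree within 3 SE of the Poisson difference
  n <- sum(!tr$error)
  for (i in seq_len(nrow(cmp))) {
    pooled_se <- sqrt(cmp$m1[i] + cmp$m2[i]) / sqrt(n)
    expect_lt(abs(cmp$m1[i] - cmp$m2[i]), 4 * pooled_se + 0.5)
  }
})

test_that("free_only tuning vanishes on imperative trials", {
  cfg <- generator_config(interest_rates = 1.5,
                          length_probs = list(c(`2` = 0.3, `4` = 0.4, `6` = 0.3)),
                          n_sequences = 60, error_rate = 0,
                          neurons = default_roster(2), seed = 17)
  free <- generate_behavior(cfg, "free")
  imp <- generate_behavior(cfg, "imperative", match_to = free)
  expect_equal(
    sort(unique(imp$sequence_length)), sort(unique(free$sequence_length))
  )
  spec <- spec_of("adaptive_progress", gain = 14, id = "fo1", free_only = TRUE)
  fit_task <- function(trials) {
    wc <- simulate_window_counts(spec, trials, seed = 9)
    fit_model(wc, trials, "eq2") %>% filter(period == "delay")
  }
  expect_lt(fit_task(free)$p_value, 0.001)
  expect_gt(fit_task(imp)$p_value, 0.01)
})

test_that("datasets round-trip through disk and honor id uniqueness", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_sequences = 8, neurons = default_roster(5), seed = 19)
  ds <- generate_dataset(cfg, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back$neurons), 5)
  expect_equal(back$neurons$tuning, cfg$neurons$tuning)
  expect_equal(as.data.frame(back$trials), as.data.frame(ds$trials))
  expect_equal(back$spikes$time, ds$spikes$time, tolerance = 1e-12)
  expect_equal(back$manifest$seed, cfg$seed)
  # same config + seed -> byte-identical files
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir2)
  for (f in c("trials.csv", "spikes.csv", "neurons.csv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
  expect_error(
    write_dataset(withr::local_tempdir(), ds$trials, ds$spikes,
                  ds$neurons[c(1, 1), ]),
    "duplicate"
  )
})
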