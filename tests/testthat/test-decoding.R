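# activity builder for decoding tests: per-neuron z with a chosen mapping
# from progress group to mean, plus Gaussian noise
decoding_activity <- function(trials, n_neurons, group_means = c(0, 0, 0),
                              noise = 1, seed = 1, period = "delay") {
  ok <- filter(trials, !error)
  qs <- quantile(ok$step, c(1 / 3, 2 / 3), type = 7)
  grp <- 1L + findInterval(ok$step, qs, left.open = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_neurons), function(i) {
    tibble(neuron_id = sprintf("d%03d", i), session_id = ok$session_id,
           trial_index = ok$trial_index, period = period,
           z = group_means[grp] + rnorm(nrow(ok), 0, noise))
  })
}

decoding_trials <- function(n_sequences = 40, seed = 81) {
  cfg <- generator_config(interest_rates = 1,
                          length_probs = list(c(`4` = 0.3, `5` = 0.3, `6` = 0.4)),
                          n_sequences = n_sequences, error_rate = 0,
                          neurons = default_roster(2), seed = seed)
  generate_behavior(cfg)
}

test_that("tercile grouping and inclusion rules follow the contract", {
  # equal counts of progress values 1..6 -> groups {1,2}, {3,4}, {5,6}
  act <- tibble(neuron_id = "t1", session_id = "s",
                trial_index = 0:17, period = "delay", z = rnorm(18))
  tr <- tibble(session_id = "s", trial_index = 0:17,
               step = rep(1:6, each = 3), error = FALSE)
  pop <- build_pseudopopulation(bind_rows(act, mutate(act, neuron_id = "t2")),
                                tr, min_trials = 2, n_matchings = 1)
  grp <- pop$values %>% filter(neuron_id == "t1")
  expect_equal(lengths(grp$z), c(6, 6, 6))
  # boundary values go to the lower group: quantiles at 2.67/4.33 put
  # steps {1,2} low, {3,4} mid, {5,6} high
  expect_equal(pop$group_sizes$m, c(6, 6, 6))
  # a neuron lacking the per-group minimum is excluded
  act4 <- tibble(neuron_id = "few", session_id = "s",
                 trial_index = c(0:3, 6:11, 12:17), period = "delay",
                 z = rnorm(16))
  pop2 <- build_pseudopopulation(bind_rows(act, mutate(act, neuron_id = "t2"),
                                           act4),
                                 tr, min_trials = 5, n_matchings = 1)
  expect_false("few" %in% pop2$neurons$neuron_id)
  # quartile grouping is supported
  pop4 <- build_pseudopopulation(bind_rows(act, mutate(act, neuron_id = "t2")),
                                 tr, n_groups = 4, min_trials = 2,
                                 n_matchings = 1)
  expect_equal(pop4$n_groups, 4)
  expect_equal(nrow(pop4$group_sizes), 4)
  expect_error(build_pseudopopulation(act, tr, min_trials = 100),
               "fewer than 2 neurons")
})

test_that("nearest-neighbor decoder matches a brute-force oracle", {
  brute_nn <- function(X, y) {
    pred <- vapply(seq_len(nrow(X)), function(i) {
      d <- vapply(seq_len(nrow(X)), function(j) {
        if (i == j) Inf else sqrt(sum((X[i, ] - X[j, ])^2))
      }, numeric(1))
      y[which.min(d)]
    }, numeric(1))
    100 * mean(pred == y)
  }
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    # occasional exact duplicates exercise deterministic tie handling
    if (rep %% 5 == 0 && n > 3) X[2, ] <- X[1, ]
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(saveseq:::nn_loo_accuracy(X, y), brute_nn(X, y))
  }
})

test_that("decoding hits chance on null data and ceiling on separable data", {
  tr <- decoding_trials()
  # null population: accuracy ~ chance within the binomial CI
  act0 <- decoding_activity(tr, 15, c(0, 0, 0), seed = 6)
  pop0 <- build_pseudopopulation(act0, tr, n_matchings = 25, seed = 2)
  res0 <- decode(pop0)
  n_dec <- sum(pop0$group_sizes$m) * 25
  ci_half <- 3 * sqrt(1 / 3 * 2 / 3 / n_dec) * 100
  expect_lt(abs(res0$mean - 100 / 3), ci_half + 2)
  # disjoint group activity ranges: perfect classification
  act1 <- decoding_activity(tr, 20, c(-10, 0, 10), noise = 0.1, seed = 7)
  pop1 <- build_pseudopopulation(act1, tr, n_matchings = 10, seed = 3)
  expect_equal(decode(pop1)$mean, 100)
  # the linear max-margin classifier agrees on the separable case
  expect_equal(decode(pop1, "linear_max_margin")$mean, 100)
  expect_equal(decode(pop1, cv = "split")$mean, 100)
})

test_that("shuffle null sits at chance and flags a real code", {
  tr <- decoding_trials()
  act <- decoding_activity(tr, 12, c(-1.2, 0, 1.2), noise = 1, seed = 8)
  pop <- build_pseudopopulation(act, tr, n_matchings = 20, seed = 4)
  res <- shuffle_null(pop, decode(pop), n_iterations = 200)
  expect_lt(abs(mean(res$null_accuracies) - 100 / 3), 2)
  expect_gt(res$mean, mean(res$null_accuracies))
  expect_lt(res$p_vs_null, 0.01)
  expect_warning(shuffle_null(pop, decode(pop), n_iterations = 50), "power")
})

test_that("accuracy grows with population size for tuned neurons", {
  tr <- decoding_trials()
  act <- decoding_activity(tr, 24, c(-0.8, 0, 0.8), noise = 1.2, seed = 9)
  curve <- neuron_count_curve(act, tr, sizes = c(1, 4, 10, 24),
                              iterations = 12, n_matchings = 2, seed = 5)
  expect_equal(nrow(curve), 4)
  ct <- cor.test(curve$size, curve$accuracy_mean, method = "spearman")
  expect_gt(ct$estimate, 0)
  # single tuned neuron still beats chance in expectation
  expect_gt(curve$accuracy_mean[curve$size == 1], 100 / 3 - 3)
  # the full-roster point agrees with a direct full decode
  pop <- build_pseudopopulation(act, tr, n_matchings = 10, seed = 11)
  full <- decode(pop)$mean
  expect_lt(abs(curve$accuracy_mean[curve$size == 24] - full), 6)
  expect_error(neuron_count_curve(act, tr, sizes = 0), "sizes must be")
})

test_that("subset decoding separates significant from non-significant rosters", {
  cfg <- generator_config(interest_rates = 1,
                          length_probs = list(c(`4` = 0.3, `5` = 0.3, `6` = 0.4)),
                          n_sequences = 50, error_rate = 0,
                          neurons = default_roster(2), seed = 83)
  tr <- generate_behavior(cfg)
  # mixed roster: 40% strongly tuned, the rest null
  roster <- purrr::map_dfr(1:50, function(i) {
    neuron_spec(sprintf("s%03d", i),
                if (i <= 20) "nonadaptive_progress" else "null",
                gain = if (i <= 20) 3 else 0, target_periods = "delay",
                region = if (i %% 3 == 0) "centromedial" else "basolateral")
  })
  wcs <- purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    simulate_window_counts(roster[i, ], tr, seed = 500 + i,
                           include_errors = FALSE)
  })
  act <- znormalize(wcs)
  fits <- fit_model(filter(wcs, period == "delay"), tr, "eq2")
  sub <- subset_analysis(act, tr, fits, roster, subset_size = 15,
                         iterations = 40, n_matchings = 1, seed = 6)
  bc <- sub$by_category
  acc <- setNames(bc$accuracy_mean, bc$category)
  expect_gt(acc["significant"], acc["nonsignificant"])
  rs <- suppressWarnings(wilcox.test(
    sub$subsets$accuracy[sub$subsets$category == "significant"],
    sub$subsets$accuracy[sub$subsets$category == "nonsignificant"]
  ))
  expect_lt(rs$p.value, 0.01)
  # accuracy rises with the subset's mean rectified progress slope
  cf <- sub$covariate_fit
  expect_gt(cf$estimate[cf$term == "mean_abs_slope"], 0)
  expect_lt(cf$p_value[cf$term == "mean_abs_slope"], 0.05)
})
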