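suppressMessages({
  library(dplyr)
  library(purrr)
})

# small, fast config used across tests; one interest rate unless asked
small_config <- function(n_sequences = 20, error_rate = 0,
                         neurons = default_roster(4), seed = 7,
                         two_rates = FALSE) {
  if (two_rates) {
    generator_config(n_sequences = n_sequences, error_rate = error_rate,
                     neurons = neurons, seed = seed)
  } else {
    generator_config(
      interest_rates = 1.5,
      length_probs = list(c(`2` = 0.2, `3` = 0.25, `4` = 0.25, `5` = 0.2,
                            `6` = 0.1)),
      n_sequences = n_sequences, error_rate = error_rate,
      neurons = neurons, seed = seed
    )
  }
}

# one-line neuron spec helpers
spec_of <- function(tuning, gain = 10, periods = "delay", id = "nx", ...) {
  neuron_spec(id, tuning = tuning, gain = gain, target_periods = periods, ...)
}

# analytic activity table (no spike noise): z = f(step, length) per trial,
# replicated over `n_neurons` identical neurons in one period
analytic_activity <- function(trials, f, n_neurons = 1, period = "delay") {
  ok <- dplyr::filter(trials, !error)
  purrr::map_dfr(seq_len(n_neurons), function(i) {
    tibble::tibble(
      neuron_id = sprintf("a%02d", i),
      session_id = ok$session_id, trial_index = ok$trial_index,
      period = period, z = f(ok$step, ok$sequence_length)
    )
  })
}

# direct OLS via normal equations: the independent oracle for fits
normal_equations <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  t <- b / se
  list(beta = drop(b), se = se, p = 2 * pt(-abs(t), df),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
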