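#' Reward accumulated over consecutive save choices
#'
#' Reward magnitude grows over a saving sequence as a geometric series: on the
#' n-th trial of a sequence the available amount is
#' \eqn{x_n = b \sum_{i=0}^{n-1} q^i}, with base rate \eqn{b} (ml) and interest
#' rate \eqn{q}. With the task's canonical parameters (b = 0.11 ml, q = 1.5)
#' the second trial of a sequence is worth 0.275 ml and the third 0.5225 ml.
#'
#' @param step trial position within the saving sequence (integer >= 1);
#'   vectorized.
#' @param base_rate base reward magnitude b in ml (> 0).
#' @param interest_rate interest rate q (> 0); q = 1 gives linear accumulation.
#' @return reward magnitude in ml, same length as `step`.
#' @examples
#' accumulate_reward(2, 0.11, 1.5) # 0.275
#' accumulate_reward(1:7, 0.11, 1.5)
#' @export
accumulate_reward <- function(step, base_rate, interest_rate) {
  if (length(step) == 0) return(numeric(0))
  if (any(is.na(step)) || any(step < 1) || any(step != round(step))) {
    abort("`step` must be a positive integer (sequence position)")
  }
  if (!is.numeric(base_rate) || any(base_rate <= 0)) abort("`base_rate` must be > 0")
  if (!is.numeric(interest_rate) || any(interest_rate <= 0)) {
    abort("`interest_rate` must be > 0")
  }
  n <- max(length(step), length(base_rate), length(interest_rate))
  step <- rep_len(step, n)
  b <- rep_len(base_rate, n)
  q <- rep_len(interest_rate, n)
  ifelse(abs(q - 1) < 1e-12, b * step, b * (q^step - 1) / (q - 1))
}

#' Subjective value table for a saving sequence
#'
#' Builds the per-step spend and save values implied by an animal's observed
#' sequence-length preferences under one interest rate. The spend value at step
#' i is the probability of producing a sequence of length i times the objective
#' reward magnitude at that step (`SVspend_i = P_i * M_i`); the save value at
#' step n is the average spend value over all future steps,
#' `SVsave_n = mean(SVspend_{n+1..m})`, with m the maximal observed length.
#' At step m there is no future spend opportunity and `sv_save` is 0.
#'
#' @param length_frequencies numeric vector of probabilities over sequence
#'   lengths 1..m (element i = probability of a length-i sequence). Must be
#'   non-negative and sum to 1 (tolerance 1e-6).
#' @param base_rate base reward magnitude in ml.
#' @param interest_rate interest rate q.
#' @return a tibble of class `sv_table` with columns `step`, `p`, `reward_ml`,
#'   `sv_spend`, `sv_save` and attributes `base_rate`, `interest_rate`, `m`.
#' @examples
#' spend_value_table(c(0, 0.5, 0, 0.5), base_rate = 0.1, interest_rate = 1)
#' @export
spend_value_table <- function(length_frequencies, base_rate, interest_rate) {
  p <- as.numeric(length_frequencies)
  if (length(p) == 0 || all(p == 0)) {
    abort("`length_frequencies` must contain positive mass")
  }
  if (any(p < 0)) abort("`length_frequencies` must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) abort("`length_frequencies` must sum to 1")
  m <- length(p)
  reward <- accumulate_reward(seq_len(m), base_rate, interest_rate)
  sv_spend <- p * reward
  sv_save <- vapply(seq_len(m), function(n) {
    if (n >= m) 0 else mean(sv_spend[(n + 1):m])
  }, numeric(1))
  out <- tibble(
    step = seq_len(m), p = p, reward_ml = reward,
    sv_spend = sv_spend, sv_save = sv_save
  )
  structure(out,
    class = c("sv_table", class(out)),
    base_rate = base_rate, interest_rate = interest_rate, m = m
  )
}

#' Save value at a sequence position
#'
#' The subjective value of saving at position n: the mean spend value
#' obtainable over future steps n+1..m of the table.
#'
#' @param table an `sv_table` from [spend_value_table()].
#' @param position sequence position n, with 1 <= n <= m-1.
#' @return scalar save value.
#' @export
save_value <- function(table, position) {
  stopifnot(inherits(table, "sv_table"))
  m <- attr(table, "m")
  if (length(position) != 1 || position < 1 || position >= m) {
    abort("`position` must satisfy 1 <= position <= m - 1 (no future beyond m)")
  }
  mean(table$sv_spend[(position + 1):m])
}

#' Empirical subjective value tables from behavior
#'
#' Estimates, separately for each interest rate in the trial table, the
#' sequence-length probabilities P_i as raw relative frequencies of completed
#' sequence lengths (no smoothing; unobserved lengths get probability 0), and
#' derives the corresponding spend/save value tables.
#'
#' @param trials a trial tibble (see [generate_behavior()] for the schema).
#' @return a tibble with one row per (interest_rate, step) and columns as in
#'   [spend_value_table()], plus `interest_rate`.
#' @export
spend_value_tables <- function(trials) {
  trials %>%
    filter(!.data$error) %>%
    distinct(.data$interest_rate, .data$base_rate, .data$sequence_id,
             .data$sequence_length) %>%
    group_by(.data$interest_rate, .data$base_rate) %>%
    summarise(
      tab = list({
        m <- max(.data$sequence_length)
        p <- tabulate(.data$sequence_length, nbins = m) / length(.data$sequence_length)
        spend_value_table(p, .data$base_rate[1], .data$interest_rate[1])
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest("tab") %>%
    select(-"base_rate")
}

#' Spend choice probability as a function of sequence progress
#'
#' For each interest rate, computes at every step s the probability that the
#' animal spends given that its sequence reached step s: the number of spend
#' choices at step s divided by the number of sequences reaching step s (a
#' discrete hazard). The value at the maximal observed step is 1.
#'
#' @param trials trial tibble; error trials are ignored.
#' @return tibble with columns `interest_rate`, `step`, `n_reaching`,
#'   `n_spend`, `p_spend`.
#' @export
choice_probability_by_progress <- function(trials) {
  ok <- trials %>% filter(!.data$error)
  if (nrow(ok) == 0) abort("no correct trials in input")
  ok %>%
    group_by(.data$interest_rate, .data$step) %>%
    summarise(
      n_reaching = dplyr::n(),
      n_spend = sum(.data$choice == "spend"),
      .groups = "drop"
    ) %>%
    mutate(p_spend = .data$n_spend / .data$n_reaching) %>%
    arrange(.data$interest_rate, .data$step)
}

#' Reaction-time regression on task variables
#'
#' Multiple linear regression of session-z-normalized reaction times on
#' sequence progress and configurable task covariates (save/spend choice,
#' sequence length, a free-vs-imperative task dummy, and the
#' progress-by-inverse-length interaction that captures adaptation of reaction
#' times to the planned sequence length). Reaction times are z-normalized
#' within each session (subtract session mean, divide by session sd) before
#' pooling, so coefficients are comparable across sessions.
#'
#' @param trials trial tibble (may pool several sessions and both tasks).
#' @param rt_field which latency to analyze: `"key"` (touch-key release) or
#'   `"saccade"` (cue-to-fixation saccade).
#' @param covariates character subset of
#'   `c("progress", "choice", "length", "task", "progress_x_invlength")`.
#' @return an object of class `rt_fit` (a wrapped OLS fit) with
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
rt_regression <- function(trials,
                          rt_field = c("key", "saccade"),
                          covariates = c("progress", "choice", "length",
                                         "progress_x_invlength")) {
  rt_field <- match.arg(rt_field)
  rt_col <- if (rt_field == "key") "rt_key" else "rt_saccade"
  dat <- trials %>%
    filter(!.data$error, !is.na(.data[[rt_col]])) %>%
    group_by(.data$session_id) %>%
    mutate(rt_z = {
      s <- stats::sd(.data[[rt_col]])
      if (is.na(s) || s == 0) (.data[[rt_col]] - mean(.data[[rt_col]]))
      else (.data[[rt_col]] - mean(.data[[rt_col]])) / s
    }) %>%
    ungroup()
  X <- cbind(`(Intercept)` = rep(1, nrow(dat)))
  if ("progress" %in% covariates) X <- cbind(X, progress = dat$step)
  if ("choice" %in% covariates) X <- cbind(X, choice_spend = as.numeric(dat$choice == "spend"))
  if ("length" %in% covariates) X <- cbind(X, seq_length = dat$sequence_length)
  if ("task" %in% covariates) X <- cbind(X, task_free = as.numeric(dat$task_type == "free"))
  if ("progress_x_invlength" %in% covariates) {
    X <- cbind(X, progress_x_invlength = dat$step / dat$sequence_length)
  }
  if (nrow(dat) <= ncol(X)) abort("fewer trials than regression parameters")
  fit <- ols_fit(X, dat$rt_z)
  if (isTRUE(fit$degenerate)) abort("rank-deficient reaction-time design")
  structure(list(fit = fit, rt_field = rt_field, n = fit$n), class = "rt_fit")
}

#' @exportS3Method generics::tidy
tidy.rt_fit <- function(x, ...) {
  f <- x$fit
  tibble(
    term = f$term, estimate = unname(f$estimate),
    std_estimate = unname(f$std_estimate), std.error = unname(f$se),
    p.value = unname(f$p_value)
  )
}

#' @exportS3Method generics::glance
glance.rt_fit <- function(x, ...) {
  tibble(r.squared = x$fit$r_squared, adj.r.squared = x$fit$adj_r_squared,
         p.value = x$fit$model_p, nobs = x$n)
}

#' @export
print.rt_fit <- function(x, ...) {
  cat("<rt_fit>", x$rt_field, "reaction times,", x$n, "trials\n")
  print(tidy(x))
  invisible(x)
}
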