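# per-trial tuning drive f(trial) for a neuron spec; reward_expectation is
# handled by a per-period ramp with f = 1
tuning_drive <- function(spec, trials) {
  step <- trials$step
  len <- trials$sequence_length
  f <- switch(spec$tuning,
    adaptive_progress = step / len,
    nonadaptive_progress = step,
    partial_adaptive = spec$adaptation_weight * step / len +
      (1 - spec$adaptation_weight) * step / max(step),
    reward_magnitude = {
      q <- trials$interest_rate
      b <- trials$base_rate
      ifelse(abs(q - 1) < 1e-12, b * step, b * (q^step - 1) / (q - 1))
    },
    elapsed_time = trials$elapsed / max(trials$elapsed),
    step_tuned = as.numeric(step %in% spec$step_centers[[1]]),
    reward_expectation = rep(1, nrow(trials)),
    null = rep(0, nrow(trials))
  )
  if (spec$free_only) f <- f * as.numeric(trials$task_type == "free")
  f * ifelse(trials$error, spec$error_attenuation, 1)
}

# modulation (Hz above baseline) of one neuron in one named period
period_modulation <- function(spec, trials, period) {
  if (!period %in% spec$target_periods[[1]]) return(rep(0, nrow(trials)))
  ramp <- if (spec$tuning == "reward_expectation") period_ramp[[period]] else 1
  spec$gain * ramp * tuning_drive(spec, trials)
}

#' Generate an inhomogeneous Poisson spike train for one neuron
#'
#' Spike times (seconds from trial start) are drawn from a piecewise-constant
#' rate: the baseline rate everywhere in the trial, plus `gain * f(trial)`
#' inside each of the neuron's target periods, where `f` is determined by the
#' tuning model (see [neuron_spec()]). Negative rates are clipped at zero with
#' a warning. The phasic modulation is a constant rate increment across each
#' whole target period.
#'
#' @param spec one-row neuron spec tibble from [neuron_spec()].
#' @param trials trial tibble (error trials included; their modulation is
#'   attenuated by `error_attenuation`).
#' @param seed integer seed for this neuron's substream; defaults to a hash of
#'   the neuron id so rosters are reproducible under edits.
#' @param periods period definition tibble ([task_periods()]).
#' @return tibble with columns `neuron_id`, `session_id`, `trial_index`,
#'   `time` (s from trial start), sorted by trial then time.
#' @export
generate_spikes <- function(spec, trials, seed = 1, periods = task_periods()) {
  stopifnot(nrow(spec) == 1)
  set.seed(substream_seed(spec$neuron_id, seed))
  n <- nrow(trials)
  tp <- periods %>% filter(.data$period %in% spec$target_periods[[1]])
  # interval bounds per trial for each target period, clipped to the trial
  starts <- ends <- mods <- list()
  for (i in seq_len(nrow(tp))) {
    a <- trials[[tp$anchor_event[i]]] + tp$start_offset[i]
    starts[[i]] <- pmax(a, 0)
    ends[[i]] <- pmin(a + tp$duration[i], trials$t_end)
    mods[[i]] <- period_modulation(spec, trials, tp$period[i])
  }
  # breakpoints per trial: trial bounds plus all target-period bounds
  bounds <- cbind(0, trials$t_end,
                  do.call(cbind, c(starts, ends)) %||% NULL)
  bounds <- t(apply(bounds, 1, sort))
  n_seg <- ncol(bounds) - 1
  seg_start <- bounds[, -ncol(bounds), drop = FALSE]
  seg_end <- bounds[, -1, drop = FALSE]
  mid <- (seg_start + seg_end) / 2
  rate <- matrix(spec$baseline_rate, n, n_seg)
  for (i in seq_along(starts)) {
    inside <- mid >= starts[[i]] & mid < ends[[i]]
    rate <- rate + inside * mods[[i]]
  }
  if (any(rate < 0)) {
    warn(paste0("negative rate clipped at 0 for neuron ", spec$neuron_id))
    rate <- pmax(rate, 0)
  }
  seg_len <- pmax(seg_end - seg_start, 0)
  counts <- rpois(length(rate), as.vector(rate * seg_len))
  trial_of_seg <- rep(seq_len(n), times = n_seg)
  times <- runif(sum(counts)) *
    rep(as.vector(seg_len), counts) + rep(as.vector(seg_start), counts)
  out <- tibble(
    neuron_id = spec$neuron_id,
    session_id = rep(trials$session_id[trial_of_seg], counts),
    trial_index = rep(trials$trial_index[trial_of_seg], counts),
    time = times
  ) %>% arrange(.data$trial_index, .data$time)
  out
}

#' Draw fixed-window spike counts directly from the rate model
#'
#' For analyses that only use the fixed task-period windows, the spike count
#' in a window is Poisson with mean equal to the window-integrated rate; this
#' generator draws those counts directly, which is distributionally identical
#' to drawing spike times with [generate_spikes()] and counting them, but much
#' faster for large rosters. Use [generate_spikes()] whenever sub-window
#' timing matters (e.g. sliding-window analyses).
#'
#' @inheritParams generate_spikes
#' @param include_errors keep error trials (default TRUE; downstream analyses
#'   filter as needed).
#' @return a windowed-counts tibble: `neuron_id`, `session_id`, `trial_index`,
#'   `period`, `count`, `duration`, `rate`.
#' @export
simulate_window_counts <- function(spec, trials, seed = 1,
                                   periods = task_periods(),
                                   include_errors = TRUE) {
  stopifnot(nrow(spec) == 1)
  set.seed(substream_seed(paste0(spec$neuron_id, "-wc"), seed))
  if (!include_errors) trials <- filter(trials, !.data$error)
  purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    p <- periods[i, ]
    mu <- pmax(spec$baseline_rate + period_modulation(spec, trials, p$period), 0)
    tibble(
      neuron_id = spec$neuron_id,
      session_id = trials$session_id,
      trial_index = trials$trial_index,
      period = p$period,
      count = rpois(nrow(trials), mu * p$duration),
      duration = p$duration
    )
  }) %>%
    mutate(rate = .data$count / .data$duration)
}

#' Generate spike trains for a whole roster
#'
#' @param neurons roster tibble of [neuron_spec()] rows.
#' @param trials trial tibble.
#' @param seed master seed; each neuron uses a substream hashed from its id.
#' @param periods period definitions.
#' @return row-bound spikes tibble across neurons.
#' @export
generate_roster_spikes <- function(neurons, trials, seed = 1,
                                   periods = task_periods()) {
  purrr::map_dfr(seq_len(nrow(neurons)), function(i) {
    generate_spikes(neurons[i, ], trials, seed = seed, periods = periods)
  })
}
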