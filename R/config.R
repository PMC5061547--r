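#' Ground-truth tuning specification for a synthetic neuron
#'
#' Describes how one synthetic neuron's firing rate is modulated by the task.
#' Inside each target period the rate is `baseline_rate + gain * f(trial)`,
#' where `f` depends on the tuning model:
#' \describe{
#'   \item{adaptive_progress}{`step / sequence_length` — progress normalized by
#'     the forthcoming sequence length (range-adapted code).}
#'   \item{nonadaptive_progress}{`step` — raw cumulative correct-trial count.}
#'   \item{partial_adaptive}{`w * step/length + (1-w) * step/max_step` with
#'     `w = adaptation_weight` mixing normalized and raw progress.}
#'   \item{reward_magnitude}{accumulated reward in ml at the current step.}
#'   \item{elapsed_time}{cumulative trials within the sequence including
#'     error trials, scaled by 1/max.}
#'   \item{step_tuned}{indicator of membership in `step_centers`.}
#'   \item{reward_expectation}{within-trial ramp toward outcome, identical
#'     across steps (gradual but progress-blind control).}
#'   \item{null}{no modulation.}
#' }
#'
#' @param neuron_id identifier string.
#' @param tuning one of the tuning models above.
#' @param baseline_rate baseline firing rate in Hz.
#' @param gain modulation gain in Hz (negative for decreasing responses).
#' @param adaptation_weight mixing weight w in `[0, 1]` for partial_adaptive.
#' @param target_periods task periods carrying the modulation; subset of
#'   `c("pre_fixation", "fixation", "cue", "delay", "outcome")`.
#' @param free_only if TRUE the tuning is silenced on imperative trials.
#' @param error_attenuation multiplier in `[0, 1]` applied to the gain on
#'   error trials (1 = no attenuation).
#' @param region categorical anatomical label carried as metadata.
#' @param step_centers integer steps at which a step_tuned neuron fires.
#' @return one-row tibble (a neuron roster is built by row-binding specs).
#' @export
neuron_spec <- function(neuron_id,
                        tuning = c("adaptive_progress", "nonadaptive_progress",
                                   "partial_adaptive", "reward_magnitude",
                                   "elapsed_time", "step_tuned",
                                   "reward_expectation", "null"),
                        baseline_rate = 8,
                        gain = 10,
                        adaptation_weight = 1,
                        target_periods = c("fixation", "cue", "delay"),
                        free_only = FALSE,
                        error_attenuation = 1,
                        region = c("basolateral", "centromedial"),
                        step_centers = integer()) {
  tuning <- match.arg(tuning)
  region <- match.arg(region)
  stopifnot(baseline_rate >= 0, adaptation_weight >= 0, adaptation_weight <= 1,
            error_attenuation >= 0, error_attenuation <= 1)
  bad <- setdiff(target_periods, c("pre_fixation", "fixation", "cue", "delay", "outcome"))
  if (length(bad)) abort(paste("unknown target periods:", paste(bad, collapse = ", ")))
  tibble(
    neuron_id = as.character(neuron_id), tuning = tuning,
    baseline_rate = baseline_rate, gain = gain,
    adaptation_weight = adaptation_weight,
    target_periods = list(target_periods),
    free_only = free_only, error_attenuation = error_attenuation,
    region = region, step_centers = list(as.integer(step_centers))
  )
}

#' Default mixed neuron roster
#'
#' A roster spanning all tuning models and both amygdala region labels, used
#' as the default population for end-to-end runs. Gains are chosen so that
#' each tuning produces comparable peak modulation above an 8 Hz baseline.
#'
#' @param n_neurons total roster size (divided about evenly across tunings).
#' @param seed integer seed controlling region assignment.
#' @return tibble of neuron specs.
#' @export
default_roster <- function(n_neurons = 60, seed = 1) {
  tunings <- c("adaptive_progress", "nonadaptive_progress", "partial_adaptive",
               "reward_magnitude", "elapsed_time", "step_tuned",
               "reward_expectation", "null")
  set.seed(seed)
  purrr::map_dfr(seq_len(n_neurons), function(i) {
    tun <- tunings[(i - 1) %% length(tunings) + 1]
    neuron_spec(
      neuron_id = sprintf("n%03d", i), tuning = tun,
      baseline_rate = 8,
      gain = switch(tun, nonadaptive_progress = 2.5, reward_magnitude = 6,
                    step_tuned = 12, 10),
      adaptation_weight = if (tun == "partial_adaptive") 0.5 else 1,
      free_only = tun %in% c("adaptive_progress", "nonadaptive_progress") &&
        i %% 2 == 0,
      error_attenuation = 0.3,
      region = sample(c("basolateral", "centromedial"), 1, prob = c(0.7, 0.3)),
      step_centers = if (tun == "step_tuned") sample(2:5, 1) else integer()
    )
  })
}

#' Generator configuration for a synthetic saving-task experiment
#'
#' Collects the task, behavior, reaction-time, and neuron parameters that the
#' generator uses. Defaults emulate the published task: base rate 0.11 ml,
#' two interest-rate blocks with length preferences shifting toward longer
#' sequences at higher interest, roughly 12 s trials with the five standard
#' analysis periods, and key reaction times that decrease with progress and
#' adapt to planned sequence length.
#'
#' @param interest_rates numeric vector of interest rates q, one block each.
#' @param length_probs list (one element per interest rate) of named numeric
#'   vectors: names are sequence lengths, values their probabilities.
#' @param n_sequences sequences generated per interest-rate block.
#' @param error_rate per-trial probability of an error (step not incremented).
#' @param base_rate base reward magnitude in ml.
#' @param timing named list of durations in seconds: `pre_fix`, `fixation`
#'   (fixation-spot onset to cue onset), `delay` (choice to release-go cue),
#'   `outcome`, `iti`.
#' @param rt named list of reaction-time model coefficients: intercepts,
#'   progress slope, progress-by-inverse-length slope and noise sd for the key
#'   release; intercept, progress slope and noise sd for the saccade.
#' @param neurons neuron roster tibble ([neuron_spec()] rows).
#' @param session_id session identifier.
#' @param seed master integer seed; per-neuron substreams are derived from it.
#' @return object of class `saveseq_config`.
#' @export
generator_config <- function(interest_rates = c(0.5, 1.5),
                             length_probs = list(
                               c(`2` = 0.45, `3` = 0.30, `4` = 0.15, `5` = 0.10),
                               c(`3` = 0.10, `4` = 0.20, `5` = 0.30, `6` = 0.25, `7` = 0.15)
                             ),
                             n_sequences = 100,
                             error_rate = 0.1,
                             base_rate = 0.11,
                             timing = list(pre_fix = 1.0, fixation = 2.0,
                                           delay = 1.5, outcome = 0.5, iti = 0.5),
                             rt = list(key_intercept = 0.40,
                                       key_progress = -0.008,
                                       key_progress_invlength = -0.040,
                                       key_sd = 0.050,
                                       saccade_intercept = 0.25,
                                       saccade_progress = 0.003,
                                       saccade_sd = 0.040),
                             neurons = default_roster(),
                             session_id = "s01",
                             seed = 1) {
  stopifnot(length(length_probs) == length(interest_rates), n_sequences >= 1,
            error_rate >= 0, error_rate < 1)
  for (p in length_probs) {
    if (sum(p) <= 0) abort("length distribution has zero mass")
    if (any(p < 0)) abort("length probabilities must be non-negative")
  }
  if (any(unlist(timing) <= 0)) abort("period durations must be > 0")
  structure(
    list(interest_rates = interest_rates,
         length_probs = lapply(length_probs, function(p) p / sum(p)),
         n_sequences = n_sequences, error_rate = error_rate,
         base_rate = base_rate, timing = timing, rt = rt,
         neurons = neurons, session_id = session_id, seed = as.integer(seed)),
    class = "saveseq_config"
  )
}

#' @export
print.saveseq_config <- function(x, ...) {
  cat("<saveseq_config>", length(x$interest_rates), "interest-rate block(s),",
      x$n_sequences, "sequences/block,", nrow(x$neurons), "neurons, seed",
      x$seed, "\n")
  invisible(x)
}
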