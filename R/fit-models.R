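#' Per-trial regressors for the tuning-model suite
#'
#' Builds, for the correct trials of a trial table, every regressor used by
#' the single-neuron models: sequence progress, length-normalized (adaptive)
#' progress, accumulated reward magnitude (ml, geometric rule at the current
#' step), elapsed within-sequence time (cumulative trials including errors),
#' step indicators, save/spend choice, spend/save/sequence subjective values
#' (from the empirical sequence-length preferences), sequence length, cue
#' position and saccade side. Subjective values are computed per interest
#' rate; at the maximal observed step the save value is 0 (no future spend).
#'
#' @param trials trial tibble.
#' @param sv optional precomputed [spend_value_tables()] output.
#' @return tibble keyed by (`session_id`, `trial_index`) with regressor
#'   columns `progress`, `adaptive_progress`, `reward_magnitude`,
#'   `elapsed_time`, `step1..stepN`, `choice_spend`, `sv_spend`, `sv_save`,
#'   `seq_sv`, `seq_length`, `cue_save_left`, `action_left`, and reaction
#'   times where present.
#' @export
design_matrix <- function(trials, sv = NULL) {
  ok <- trials %>% filter(!.data$error)
  if (nrow(ok) == 0) abort("no correct trials")
  sv <- sv %||% spend_value_tables(trials)
  sv_by <- sv %>% select("interest_rate", "step", "sv_spend", "sv_save")
  seq_sv <- sv_by %>%
    rename(sequence_length = "step", seq_sv = "sv_spend") %>%
    select("interest_rate", "sequence_length", "seq_sv")
  max_step <- max(ok$step)
  out <- ok %>%
    mutate(
      progress = .data$step,
      adaptive_progress = .data$step / .data$sequence_length,
      reward_magnitude = ifelse(
        abs(.data$interest_rate - 1) < 1e-12,
        .data$base_rate * .data$step,
        .data$base_rate * (.data$interest_rate^.data$step - 1) /
          (.data$interest_rate - 1)
      ),
      elapsed_time = .data$elapsed,
      choice_spend = as.numeric(.data$choice == "spend"),
      seq_length = .data$sequence_length,
      cue_save_left = as.numeric(.data$cue_position == "save_left"),
      action_left = as.numeric(.data$action_side == "left")
    ) %>%
    left_join(sv_by, by = c("interest_rate", "step")) %>%
    left_join(seq_sv, by = c("interest_rate", "sequence_length"))
  for (s in seq_len(max_step)) {
    out[[paste0("step", s)]] <- as.numeric(out$step == s)
  }
  out %>%
    select("session_id", "trial_index", "progress", "adaptive_progress",
           "reward_magnitude", "elapsed_time", dplyr::starts_with("step", ignore.case = FALSE) &
             !dplyr::any_of("step"), "choice_spend", "sv_spend", "sv_save",
           "seq_sv", "seq_length", "cue_save_left", "action_left",
           dplyr::any_of(c("rt_key", "rt_saccade")))
}

model_terms <- function(model, dm) {
  switch(model,
    eq2 = "progress",
    eq3 = "adaptive_progress",
    eq4 = "reward_magnitude",
    eq5 = "elapsed_time",
    eq6 = grep("^step[0-9]+$", names(dm), value = TRUE),
    eq8 = c("progress", "adaptive_progress"),
    abort(paste("unknown model:", model))
  )
}

#' Fit a tuning model to windowed activity
#'
#' Ordinary least-squares regression of trial-by-trial firing rate on the
#' regressor(s) of one tuning model, fitted separately for every (neuron,
#' period) response in `counts`:
#' `eq2` raw sequence progress, `eq3` length-normalized (adaptive) progress,
#' `eq4` accumulated reward magnitude, `eq5` elapsed within-sequence time
#' including errors, `eq6` step indicator tuning (no intercept), and `eq8`
#' partial adaptation (raw and normalized progress jointly). Slope p-values
#' are two-sided t-tests; `model_p_value` is the overall F test (for single-
#' regressor models it equals the slope p-value). Responses with a
#' rank-deficient design (e.g. a single sequence length under eq3) are
#' flagged degenerate and skipped.
#'
#' @param counts windowed-counts tibble (correct trials; error trials are
#'   dropped if present).
#' @param trials trial tibble.
#' @param model one of `"eq2", "eq3", "eq4", "eq5", "eq6", "eq8"`.
#' @param sv optional precomputed subjective-value tables (unused by these
#'   models but accepted for interface symmetry).
#' @param response column of `counts` to regress (default `"rate"`; use
#'   `"z"` for normalized activity).
#' @return tidy tibble, one row per (neuron, period, term) with `estimate`,
#'   `std_estimate`, `p_value`, `r_squared`, `adj_r_squared`,
#'   `model_p_value`, `n_trials`, `degenerate`.
#' @export
fit_model <- function(counts, trials, model = "eq2", sv = NULL,
                      response = "rate") {
  dm <- design_matrix(trials, sv = sv)
  terms <- model_terms(model, dm)
  dat <- counts %>%
    dplyr::inner_join(dm, by = c("session_id", "trial_index"))
  intercept <- model != "eq6"
  dat %>%
    group_by(.data$neuron_id, .data$period) %>%
    dplyr::group_modify(function(d, key) {
      X <- as.matrix(d[, terms, drop = FALSE])
      if (intercept) X <- cbind(`(Intercept)` = 1, X)
      y <- d[[response]]
      if (nrow(X) <= ncol(X)) {
        return(tibble(term = NA_character_, estimate = NA_real_,
                      std_estimate = NA_real_, p_value = NA_real_,
                      r_squared = NA_real_, adj_r_squared = NA_real_,
                      bic = NA_real_, model_p_value = NA_real_, n_trials = nrow(X),
                      degenerate = TRUE))
      }
      f <- ols_fit(X, y)
      if (isTRUE(f$degenerate)) {
        return(tibble(term = NA_character_, estimate = NA_real_,
                      std_estimate = NA_real_, p_value = NA_real_,
                      r_squared = NA_real_, adj_r_squared = NA_real_,
                      bic = NA_real_, model_p_value = NA_real_, n_trials = f$n,
                      degenerate = TRUE))
      }
      keep <- f$term != "(Intercept)"
      tibble(term = f$term[keep], estimate = unname(f$estimate[keep]),
             std_estimate = unname(f$std_estimate[keep]),
             p_value = unname(f$p_value[keep]),
             r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
             bic = f$bic, model_p_value = f$model_p, n_trials = f$n, degenerate = FALSE)
    }) %>%
    ungroup() %>%
    mutate(model = model, .after = "period")
}

#' Fit several tuning models at once
#'
#' @inheritParams fit_model
#' @param models character vector of model ids.
#' @return row-bound tidy fits for all models.
#' @export
fit_models <- function(counts, trials, models = c("eq2", "eq3", "eq4", "eq5",
                                                  "eq6", "eq8"),
                       sv = NULL, response = "rate") {
  sv <- sv %||% spend_value_tables(trials)
  purrr::map_dfr(models, ~ fit_model(counts, trials, .x, sv = sv,
                                     response = response))
}

#' Best-fitting tuning model per response
#'
#' Picks, for each (neuron, period) response, the winning model under a
#' model-selection criterion. The default is BIC: the candidate set contains
#' nested models (the step-indicator and partial-adaptation models nest raw
#' progress), for which raw R-squared can never favor the smaller model and
#' adjusted R-squared penalizes extra parameters too weakly at typical trial
#' counts. The pairwise published-style contests in [compare_models()] use
#' raw R-squared between non-nested one-regressor models.
#'
#' @param fits tidy fits from [fit_models()].
#' @param criterion `"bic"` (lowest wins), `"adj_r_squared"` or
#'   `"r_squared"` (highest wins).
#' @param significant_only restrict to responses with `model_p_value < 0.05`.
#' @return tibble with one row per response: `neuron_id`, `period`,
#'   `best_model` and the criterion value.
#' @export
best_fit_model <- function(fits, criterion = c("bic", "adj_r_squared",
                                               "r_squared"),
                           significant_only = FALSE) {
  criterion <- match.arg(criterion)
  one <- fits %>%
    filter(!.data$degenerate) %>%
    distinct(.data$neuron_id, .data$period, .data$model, .data$r_squared,
             .data$adj_r_squared, .data$bic, .data$model_p_value)
  if (significant_only) one <- filter(one, .data$model_p_value < 0.05)
  one %>%
    group_by(.data$neuron_id, .data$period) %>%
    slice(if (criterion == "bic") which.min(.data$bic)
          else which.max(.data[[criterion]])) %>%
    ungroup() %>%
    rename(best_model = "model") %>%
    select("neuron_id", "period", "best_model", dplyr::all_of(criterion))
}

#' Task-relatedness screening of windowed activity
#'
#' Flags each (neuron, period) response as task-related if its per-trial
#' rates differ from the pre-fixation control period (two-sided Wilcoxon
#' signed-rank test on paired trials, strict p < 0.0083, a Bonferroni-style
#' criterion). The control period itself is never screened. Neurons with too
#' few correct trials are excluded with a message.
#'
#' @param counts windowed-counts tibble (correct trials).
#' @param control_period the control period name.
#' @param alpha significance threshold (strict `<`).
#' @param min_trials minimum correct trials per neuron.
#' @return tibble of `neuron_id`, `period`, `p_value`, `task_related`.
#' @export
select_task_related <- function(counts, control_period = "pre_fixation",
                                alpha = 0.0083, min_trials = 20) {
  n_tr <- counts %>%
    filter(.data$period == control_period) %>%
    count(.data$neuron_id, name = "n")
  drop <- n_tr %>% filter(.data$n < min_trials)
  if (nrow(drop)) {
    inform(paste("excluding", nrow(drop), "neuron(s) with <", min_trials,
                 "trials"))
  }
  keep_ids <- setdiff(n_tr$neuron_id, drop$neuron_id)
  ctrl <- counts %>%
    filter(.data$period == control_period, .data$neuron_id %in% keep_ids) %>%
    select("neuron_id", "session_id", "trial_index", ctrl_rate = "rate")
  counts %>%
    filter(.data$period != control_period, .data$neuron_id %in% keep_ids) %>%
    dplyr::inner_join(ctrl, by = c("neuron_id", "session_id", "trial_index")) %>%
    group_by(.data$neuron_id, .data$period) %>%
    summarise(p_value = {
      d <- .data$rate - .data$ctrl_rate
      if (all(d == 0)) 1
      else suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    }, .groups = "drop") %>%
    mutate(task_related = .data$p_value < alpha)
}

#' Summary of progress-slope signs across significant responses
#'
#' Counts positive and negative regression slopes among significant responses
#' and tests the split against 50/50 with an exact two-sided binomial test.
#'
#' @param fits tidy fits for a single-slope model (e.g. eq2).
#' @param alpha significance criterion on the slope p-value.
#' @return one-row tibble `n_positive`, `n_negative`, `p_value` (binomial);
#'   zero-row tibble if no significant responses.
#' @export
summarize_slope_signs <- function(fits, alpha = 0.05) {
  sig <- fits %>%
    filter(!.data$degenerate, .data$p_value < alpha, .data$estimate != 0)
  if (nrow(sig) == 0) {
    return(tibble(n_positive = integer(), n_negative = integer(),
                  p_value = numeric()))
  }
  pos <- sum(sig$estimate > 0)
  neg <- sum(sig$estimate < 0)
  tibble(n_positive = pos, n_negative = neg,
         p_value = binom.test(pos, pos + neg, 0.5)$p.value)
}
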