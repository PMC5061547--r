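#' Generate synthetic saving-task behavior
#'
#' Simulates one session of the sequential save-spend task. Sequence lengths
#' are drawn i.i.d. from the per-interest-rate length distribution; each
#' sequence consists of save choices followed by one final spend choice. Error
#' trials (failed fixation / premature key release) are injected with the
#' configured per-trial probability; they do not advance sequence progress and
#' accumulated reward is retained across them. Key-release reaction times
#' follow a linear model with a negative progress slope and a
#' progress-by-inverse-length interaction (reaction times adapt to the planned
#' sequence length), plus Gaussian noise.
#'
#' An imperative control session can reuse the realized sequence lengths of a
#' free-choice session (`match_to`), matching save/spend statistics between
#' tasks.
#'
#' @param config a [generator_config()].
#' @param task_type `"free"` or `"imperative"`.
#' @param match_to optional trial tibble from a free-choice run whose realized
#'   sequence lengths (per interest rate) are reused.
#' @param session_id optional session identifier override.
#' @return tibble with one row per trial (error trials included), columns:
#'   `session_id`, `trial_index` (0-based, session order), `sequence_id`,
#'   `step`, `sequence_length`, `elapsed`, `interest_rate`, `base_rate`,
#'   `choice`, `task_type`, `cue_position`, `action_side`, `error`,
#'   `t_fix_on`, `t_cue_on`, `t_choice`, `t_outcome`, `t_end`, `rt_key`,
#'   `rt_saccade`, `reward_ml`.
#' @export
generate_behavior <- function(config, task_type = c("free", "imperative"),
                              match_to = NULL, session_id = NULL) {
  stopifnot(inherits(config, "saveseq_config"))
  task_type <- match.arg(task_type)
  session_id <- session_id %||%
    paste0(config$session_id, if (task_type == "imperative") "-imp" else "")
  set.seed(substream_seed(paste0("behavior-", task_type), config$seed))

  blocks <- purrr::map2(config$interest_rates, config$length_probs,
    function(q, probs) {
      lens_avail <- as.integer(names(probs))
      if (!is.null(match_to)) {
        lengths <- match_to %>%
          filter(.data$interest_rate == q, !.data$error) %>%
          distinct(.data$sequence_id, .data$sequence_length) %>%
          pull("sequence_length")
        if (length(lengths) == 0) abort("`match_to` has no sequences for this interest rate")
      } else {
        lengths <- lens_avail[sample.int(length(lens_avail), config$n_sequences,
                                         replace = TRUE, prob = probs)]
      }
      purrr::map_dfr(seq_along(lengths), function(s) {
        L <- lengths[s]
        rows <- list()
        elapsed <- 0L
        for (st in seq_len(L)) {
          # error attempts before (or instead of) the pending correct trial
          while (runif(1) < config$error_rate) {
            elapsed <- elapsed + 1L
            rows[[length(rows) + 1L]] <- tibble(
              seq_in_block = s, step = st, sequence_length = L,
              elapsed = elapsed, error = TRUE, choice = NA_character_
            )
          }
          elapsed <- elapsed + 1L
          rows[[length(rows) + 1L]] <- tibble(
            seq_in_block = s, step = st, sequence_length = L,
            elapsed = elapsed, error = FALSE,
            choice = if (st == L) "spend" else "save"
          )
        }
        bind_rows(rows)
      }) %>%
        mutate(interest_rate = q)
    })

  trials <- bind_rows(blocks)
  # sequence ids: new id whenever (block, seq_in_block) changes
  key <- paste(trials$interest_rate, trials$seq_in_block)
  trials$sequence_id <- cumsum(c(TRUE, key[-1] != key[-length(key)]))

  n <- nrow(trials)
  tm <- config$timing
  rt <- config$rt
  rt_key <- pmax(0.08, rt$key_intercept + rt$key_progress * trials$step +
                   rt$key_progress_invlength * trials$step / trials$sequence_length +
                   rnorm(n, 0, rt$key_sd))
  rt_sac <- pmax(0.08, rt$saccade_intercept + rt$saccade_progress * trials$step +
                   rnorm(n, 0, rt$saccade_sd))
  cue_pos <- sample(c("save_left", "save_right"), n, replace = TRUE)
  save_side <- ifelse(cue_pos == "save_left", "left", "right")
  action_side <- ifelse(trials$choice == "save", save_side,
                        ifelse(save_side == "left", "right", "left"))

  trials %>%
    mutate(
      session_id = session_id,
      trial_index = dplyr::row_number() - 1L,
      task_type = task_type,
      base_rate = config$base_rate,
      cue_position = cue_pos,
      action_side = ifelse(.data$error, NA_character_, action_side),
      t_fix_on = tm$pre_fix,
      t_cue_on = tm$pre_fix + tm$fixation,
      t_choice = .data$t_cue_on + rt_sac,
      t_outcome = .data$t_choice + tm$delay + rt_key,
      t_end = .data$t_outcome + tm$outcome + tm$iti,
      rt_key = ifelse(.data$error, NA_real_, rt_key),
      rt_saccade = ifelse(.data$error, NA_real_, rt_sac),
      reward_ml = ifelse(!.data$error & .data$choice == "spend",
                         accumulate_reward(.data$step, config$base_rate[1],
                                           .data$interest_rate),
                         0),
      reward_ml = ifelse(is.na(.data$reward_ml), 0, .data$reward_ml)
    ) %>%
    select("session_id", "trial_index", "sequence_id", "step",
           "sequence_length", "elapsed", "interest_rate", "base_rate",
           "choice", "task_type", "cue_position", "action_side", "error",
           "t_fix_on", "t_cue_on", "t_choice", "t_outcome", "t_end",
           "rt_key", "rt_saccade", "reward_ml")
}

#' Validate the structural invariants of a trial table
#'
#' Checks the bookkeeping contract of a trial table: exactly one spend choice
#' per sequence, placed on its last correct trial with `step ==
#' sequence_length`; step incrementing by one over consecutive correct trials
#' and resetting at sequence starts; errors not advancing step; spend-trial
#' rewards equal to the geometric accumulation rule; event times strictly
#' increasing within a trial.
#'
#' @param trials trial tibble.
#' @return invisibly TRUE; aborts with offending row numbers otherwise.
#' @export
validate_trials <- function(trials) {
  fail <- function(msg, rows) {
    abort(paste0(msg, " (rows: ", paste(utils::head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) ", ..." else "", ")"))
  }
  if (nrow(trials) == 0) return(invisible(TRUE))
  ok <- trials %>% mutate(.row = dplyr::row_number()) %>% filter(!.data$error)
  per_seq <- ok %>%
    group_by(.data$session_id, .data$sequence_id) %>%
    summarise(
      n_spend = sum(.data$choice == "spend"),
      last_is_spend = .data$choice[which.max(.data$step)] == "spend",
      step_ok = length(.data$step) == max(.data$step) &&
        all(sort(.data$step) == seq_along(.data$step)),
      len_ok = all(.data$sequence_length == max(.data$step)),
      .row = .data$.row[1], .groups = "drop"
    )
  bad <- per_seq %>% filter(.data$n_spend != 1 | !.data$last_is_spend)
  if (nrow(bad)) fail("sequence without exactly one final spend choice", bad$.row)
  bad <- per_seq %>% filter(!.data$step_ok | !.data$len_ok)
  if (nrow(bad)) fail("step/sequence_length bookkeeping violated", bad$.row)
  spend <- ok %>% filter(.data$choice == "spend")
  expected <- purrr::pmap_dbl(
    list(spend$step, spend$base_rate, spend$interest_rate), accumulate_reward
  )
  bad_r <- which(abs(spend$reward_ml - expected) > 1e-9)
  if (length(bad_r)) fail("spend reward deviates from accumulation rule", spend$.row[bad_r])
  times <- trials %>% mutate(.row = dplyr::row_number()) %>%
    filter(!(.data$t_fix_on < .data$t_cue_on & .data$t_cue_on < .data$t_choice &
               .data$t_choice < .data$t_outcome & .data$t_outcome < .data$t_end))
  if (nrow(times)) fail("event times not strictly increasing", times$.row)
  invisible(TRUE)
}
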