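#' Standard task-period analysis windows
#'
#' The five fixed windows used for spike counting, each anchored to a trial
#' event: 1000 ms before the fixation spot (pre-fixation control period),
#' 1775 ms of fixation starting 25 ms after fixation-spot onset, 300 ms of cue
#' starting 20 ms after cue onset, 1500 ms of delay starting 25 ms after the
#' choice, and 500 ms of outcome starting 50 ms after reinforcer onset.
#' Windows are half-open `[start, start + duration)`.
#'
#' @return tibble with columns `period`, `anchor_event` (a trial time column),
#'   `start_offset` (s, signed), `duration` (s).
#' @export
task_periods <- function() {
  tibble(
    period = c("pre_fixation", "fixation", "cue", "delay", "outcome"),
    anchor_event = c("t_fix_on", "t_fix_on", "t_cue_on", "t_choice", "t_outcome"),
    start_offset = c(-1.0, 0.025, 0.020, 0.025, 0.050),
    duration = c(1.0, 1.775, 0.300, 1.500, 0.500)
  )
}

# relative position of each period along the trial, used by the
# reward-expectation control tuning (within-trial ramp toward outcome)
period_ramp <- c(pre_fixation = 0.1, fixation = 0.35, cue = 0.6,
                 delay = 0.8, outcome = 1.0)
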