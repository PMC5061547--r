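#' Write a synthetic dataset to disk
#'
#' Emits the three delimited tables (trials, spikes, neuron ground truth) and
#' a JSON manifest echoing the generator configuration and seed. Booleans are
#' written as 0/1 and missing values as "NA"; list-valued neuron fields are
#' serialized as semicolon-joined strings.
#'
#' @param dir output directory (created if needed).
#' @param trials,spikes,neurons the three tables.
#' @param config optional [generator_config()] echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, trials, spikes, neurons, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (anyDuplicated(neurons$neuron_id)) abort("duplicate neuron ids in roster")
  readr::write_csv(mutate(trials, error = as.integer(.data$error)),
                   file.path(dir, "trials.csv"), na = "NA")
  readr::write_csv(spikes, file.path(dir, "spikes.csv"), na = "NA")
  flat <- neurons %>%
    mutate(
      target_periods = purrr::map_chr(.data$target_periods, paste, collapse = ";"),
      step_centers = purrr::map_chr(.data$step_centers, paste, collapse = ";"),
      free_only = as.integer(.data$free_only)
    )
  readr::write_csv(flat, file.path(dir, "neurons.csv"), na = "NA")
  manifest <- list(
    package = "saveseq",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) {
      unclass(config)[setdiff(names(config), "neurons")]
    } else NULL,
    n_trials = nrow(trials), n_neurons = nrow(neurons)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset from disk, with validation
#'
#' Reads the tables written by [write_dataset()], restores types (booleans,
#' list columns), and checks the trial-table invariants via
#' [validate_trials()]; violations abort with offending row numbers.
#'
#' @param dir dataset directory.
#' @param validate run invariant checks (default TRUE).
#' @return list with elements `trials`, `spikes`, `neurons`, `manifest`.
#' @export
read_dataset <- function(dir, validate = TRUE) {
  req <- file.path(dir, c("trials.csv", "spikes.csv", "neurons.csv"))
  missing <- req[!file.exists(req)]
  if (length(missing)) abort(paste("missing dataset files:", paste(missing, collapse = ", ")))
  trials <- readr::read_csv(req[1], show_col_types = FALSE, na = "NA",
                            progress = FALSE) %>%
    mutate(error = as.logical(.data$error))
  expected <- c("session_id", "trial_index", "sequence_id", "step",
                "sequence_length", "interest_rate", "base_rate", "choice",
                "task_type", "error", "t_fix_on", "t_cue_on", "t_choice",
                "t_outcome")
  gone <- setdiff(expected, names(trials))
  if (length(gone)) abort(paste("trials table lacks columns:", paste(gone, collapse = ", ")))
  spikes <- readr::read_csv(req[2], show_col_types = FALSE, na = "NA",
                            progress = FALSE)
  neurons <- readr::read_csv(
    req[3], show_col_types = FALSE, na = "NA", progress = FALSE,
    col_types = readr::cols(step_centers = readr::col_character(),
                            target_periods = readr::col_character())
  ) %>%
    mutate(
      target_periods = purrr::map(.data$target_periods,
                                  ~ strsplit(.x %||% "", ";")[[1]]),
      step_centers = purrr::map(.data$step_centers, function(s) {
        if (is.na(s) || identical(s, "")) integer() else as.integer(strsplit(as.character(s), ";")[[1]])
      }),
      free_only = as.logical(.data$free_only)
    )
  manifest <- if (file.exists(file.path(dir, "manifest.json"))) {
    jsonlite::read_json(file.path(dir, "manifest.json"))
  } else NULL
  if (validate) validate_trials(trials)
  list(trials = trials, spikes = spikes, neurons = neurons, manifest = manifest)
}

#' Generate a complete dataset on disk
#'
#' Runs the behavior and spike generators under one configuration and writes
#' the result with [write_dataset()]. The same config and seed always produce
#' identical files.
#'
#' @param config a [generator_config()].
#' @param dir output directory.
#' @param tasks which task types to generate; imperative sessions reuse the
#'   free-choice sequence lengths so the tasks have matched statistics.
#' @return the dataset list (as from [read_dataset()]), invisibly.
#' @export
generate_dataset <- function(config, dir, tasks = "free") {
  free <- generate_behavior(config, "free")
  trials <- free
  if ("imperative" %in% tasks) {
    trials <- bind_rows(free, generate_behavior(config, "imperative",
                                                match_to = free))
  }
  validate_trials(trials)
  spikes <- generate_roster_spikes(config$neurons, trials, seed = config$seed)
  write_dataset(dir, trials, spikes, config$neurons, config)
  invisible(list(trials = trials, spikes = spikes, neurons = config$neurons))
}

#' Count spikes in fixed task-period windows
#'
#' Counts each neuron's spikes on each trial inside the named analysis
#' windows (half-open `[start, start + duration)` intervals anchored to trial
#' events) and converts them to rates. Error trials are excluded by default,
#' matching the convention that single-neuron statistics use correct trials
#' only; set `include_errors = TRUE` for error-trial analyses. Spikes outside
#' the trial span are dropped with a warning.
#'
#' @param spikes spikes tibble (`neuron_id`, `session_id`, `trial_index`,
#'   `time`).
#' @param trials trial tibble.
#' @param periods period definitions ([task_periods()]).
#' @param include_errors keep error trials.
#' @return windowed-counts tibble: `neuron_id`, `session_id`, `trial_index`,
#'   `period`, `count`, `duration`, `rate`.
#' @export
extract_window_counts <- function(spikes, trials, periods = task_periods(),
                                  include_errors = FALSE) {
  if (!include_errors) trials <- filter(trials, !.data$error)
  sp <- spikes %>%
    left_join(select(trials, "session_id", "trial_index", "t_fix_on",
                     "t_cue_on", "t_choice", "t_outcome", "t_end"),
              by = c("session_id", "trial_index")) %>%
    filter(!is.na(.data$t_end))
  out_of_span <- sp$time < 0 | sp$time >= sp$t_end
  if (any(out_of_span)) {
    warn(paste(sum(out_of_span), "spike(s) outside trial span dropped"))
    sp <- sp[!out_of_span, ]
  }
  base <- tidyr::crossing(
    distinct(trials, .data$session_id, .data$trial_index),
    select(periods, "period", "duration")
  ) %>%
    tidyr::crossing(tibble(.n = unique(spikes$neuron_id))) %>%
    rename(neuron_id = ".n")
  counted <- purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    p <- periods[i, ]
    lo <- sp[[p$anchor_event]] + p$start_offset
    keep <- sp$time >= lo & sp$time < lo + p$duration
    sp[keep, ] %>%
      count(.data$neuron_id, .data$session_id, .data$trial_index,
            name = "count") %>%
      mutate(period = p$period)
  })
  base %>%
    left_join(counted, by = c("neuron_id", "session_id", "trial_index", "period")) %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           rate = .data$count / .data$duration) %>%
    arrange(.data$neuron_id, .data$period, .data$session_id, .data$trial_index)
}

#' Z-normalize windowed activity against a control period
#'
#' Converts each neuron's task-period rates to z-scores by subtracting the
#' mean and dividing by the standard deviation of its control-period rates
#' (default: the pre-fixation period; `mode = "session"` normalizes against
#' all of the neuron's rates instead). Neurons whose reference sd is zero are
#' excluded with a message.
#'
#' @param counts windowed-counts tibble from [extract_window_counts()] or
#'   [simulate_window_counts()].
#' @param mode `"control_period"` or `"session"`.
#' @param control_period name of the control period.
#' @return tibble with an added `z` column; control-excluded neurons dropped.
#' @export
znormalize <- function(counts, mode = c("control_period", "session"),
                       control_period = "pre_fixation") {
  mode <- match.arg(mode)
  ref <- if (mode == "control_period") {
    counts %>% filter(.data$period == control_period)
  } else {
    counts
  }
  stats_tbl <- ref %>%
    group_by(.data$neuron_id) %>%
    summarise(ref_mean = mean(.data$rate), ref_sd = stats::sd(.data$rate),
              .groups = "drop")
  bad <- stats_tbl %>% filter(is.na(.data$ref_sd) | .data$ref_sd == 0)
  if (nrow(bad)) {
    inform(paste("excluding", nrow(bad),
                 "neuron(s) with zero control-period variance:",
                 paste(utils::head(bad$neuron_id, 5), collapse = ", ")))
  }
  counts %>%
    dplyr::inner_join(filter(stats_tbl, !is.na(.data$ref_sd), .data$ref_sd > 0),
                      by = "neuron_id") %>%
    mutate(z = (.data$rate - .data$ref_mean) / .data$ref_sd) %>%
    select(-"ref_mean", -"ref_sd")
}

#' Sign-correct normalized responses by their progress slope
#'
#' Flips the z-scored activity of every (neuron, period) response whose
#' regression slope of activity on sequence progress (correct trials) is
#' negative, so that population averages of progress coding aggregate
#' coherently.
#'
#' @param activity z-normalized tibble from [znormalize()].
#' @param trials trial tibble.
#' @return `activity` with `z` flipped where needed and a `sign_flipped`
#'   logical column.
#' @export
sign_correct <- function(activity, trials) {
  slopes <- activity %>%
    left_join(select(trials, "session_id", "trial_index", "step", "error"),
              by = c("session_id", "trial_index")) %>%
    filter(!.data$error) %>%
    group_by(.data$neuron_id, .data$period) %>%
    summarise(slope = {
      if (stats::sd(.data$z) == 0 || stats::sd(.data$step) == 0) 0
      else stats::cov(.data$step, .data$z) / stats::var(.data$step)
    }, .groups = "drop")
  activity %>%
    left_join(slopes, by = c("neuron_id", "period")) %>%
    mutate(sign_flipped = !is.na(.data$slope) & .data$slope < 0,
           z = ifelse(.data$sign_flipped, -.data$z, .data$z)) %>%
    select(-"slope")
}
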