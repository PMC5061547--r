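#' Event-aligned segments for sliding-window analysis
#'
#' The sliding-window epoch is stitched from event-aligned segments rather
#' than one continuous clock, so variable-duration gaps (saccade and key
#' reaction times) do not smear windows across events: a fixation-aligned
#' segment covering the pre-fixation and fixation periods, a cue-aligned
#' segment, a choice-aligned segment covering the delay, and an
#' outcome-aligned segment.
#'
#' @return tibble with `segment`, `anchor_event`, `from`, `to` (s, relative
#'   to the anchor).
#' @export
sliding_segments <- function() {
  tibble(
    segment = c("fixation", "cue", "choice", "outcome"),
    anchor_event = c("t_fix_on", "t_cue_on", "t_choice", "t_outcome"),
    from = c(-1.0, -0.1, 0.0, -0.1),
    to = c(1.825, 0.5, 1.55, 0.6)
  )
}

# trials x windows spike-count matrix for one neuron in one aligned segment;
# windows are [s, s + window) with starts every `step` seconds
window_count_matrix <- function(spikes_one, trials, anchor_event, starts,
                                window) {
  anchors <- trials[[anchor_event]]
  key <- paste(trials$session_id, trials$trial_index)
  sp_key <- paste(spikes_one$session_id, spikes_one$trial_index)
  idx <- match(sp_key, key)
  ok <- !is.na(idx)
  aligned <- split(spikes_one$time[ok] - anchors[idx[ok]], idx[ok])
  M <- matrix(0L, nrow(trials), length(starts))
  fi <- function(v, x) findInterval(v, x, left.open = TRUE)
  for (nm in names(aligned)) {
    x <- sort(aligned[[nm]])
    i <- as.integer(nm)
    M[i, ] <- fi(starts + window, x) - fi(starts, x)
  }
  M
}

# per-window two-sided OLS slope p-values of count on x (zero-variance
# windows get p = 1), vectorized across windows
window_pvalues <- function(M, x) {
  n <- length(x)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  if (sx == 0) return(rep(1, ncol(M)))
  Mc <- sweep(M, 2, colMeans(M))
  sy <- sqrt(colSums(Mc^2))
  r <- as.vector(crossprod(Mc, xc)) / (sx * ifelse(sy == 0, Inf, sy))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tval), n - 2)
  ifelse(sy == 0, 1, p)
}

max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Sliding-window regression of activity on a task regressor
#'
#' Moves a 200 ms counting window in 25 ms steps across each event-aligned
#' segment of the trial and regresses, window by window, the per-trial spike
#' count of each neuron on the chosen regressor (correct trials). Windows
#' with zero count variance record p = 1.
#'
#' @param spikes spikes tibble (one or more neurons).
#' @param trials trial tibble.
#' @param regressor design-matrix column name (default `"progress"`).
#' @param window window length in seconds.
#' @param step step between window starts in seconds.
#' @param segments segment definitions ([sliding_segments()]).
#' @return tibble `neuron_id`, `segment`, `window_start`, `p_value`.
#' @export
sliding_window_regression <- function(spikes, trials, regressor = "progress",
                                      window = 0.2, step = 0.025,
                                      segments = sliding_segments()) {
  ok <- trials %>% filter(!.data$error) %>% arrange(.data$trial_index)
  dm <- design_matrix(ok)
  x <- dm[[regressor]][match(paste(ok$session_id, ok$trial_index),
                             paste(dm$session_id, dm$trial_index))]
  purrr::map_dfr(split(spikes, spikes$neuron_id), function(sp) {
    purrr::map_dfr(seq_len(nrow(segments)), function(i) {
      seg <- segments[i, ]
      starts <- seq(seg$from, seg$to - window, by = step)
      M <- window_count_matrix(sp, ok, seg$anchor_event, starts, window)
      tibble(neuron_id = sp$neuron_id[1], segment = seg$segment,
             window_start = starts, p_value = window_pvalues(M, x))
    })
  })
}

#' Longest run of consecutive significant windows per neuron
#'
#' Runs are counted within each aligned segment (windows cannot be
#' consecutive across segment boundaries).
#'
#' @param sw output of [sliding_window_regression()].
#' @param alpha per-window significance level.
#' @return tibble `neuron_id`, `max_run`.
#' @export
significant_runs <- function(sw, alpha = 0.05) {
  sw %>%
    group_by(.data$neuron_id, .data$segment) %>%
    summarise(run = max_run(.data$p_value < alpha), .groups = "drop") %>%
    group_by(.data$neuron_id) %>%
    summarise(max_run = max(.data$run), .groups = "drop")
}

#' Calibrate the run-length criterion on trial-shuffled data
#'
#' For each neuron, repeats the sliding-window regression on trial-shuffled
#' data (the regressor is permuted across trials, breaking any relation to
#' activity while preserving both marginals) and records the longest run of
#' consecutive significant windows per shuffle. The returned criterion is the
#' smallest run length L such that fewer than `level` of shuffled series show
#' a run longer than L; a neuron is then flagged only when its observed run
#' exceeds L, giving a false-positive rate below `level` by construction.
#'
#' @inheritParams sliding_window_regression
#' @param n_shuffles shuffles per neuron (>= 100; the reference analysis
#'   uses 1000).
#' @param alpha per-window significance level.
#' @param level target false-positive rate for the criterion.
#' @return list with `threshold` (integer L), `exceed_fraction` (fraction of
#'   shuffled series with run > L), and `runs` (all shuffled max runs).
#' @export
calibrate_run_threshold <- function(spikes, trials, regressor = "progress",
                                    n_shuffles = 1000, window = 0.2,
                                    step = 0.025, alpha = 0.05, level = 0.05,
                                    segments = sliding_segments(), seed = 1) {
  if (n_shuffles < 1) abort("`n_shuffles` must be positive")
  if (n_shuffles < 100) warn("fewer than 100 shuffles gives an unstable criterion")
  ok <- trials %>% filter(!.data$error) %>% arrange(.data$trial_index)
  dm <- design_matrix(ok)
  x <- dm[[regressor]]
  set.seed(seed)
  runs <- purrr::map(split(spikes, spikes$neuron_id), function(sp) {
    mats <- purrr::map(seq_len(nrow(segments)), function(i) {
      seg <- segments[i, ]
      starts <- seq(seg$from, seg$to - window, by = step)
      window_count_matrix(sp, ok, seg$anchor_event, starts, window)
    })
    vapply(seq_len(n_shuffles), function(s) {
      xs <- sample(x)
      max(vapply(mats, function(M) max_run(window_pvalues(M, xs) < alpha),
                 integer(1)))
    }, integer(1))
  })
  runs <- unlist(runs, use.names = FALSE)
  cand <- 0:max(c(runs, 1))
  frac <- vapply(cand, function(L) mean(runs > L), numeric(1))
  threshold <- cand[which(frac < level)[1]]
  list(threshold = threshold, exceed_fraction = frac[threshold + 1],
       runs = runs)
}

#' Flag neurons with sustained sliding-window progress coding
#'
#' @inheritParams sliding_window_regression
#' @param run_threshold run-length criterion L (a neuron is flagged when its
#'   longest run of significant windows strictly exceeds L); the reference
#'   calibration yields L = 8 for the 200/25 ms geometry.
#' @param alpha per-window significance level.
#' @return tibble `neuron_id`, `max_run`, `detected`.
#' @export
detect_progress_neurons <- function(spikes, trials, regressor = "progress",
                                    run_threshold = 8, window = 0.2,
                                    step = 0.025, alpha = 0.05,
                                    segments = sliding_segments()) {
  sw <- sliding_window_regression(spikes, trials, regressor, window, step,
                                  segments)
  significant_runs(sw, alpha) %>%
    mutate(detected = .data$max_run > run_threshold)
}
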