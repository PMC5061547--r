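#' Population adaptation of progress slopes to sequence length
#'
#' Fits, separately for each sequence length with enough sequences, a linear
#' regression of pooled normalized population activity on sequence progress,
#' then regresses the per-length slopes on inverse sequence length. An
#' adaptive (length-normalized) progress code yields slopes proportional to
#' 1/length; a non-adaptive code yields constant slopes and a flat
#' slope-vs-1/length relation.
#'
#' @param activity normalized (and typically sign-corrected) activity tibble
#'   with columns `neuron_id`, `session_id`, `trial_index`, `period`, `z`;
#'   restrict beforehand to the responses of interest (e.g. progress-
#'   significant ones).
#' @param trials trial tibble.
#' @param min_sequences minimum sequences per length for a per-length fit.
#' @param per_neuron if TRUE, per-length slopes are computed per neuron and
#'   averaged instead of from pooled trial-level activity.
#' @return object of class `adaptation_result`: list with `by_length`
#'   (tibble: `sequence_length`, `slope`, `se`, `n_trials`),
#'   `inv_length_fit` (one-row tibble: `intercept`, `slope`, `p_value`,
#'   `r_squared`).
#' @export
adaptation_by_length <- function(activity, trials, min_sequences = 10,
                                 per_neuron = FALSE) {
  dat <- activity %>%
    dplyr::inner_join(select(trials, "session_id", "trial_index", "step",
                             "sequence_length", "sequence_id", "error"),
                      by = c("session_id", "trial_index")) %>%
    filter(!.data$error)
  eligible <- dat %>%
    distinct(.data$sequence_length, .data$sequence_id) %>%
    count(.data$sequence_length) %>%
    filter(.data$n >= min_sequences, .data$sequence_length >= 2)
  if (nrow(eligible) < 2) abort("need >= 2 distinct sequence lengths")
  dat <- dplyr::semi_join(dat, eligible, by = "sequence_length")
  slope_of <- function(d) {
    f <- ols_fit(cbind(1, step = d$step), d$z)
    if (isTRUE(f$degenerate)) return(c(NA_real_, NA_real_))
    c(unname(f$estimate[2]), unname(f$se[2]))
  }
  by_length <- if (per_neuron) {
    dat %>%
      group_by(.data$sequence_length, .data$neuron_id) %>%
      summarise(slope = slope_of(dplyr::pick(dplyr::everything()))[1],
                .groups = "drop_last") %>%
      summarise(se = stats::sd(.data$slope) / sqrt(dplyr::n()),
                slope = mean(.data$slope), n_trials = dplyr::n(),
                .groups = "drop") %>%
      select("sequence_length", "slope", "se", "n_trials")
  } else {
    dat %>%
      group_by(.data$sequence_length) %>%
      summarise(fit = list(slope_of(dplyr::pick(dplyr::everything()))),
                n_trials = dplyr::n(), .groups = "drop") %>%
      mutate(slope = purrr::map_dbl(.data$fit, 1),
             se = purrr::map_dbl(.data$fit, 2)) %>%
      select("sequence_length", "slope", "se", "n_trials")
  }
  inv <- ols_fit(cbind(1, inv_length = 1 / by_length$sequence_length),
                 by_length$slope)
  inv_fit <- tibble(intercept = unname(inv$estimate[1]),
                    slope = unname(inv$estimate[2]),
                    p_value = unname(inv$p_value[2]),
                    r_squared = inv$r_squared)
  structure(list(by_length = by_length, inv_length_fit = inv_fit),
            class = "adaptation_result")
}

#' @exportS3Method generics::tidy
tidy.adaptation_result <- function(x, ...) x$by_length

#' @exportS3Method generics::glance
glance.adaptation_result <- function(x, ...) x$inv_length_fit

#' @export
print.adaptation_result <- function(x, ...) {
  cat("<adaptation_result>\n")
  print(x$by_length)
  cat("slope ~ 1/length: slope =", signif(x$inv_length_fit$slope, 4),
      " R2 =", signif(x$inv_length_fit$r_squared, 4),
      " p =", signif(x$inv_length_fit$p_value, 3), "\n")
  invisible(x)
}

#' Predict forthcoming sequence length from activity at a fixed step
#'
#' Regresses the final (self-determined) length of each sequence on the mean
#' population activity measured on the sequence's trial at step k. Under an
#' adaptive progress code the activity at a given step is lower for longer
#' planned sequences, so the relation is negative from the second step on,
#' while first-step activity (a common starting point) predicts nothing.
#'
#' @param activity normalized activity tibble (see [adaptation_by_length()]).
#' @param trials trial tibble.
#' @param step_k sequence step at which activity is measured.
#' @return one-row tibble `step`, `slope`, `p_value`, `r_squared`,
#'   `n_sequences`.
#' @export
predict_sequence_length <- function(activity, trials, step_k = 2) {
  dat <- activity %>%
    dplyr::inner_join(select(trials, "session_id", "trial_index", "step",
                             "sequence_length", "sequence_id", "error"),
                      by = c("session_id", "trial_index")) %>%
    filter(!.data$error, .data$step == step_k) %>%
    group_by(.data$session_id, .data$sequence_id, .data$sequence_length) %>%
    summarise(act = mean(.data$z), .groups = "drop")
  if (dplyr::n_distinct(dat$sequence_length) < 2) {
    abort("need >= 2 distinct forthcoming lengths at this step")
  }
  f <- ols_fit(cbind(1, act = dat$act), dat$sequence_length)
  tibble(step = step_k, slope = unname(f$estimate[2]),
         p_value = unname(f$p_value[2]), r_squared = f$r_squared,
         n_sequences = nrow(dat))
}

#' Slope re-adaptation across consecutive sequences
#'
#' For each pair of adjacent sequences within a session and interest-rate
#' block (both of length >= 2), computes the progress slope of pooled
#' population activity within each sequence and regresses the slope
#' difference on the difference in inverse lengths. Under an adaptive code
#' with gain g, the slope in a length-L sequence is g/L, so the regression
#' coefficient recovers g; a non-adaptive code yields a coefficient near 0.
#'
#' @param activity normalized activity tibble.
#' @param trials trial tibble.
#' @return object of class `consecutive_adaptation`: list with `pairs`
#'   (tibble of per-pair `d_slope`, `d_inv_length`) and `fit` (one-row
#'   tibble `coefficient`, `p_value`, `r_squared`).
#' @export
consecutive_adaptation <- function(activity, trials) {
  dat <- activity %>%
    dplyr::inner_join(select(trials, "session_id", "trial_index", "step",
                             "sequence_length", "sequence_id",
                             "interest_rate", "error"),
                      by = c("session_id", "trial_index")) %>%
    filter(!.data$error, .data$sequence_length >= 2)
  slopes <- dat %>%
    group_by(.data$session_id, .data$interest_rate, .data$sequence_id,
             .data$sequence_length) %>%
    summarise(slope = {
      if (stats::var(.data$step) == 0) NA_real_
      else stats::cov(.data$step, .data$z) / stats::var(.data$step)
    }, .groups = "drop") %>%
    filter(!is.na(.data$slope)) %>%
    arrange(.data$session_id, .data$sequence_id)
  pairs <- slopes %>%
    group_by(.data$session_id, .data$interest_rate) %>%
    mutate(adjacent = .data$sequence_id - dplyr::lag(.data$sequence_id) == 1,
           d_slope = .data$slope - dplyr::lag(.data$slope),
           d_inv_length = 1 / .data$sequence_length -
             1 / dplyr::lag(.data$sequence_length)) %>%
    ungroup() %>%
    filter(!is.na(.data$d_slope), .data$adjacent)
  if (nrow(pairs) == 0) abort("no qualifying consecutive sequence pairs")
  if (stats::var(pairs$d_inv_length) == 0) {
    abort("all consecutive pairs have equal lengths; regression undefined")
  }
  f <- ols_fit(cbind(1, d_inv = pairs$d_inv_length), pairs$d_slope)
  structure(list(
    pairs = select(pairs, "session_id", "interest_rate", "sequence_id",
                   "d_slope", "d_inv_length"),
    fit = tibble(coefficient = unname(f$estimate[2]),
                 p_value = unname(f$p_value[2]), r_squared = f$r_squared,
                 n_pairs = nrow(pairs))
  ), class = "consecutive_adaptation")
}

#' @exportS3Method generics::tidy
tidy.consecutive_adaptation <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.consecutive_adaptation <- function(x, ...) x$fit

#' @export
print.consecutive_adaptation <- function(x, ...) {
  cat("<consecutive_adaptation>", x$fit$n_pairs, "pairs; coefficient =",
      signif(x$fit$coefficient, 4), " p =", signif(x$fit$p_value, 3), "\n")
  invisible(x)
}

#' Progress coding around performance errors
#'
#' Regresses normalized activity on sequence progress separately for trials
#' immediately preceding an error, error trials themselves, and trials
#' immediately following an error, and compares the per-neuron coefficients
#' with dependent-samples t-tests. Attenuated progress coding on error trials
#' shows up as a pooled on-error/pre-error coefficient ratio below 1; the
#' pooled ratio and its delta-method standard error are returned so a
#' configured generator attenuation can be checked against the estimate.
#'
#' @param activity normalized activity tibble extracted with error trials
#'   included.
#' @param trials trial tibble (must contain error trials).
#' @return object of class `error_coding`: list with `pooled` (tibble of
#'   per-class pooled slope, se, n), `per_neuron` (tibble of per-neuron
#'   per-class slopes), `contrasts` (paired t-tests), `ratio` and
#'   `ratio_se` (on/pre pooled ratio).
#' @export
error_trial_coding <- function(activity, trials) {
  tr <- trials %>% arrange(.data$session_id, .data$trial_index)
  if (!any(tr$error)) abort("no error trials in input")
  cls <- tr %>%
    group_by(.data$session_id) %>%
    mutate(
      pre_error = !.data$error & dplyr::lead(.data$error, default = FALSE),
      post_error = !.data$error & dplyr::lag(.data$error, default = FALSE),
      class = dplyr::case_when(
        .data$error ~ "on_error",
        .data$pre_error ~ "pre_error",
        .data$post_error ~ "post_error",
        TRUE ~ NA_character_
      )
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$class)) %>%
    select("session_id", "trial_index", "step", "class")
  dat <- activity %>%
    dplyr::inner_join(cls, by = c("session_id", "trial_index"))
  slope_se <- function(d) {
    f <- ols_fit(cbind(1, step = d$step), d$z)
    if (isTRUE(f$degenerate)) tibble(slope = NA_real_, se = NA_real_, n = nrow(d))
    else tibble(slope = unname(f$estimate[2]), se = unname(f$se[2]), n = f$n)
  }
  pooled <- dat %>%
    group_by(class = .data$class) %>%
    dplyr::group_modify(~ slope_se(.x)) %>%
    ungroup()
  per_neuron <- dat %>%
    group_by(.data$neuron_id, .data$class) %>%
    dplyr::group_modify(~ slope_se(.x)) %>%
    ungroup() %>%
    select("neuron_id", "class", "slope") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "slope")
  pairt <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3) return(NA_real_)
    t.test(a[ok], b[ok], paired = TRUE)$p.value
  }
  contrasts <- tibble(
    contrast = c("pre_vs_on", "post_vs_on", "pre_vs_post"),
    p_value = c(pairt(per_neuron$pre_error, per_neuron$on_error),
                pairt(per_neuron$post_error, per_neuron$on_error),
                pairt(per_neuron$pre_error, per_neuron$post_error))
  )
  b_on <- pooled$slope[pooled$class == "on_error"]
  b_pre <- pooled$slope[pooled$class == "pre_error"]
  se_on <- pooled$se[pooled$class == "on_error"]
  se_pre <- pooled$se[pooled$class == "pre_error"]
  ratio <- b_on / b_pre
  ratio_se <- abs(ratio) * sqrt((se_on / b_on)^2 + (se_pre / b_pre)^2)
  structure(list(pooled = pooled, per_neuron = per_neuron,
                 contrasts = contrasts, ratio = ratio, ratio_se = ratio_se),
            class = "error_coding")
}

#' @exportS3Method generics::tidy
tidy.error_coding <- function(x, ...) x$pooled

#' @exportS3Method generics::glance
glance.error_coding <- function(x, ...) {
  tibble(ratio_on_pre = x$ratio, ratio_se = x$ratio_se)
}

#' @export
print.error_coding <- function(x, ...) {
  cat("<error_coding>\n")
  print(x$pooled)
  cat("on/pre slope ratio:", signif(x$ratio, 4), "+/-",
      signif(x$ratio_se, 4), "\n")
  invisible(x)
}
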