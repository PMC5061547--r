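#' Paired contest between two tuning models
#'
#' Compares two models response-by-response (same neuron, period and trials).
#' Among responses significant for both models, counts which model attains
#' the higher R-squared (exact ties count for neither) and runs a one-sample
#' t-test on the R-squared differences. Among responses significant for
#' exactly one model, computes the dependent-proportions z statistic
#' `z = (n_A_only - n_B_only) / sqrt(n_A_only + n_B_only)` (z = 0, p = 1 when
#' there are no discordant pairs). With `paired_scope = "all"` the win counts
#' use every jointly fitted response instead of the both-significant subset.
#'
#' @param fits_a,fits_b tidy fits from [fit_model()] for the two models.
#' @param paired_scope `"both_significant"` or `"all"`.
#' @param alpha significance criterion on `model_p_value`.
#' @return object of class `model_comparison`; see [tidy.model_comparison()].
#' @export
compare_models <- function(fits_a, fits_b,
                           paired_scope = c("both_significant", "all"),
                           alpha = 0.05) {
  paired_scope <- match.arg(paired_scope)
  squash <- function(f) {
    f %>% filter(!.data$degenerate) %>%
      distinct(.data$neuron_id, .data$period, .data$model,
               .data$r_squared, .data$model_p_value)
  }
  a <- squash(fits_a)
  b <- squash(fits_b)
  j <- dplyr::inner_join(a, b, by = c("neuron_id", "period"),
                         suffix = c("_a", "_b")) %>%
    mutate(sig_a = .data$model_p_value_a < alpha,
           sig_b = .data$model_p_value_b < alpha)
  scope <- if (paired_scope == "both_significant") {
    filter(j, .data$sig_a, .data$sig_b)
  } else j
  wins_a <- sum(scope$r_squared_a > scope$r_squared_b)
  wins_b <- sum(scope$r_squared_b > scope$r_squared_a)
  d <- scope$r_squared_a - scope$r_squared_b
  shift <- if (length(d) >= 2 && stats::sd(d) > 0) t.test(d) else NULL
  n_a_only <- sum(j$sig_a & !j$sig_b)
  n_b_only <- sum(j$sig_b & !j$sig_a)
  if (n_a_only + n_b_only == 0) {
    z <- 0; z_p <- 1
  } else {
    z <- (n_a_only - n_b_only) / sqrt(n_a_only + n_b_only)
    z_p <- 2 * pnorm(-abs(z))
  }
  structure(list(
    model_a = a$model[1], model_b = b$model[1],
    n_paired = nrow(j), n_scope = nrow(scope),
    wins_a = wins_a, wins_b = wins_b,
    n_a_only = n_a_only, n_b_only = n_b_only,
    discordant_z = z, discordant_p = z_p,
    r2_diff_mean = if (length(d)) mean(d) else NA_real_,
    r2_diff_p = if (!is.null(shift)) shift$p.value else NA_real_,
    r2_diff = d
  ), class = "model_comparison")
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  tibble(
    model_a = x$model_a, model_b = x$model_b, n_paired = x$n_paired,
    n_scope = x$n_scope, wins_a = x$wins_a, wins_b = x$wins_b,
    n_a_only = x$n_a_only, n_b_only = x$n_b_only,
    discordant_z = x$discordant_z, discordant_p = x$discordant_p,
    r2_diff_mean = x$r2_diff_mean, r2_diff_p = x$r2_diff_p
  )
}

#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) tidy(x)

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", x$model_a, "vs", x$model_b, "\n")
  cat("  higher R2:", x$wins_a, "vs", x$wins_b, "of", x$n_scope, "responses\n")
  cat("  discordant z =", signif(x$discordant_z, 4),
      " p =", signif(x$discordant_p, 3), "\n")
  invisible(x)
}

#' Free-choice vs imperative contrast of model-fit differences
#'
#' For responses fitted in both tasks, compares the per-response R-squared
#' difference between two models across tasks with a paired t-test (the
#' published contrast showing that the adaptive model's advantage is specific
#' to self-determined sequences).
#'
#' @param comparison_free,comparison_imp `model_comparison` objects built on
#'   matched response sets from the two tasks.
#' @return one-row tibble with the mean difference-in-differences and paired
#'   t-test p-value.
#' @export
task_contrast <- function(comparison_free, comparison_imp) {
  df <- comparison_free$r2_diff
  di <- comparison_imp$r2_diff
  n <- min(length(df), length(di))
  if (n < 2) abort("need at least two paired responses per task")
  tt <- t.test(df[seq_len(n)], di[seq_len(n)], paired = TRUE)
  tibble(mean_free = mean(df), mean_imp = mean(di),
         mean_contrast = mean(df[seq_len(n)] - di[seq_len(n)]),
         p_value = tt$p.value, n = n)
}
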