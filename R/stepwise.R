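# p-value-driven stepwise OLS: forward entry at p_enter, backward removal at
# p_remove, on an intercept-always design. Collinear candidates (rank
# deficiency on entry) are skipped, so later-entering redundant columns drop.
stepwise_ols <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  terms_all <- colnames(X)
  inside <- character()
  repeat {
    changed <- FALSE
    # forward
    cand <- setdiff(terms_all, inside)
    if (length(cand)) {
      ps <- vapply(cand, function(tm) {
        Xi <- cbind(`(Intercept)` = 1, X[, c(inside, tm), drop = FALSE])
        f <- ols_fit(Xi, y)
        if (isTRUE(f$degenerate)) return(NA_real_)
        unname(f$p_value[length(f$p_value)])
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        inside <- c(inside, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward
    if (length(inside) > 1 || (length(inside) == 1 && !changed)) {
      Xi <- cbind(`(Intercept)` = 1, X[, inside, drop = FALSE])
      f <- ols_fit(Xi, y)
      if (!isTRUE(f$degenerate)) {
        ps <- f$p_value[-1]
        if (length(ps) && max(ps) > p_remove) {
          inside <- setdiff(inside, inside[which.max(ps)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  inside
}

#' Stepwise multiple regression with task and value covariates
#'
#' Fits the full multiple-regression model of trial-by-trial activity on
#' save/spend choice, spend value, save value, sequence value, sequence
#' length, cue position, saccade side and sequence progress — optionally with
#' the two reaction-time measures as additional covariates — separately for
#' every (neuron, period) response. By default regressors are selected
#' stepwise (p-to-enter 0.05, p-to-remove 0.10); `method = "simultaneous"`
#' forces standard estimation of all coefficients. An all-noise response
#' yields an intercept-only (empty) model under stepwise selection.
#'
#' @inheritParams fit_model
#' @param include_rts add `rt_key` and `rt_saccade` covariates.
#' @param method `"stepwise"` or `"simultaneous"`.
#' @param progress_regressor `"progress"` (raw) or `"adaptive_progress"`.
#' @return tidy tibble as in [fit_model()] (one row per retained term;
#'   a single all-NA `term` row marks an empty model), `model = "eq7"`.
#' @export
fit_stepwise <- function(counts, trials, include_rts = FALSE,
                         method = c("stepwise", "simultaneous"),
                         progress_regressor = "progress",
                         sv = NULL, response = "rate") {
  method <- match.arg(method)
  dm <- design_matrix(trials, sv = sv)
  terms <- c("choice_spend", "sv_spend", "sv_save", "seq_sv", "seq_length",
             "cue_save_left", "action_left", progress_regressor)
  if (include_rts) terms <- c(terms, intersect(c("rt_key", "rt_saccade"), names(dm)))
  dat <- counts %>% dplyr::inner_join(dm, by = c("session_id", "trial_index"))
  dat %>%
    group_by(.data$neuron_id, .data$period) %>%
    dplyr::group_modify(function(d, key) {
      X <- as.matrix(d[, terms, drop = FALSE])
      y <- d[[response]]
      empty <- tibble(term = NA_character_, estimate = NA_real_,
                      std_estimate = NA_real_, p_value = NA_real_,
                      r_squared = 0, adj_r_squared = 0,
                      bic = NA_real_, model_p_value = 1, n_trials = length(y),
                      degenerate = FALSE)
      if (nrow(X) <= ncol(X) + 1) return(mutate(empty, degenerate = TRUE))
      kept <- if (method == "stepwise") stepwise_ols(X, y) else colnames(X)
      if (length(kept) == 0) return(empty)
      f <- ols_fit(cbind(`(Intercept)` = 1, X[, kept, drop = FALSE]), y)
      if (isTRUE(f$degenerate)) {
        # simultaneous fit with redundant value regressors: drop later columns
        keep <- kept
        while (length(keep) > 1) {
          f <- ols_fit(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]), y)
          if (!isTRUE(f$degenerate)) break
          keep <- keep[-length(keep)]
        }
        if (isTRUE(f$degenerate)) return(mutate(empty, degenerate = TRUE))
      }
      sel <- f$term != "(Intercept)"
      tibble(term = f$term[sel], estimate = unname(f$estimate[sel]),
             std_estimate = unname(f$std_estimate[sel]),
             p_value = unname(f$p_value[sel]),
             r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
             bic = f$bic, model_p_value = f$model_p, n_trials = f$n, degenerate = FALSE)
    }) %>%
    ungroup() %>%
    mutate(model = "eq7", .after = "period")
}
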