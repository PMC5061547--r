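#' Assemble a pseudo-population for progress decoding
#'
#' Splits every neuron's correct trials (in one task period) into low /
#' medium / high progress groups using per-neuron progress terciles (boundary
#' values go to the lower group; `n_groups = 4` gives quartiles). Neurons
#' with fewer than `min_trials` trials in any group are excluded. Because
#' neurons were not recorded simultaneously, trials are matched up at random
#' within each group; every group matrix gets the same number of rows (the
#' minimum trial count over all neuron-group cells, so chance is exactly
#' 1/n_groups), and the matching is repeated `n_matchings` times at decode
#' time.
#'
#' @param activity z-normalized activity tibble (no pre-selection for tuning).
#' @param trials trial tibble.
#' @param period task period to decode.
#' @param n_groups number of progress groups (3 = terciles).
#' @param min_trials minimum trials per group for a neuron to be included.
#' @param n_matchings random within-group trial matchings per decode.
#' @param seed integer seed for matching and classifier tie-free ordering.
#' @return object of class `pseudo_population`.
#' @export
build_pseudopopulation <- function(activity, trials, period = "delay",
                                   n_groups = 3, min_trials = 5,
                                   n_matchings = 150, seed = 1,
                                   allow_single = FALSE) {
  per <- period
  dat <- activity %>%
    filter(.data$period == per) %>%
    dplyr::inner_join(select(trials, "session_id", "trial_index", "step",
                             "error"),
                      by = c("session_id", "trial_index")) %>%
    filter(!.data$error)
  grouped <- dat %>%
    group_by(.data$neuron_id) %>%
    mutate(group = {
      qs <- quantile(.data$step, probs = seq_len(n_groups - 1) / n_groups,
                     type = 7)
      1L + findInterval(.data$step, qs, left.open = TRUE)
    }) %>%
    ungroup()
  counts_per <- grouped %>%
    count(.data$neuron_id, .data$group) %>%
    tidyr::complete(.data$neuron_id, group = seq_len(n_groups),
                    fill = list(n = 0L))
  ok_ids <- counts_per %>%
    group_by(.data$neuron_id) %>%
    summarise(min_n = min(.data$n), .groups = "drop") %>%
    filter(.data$min_n >= min_trials) %>%
    pull("neuron_id")
  if (length(ok_ids) < if (allow_single) 1 else 2) {
    abort("fewer than 2 neurons survive the per-group trial minimum")
  }
  grouped <- filter(grouped, .data$neuron_id %in% ok_ids)
  values <- grouped %>%
    arrange(.data$neuron_id, .data$group, .data$session_id, .data$trial_index) %>%
    group_by(.data$neuron_id, .data$group) %>%
    summarise(z = list(.data$z), .groups = "drop")
  # one shared m: each group matrix has the same number of rows, the minimum
  # trial count over all (neuron, group) cells
  m_all <- min(lengths(values$z))
  group_sizes <- tibble(group = seq_len(n_groups), m = m_all)
  structure(list(
    values = values, group_sizes = group_sizes,
    neurons = tibble(neuron_id = sort(unique(values$neuron_id))),
    n_groups = n_groups, min_trials = min_trials,
    n_matchings = n_matchings, period = period, seed = as.integer(seed)
  ), class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat("<pseudo_population>", nrow(x$neurons), "neurons,", x$n_groups,
      "progress groups (", paste(x$group_sizes$m, collapse = "/"),
      "trials ), period", x$period, "\n")
  invisible(x)
}

# one random within-group trial matching -> list(X = trials x neurons, y)
matching_matrices <- function(pop) {
  ids <- pop$neurons$neuron_id
  vals <- split(pop$values, pop$values$neuron_id)
  Xs <- list(); ys <- list()
  for (g in seq_len(pop$n_groups)) {
    m <- pop$group_sizes$m[pop$group_sizes$group == g]
    cols <- lapply(ids, function(id) {
      v <- vals[[id]]
      zz <- v$z[[which(v$group == g)]]
      zz[sample.int(length(zz), m)]
    })
    Xs[[g]] <- do.call(cbind, cols)
    ys[[g]] <- rep(g, m)
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

# leave-one-out nearest-neighbor (Euclidean) accuracy; distance ties go to
# the earliest trial in the stable row order
nn_loo_accuracy <- function(X, y) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  pred <- y[apply(D, 1, which.min)]
  100 * mean(pred == y)
}

svm_loo_accuracy <- function(X, y) {
  n <- nrow(X)
  correct <- vapply(seq_len(n), function(i) {
    fit <- e1071::svm(X[-i, , drop = FALSE], factor(y[-i]), kernel = "linear",
                      scale = FALSE)
    as.character(stats::predict(fit, X[i, , drop = FALSE])) == as.character(y[i])
  }, logical(1))
  100 * mean(correct)
}

split_accuracy <- function(X, y, classifier, train_frac = 0.8) {
  n <- nrow(X)
  tr <- sort(sample.int(n, max(2, floor(train_frac * n))))
  te <- setdiff(seq_len(n), tr)
  if (length(te) == 0) te <- tr[1]
  if (classifier == "nearest_neighbor") {
    D <- as.matrix(stats::dist(X))[te, tr, drop = FALSE]
    pred <- y[tr][apply(D, 1, which.min)]
  } else {
    fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]), kernel = "linear",
                      scale = FALSE)
    pred <- as.integer(as.character(stats::predict(fit, X[te, , drop = FALSE])))
  }
  100 * mean(pred == y[te])
}

#' Decode sequence progress from a pseudo-population
#'
#' Cross-validated classification of progress group from population activity
#' vectors, repeated over random within-group trial matchings. The
#' nearest-neighbor classifier assigns each held-out trial to the group of
#' its Euclidean nearest neighbor; the linear max-margin classifier is a
#' linear-kernel support vector machine. Leave-one-out cross-validation is
#' the default; an 80/20 split is available as `cv = "split"`. Accuracy is
#' the percentage of correctly classified trials, fold-averaged within each
#' matching and then summarized across matchings.
#'
#' @param pop a [build_pseudopopulation()] object.
#' @param classifier `"nearest_neighbor"` or `"linear_max_margin"`.
#' @param cv `"leave_one_out"` or `"split"`.
#' @return object of class `decoding_result` with per-matching accuracies.
#' @export
decode <- function(pop, classifier = c("nearest_neighbor", "linear_max_margin"),
                   cv = c("leave_one_out", "split")) {
  classifier <- match.arg(classifier)
  cv <- match.arg(cv)
  set.seed(pop$seed)
  acc <- vapply(seq_len(pop$n_matchings), function(i) {
    mm <- matching_matrices(pop)
    if (cv == "leave_one_out") {
      if (classifier == "nearest_neighbor") nn_loo_accuracy(mm$X, mm$y)
      else svm_loo_accuracy(mm$X, mm$y)
    } else {
      split_accuracy(mm$X, mm$y, classifier)
    }
  }, numeric(1))
  structure(list(
    accuracies = acc, mean = mean(acc),
    sem = stats::sd(acc) / sqrt(length(acc)),
    classifier = classifier, cv = cv, n_groups = pop$n_groups,
    chance = 100 / pop$n_groups, n_neurons = nrow(pop$neurons),
    period = pop$period
  ), class = "decoding_result")
}

#' @exportS3Method generics::tidy
tidy.decoding_result <- function(x, ...) {
  tibble(matching = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @exportS3Method generics::glance
glance.decoding_result <- function(x, ...) {
  tibble(classifier = x$classifier, accuracy_mean = x$mean,
         accuracy_sem = x$sem, chance = x$chance, n_neurons = x$n_neurons,
         n_matchings = length(x$accuracies),
         null_mean = if (is.null(x$null_accuracies)) NA_real_
                     else mean(x$null_accuracies),
         p_vs_null = x$p_vs_null %||% NA_real_)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>", x$classifier, "(", x$cv, ")",
      sprintf("%.2f%% +/- %.2f (chance %.1f%%)", x$mean, x$sem, x$chance),
      "\n")
  if (!is.null(x$p_vs_null)) {
    cat("  vs shuffled labels: p =", signif(x$p_vs_null, 3), "\n")
  }
  invisible(x)
}

#' Shuffled-label null distribution for a decoding result
#'
#' Repeats the decoding with group labels shuffled without replacement (the
#' label multiset is preserved on every iteration) and compares the real
#' per-matching accuracies against the null accuracies with a two-sided
#' rank-sum test.
#'
#' @param pop the pseudo-population used for `result`.
#' @param result a [decode()] result.
#' @param n_iterations shuffle iterations (reference analyses use
#'   1500-5000; fewer than 100 triggers a power warning).
#' @return `result` with `null_accuracies` and `p_vs_null` filled in.
#' @export
shuffle_null <- function(pop, result, n_iterations = 500) {
  if (n_iterations < 100) warn("fewer than 100 shuffle iterations has low power")
  set.seed(pop$seed + 1L)
  nulls <- vapply(seq_len(n_iterations), function(i) {
    mm <- matching_matrices(pop)
    y_s <- sample(mm$y)
    if (result$cv == "leave_one_out") {
      if (result$classifier == "nearest_neighbor") nn_loo_accuracy(mm$X, y_s)
      else svm_loo_accuracy(mm$X, y_s)
    } else {
      split_accuracy(mm$X, y_s, result$classifier)
    }
  }, numeric(1))
  result$null_accuracies <- nulls
  result$p_vs_null <- suppressWarnings(
    stats::wilcox.test(result$accuracies, nulls)$p.value
  )
  result
}

#' Decoding accuracy as a function of population size
#'
#' Randomly selects `size` neurons, rebuilds the pseudo-population and
#' decodes, repeating `iterations` times per size.
#'
#' @param activity,trials,period as in [build_pseudopopulation()].
#' @param sizes integer vector of neuron counts.
#' @param iterations random selections per size.
#' @param classifier classifier passed to [decode()].
#' @param n_matchings matchings per decode (small by default; the curve
#'   averages over selections).
#' @param min_trials per-group trial minimum.
#' @param seed integer seed.
#' @return tibble `size`, `accuracy_mean`, `accuracy_sem`.
#' @export
neuron_count_curve <- function(activity, trials, period = "delay",
                               sizes = c(1, 5, 10, 20), iterations = 100,
                               classifier = "nearest_neighbor",
                               n_matchings = 2, min_trials = 5, seed = 1) {
  if (any(sizes < 1)) abort("population sizes must be >= 1")
  ids <- unique(activity$neuron_id)
  if (max(sizes) > length(ids)) abort("requested size exceeds available neurons")
  set.seed(seed)
  purrr::map_dfr(sizes, function(sz) {
    accs <- vapply(seq_len(iterations), function(i) {
      pick <- sample(ids, sz)
      act <- filter(activity, .data$neuron_id %in% pick)
      pop <- tryCatch(
        build_pseudopopulation(act, trials, period = period,
                               min_trials = min_trials,
                               n_matchings = n_matchings,
                               seed = sample.int(1e6, 1),
                               allow_single = TRUE),
        error = function(e) NULL
      )
      if (is.null(pop)) return(NA_real_)
      decode(pop, classifier)$mean
    }, numeric(1))
    accs <- accs[!is.na(accs)]
    tibble(size = sz, accuracy_mean = mean(accs),
           accuracy_sem = stats::sd(accs) / sqrt(length(accs)),
           n_ok = length(accs))
  })
}

#' Decoding from fixed-size neuron subsets and its covariates
#'
#' Draws subsets of `subset_size` neurons from three eligibility categories
#' (progress-significant, random, non-significant; categories with too few
#' eligible neurons are skipped with a message), decodes each subset, and
#' regresses subset accuracy on the subset's mean rectified progress slope,
#' the standard deviation of its progress slopes, and its fraction of
#' centromedial neurons.
#'
#' @param activity,trials,period as in [build_pseudopopulation()].
#' @param fits tidy eq2 fits providing per-neuron progress slopes and
#'   significance (the fit rows for `period` are used).
#' @param neurons roster tibble carrying `neuron_id` and `region`.
#' @param subset_size neurons per subset.
#' @param iterations subsets drawn per category.
#' @param classifier,n_matchings,min_trials,seed as in the other decoders.
#' @return list with `subsets` (per-subset accuracies and covariates),
#'   `by_category` (summary), `covariate_fit` (tidy OLS of accuracy on
#'   covariates over the random-category subsets).
#' @export
subset_analysis <- function(activity, trials, fits, neurons,
                            period = "delay", subset_size = 20,
                            iterations = 300,
                            classifier = "nearest_neighbor",
                            n_matchings = 2, min_trials = 5, seed = 1) {
  per <- period
  slopes <- fits %>%
    filter(.data$model == "eq2", .data$period == per, !.data$degenerate) %>%
    select("neuron_id", slope = "estimate", p_value = "p_value")
  info <- neurons %>%
    select("neuron_id", "region") %>%
    dplyr::inner_join(slopes, by = "neuron_id")
  eligible <- list(
    significant = info$neuron_id[info$p_value < 0.05],
    random = info$neuron_id,
    nonsignificant = info$neuron_id[info$p_value >= 0.05]
  )
  set.seed(seed)
  subsets <- purrr::imap_dfr(eligible, function(ids, cat) {
    if (length(ids) < subset_size) {
      inform(paste("category", cat, "has fewer than", subset_size,
                   "eligible neurons; skipped"))
      return(tibble())
    }
    purrr::map_dfr(seq_len(iterations), function(i) {
      pick <- sample(ids, subset_size)
      act <- filter(activity, .data$neuron_id %in% pick)
      pop <- tryCatch(
        build_pseudopopulation(act, trials, period = per,
                               min_trials = min_trials,
                               n_matchings = n_matchings,
                               seed = sample.int(1e6, 1)),
        error = function(e) NULL
      )
      if (is.null(pop)) return(tibble())
      sub <- info %>% filter(.data$neuron_id %in% pick)
      tibble(
        category = cat, iteration = i,
        accuracy = decode(pop, classifier)$mean,
        mean_abs_slope = mean(abs(sub$slope)),
        sd_slope = stats::sd(sub$slope),
        frac_centromedial = mean(sub$region == "centromedial")
      )
    })
  })
  by_category <- subsets %>%
    group_by(.data$category) %>%
    summarise(accuracy_mean = mean(.data$accuracy),
              accuracy_sem = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop")
  rnd <- filter(subsets, .data$category == "random")
  covariate_fit <- NULL
  if (nrow(rnd) > 4) {
    X <- cbind(`(Intercept)` = 1, mean_abs_slope = rnd$mean_abs_slope,
               sd_slope = rnd$sd_slope,
               frac_centromedial = rnd$frac_centromedial)
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 0)
    f <- ols_fit(X[, keep, drop = FALSE], rnd$accuracy)
    if (!isTRUE(f$degenerate)) {
      covariate_fit <- tibble(term = f$term, estimate = unname(f$estimate),
                              std_estimate = unname(f$std_estimate),
                              p_value = unname(f$p_value),
                              r_squared = f$r_squared)
    }
  }
  list(subsets = subsets, by_category = by_category,
       covariate_fit = covariate_fit)
}
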