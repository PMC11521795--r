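# Cross-validated decoding of the traveled path: per-condition Poisson or
# Hawkes models are fitted on 2/3 of each condition's trials and each
# held-out trial is assigned the condition whose model minimizes the
# held-out least-squares contrast, summed over units.

#' Session eligibility for the decoding analysis
#'
#' A session enters the decoding analysis when it has at least 2
#' full-path coding units and at least 2 distinct path labels each
#' repeated at least 3 times.
#'
#' @param traversals classified traversal table.
#' @param coding full-path coding table from [detect_coding_units()].
#' @param min_coders,min_conditions,min_trials rule thresholds.
#' @return list with `eligible` (logical) and `reasons` (character,
#'   empty when eligible).
#' @export
session_eligibility <- function(traversals, coding, min_coders = 2,
                                min_conditions = 2, min_trials = 3) {
  reasons <- character(0)
  n_coders <- sum(coding$coding, na.rm = TRUE)
  if (n_coders < min_coders) {
    reasons <- c(reasons, sprintf("fewer than %d full-path coding units (%d)",
                                  min_coders, n_coders))
  }
  cls <- traversals[traversals$label != "unclassified", , drop = FALSE]
  reps <- table(cls$label)
  n_ok <- sum(reps >= min_trials)
  if (n_ok < min_conditions) {
    reasons <- c(reasons, sprintf(
      "fewer than %d distinct paths repeated >= %d times (%d)",
      min_conditions, min_trials, n_ok
    ))
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Split trials into train and test sets per condition
#'
#' Conditions with fewer than 3 trials are dropped from decoding. Per
#' retained condition with m trials, `ceiling(fraction * m)` trials go to
#' training (capped at m - 1 so at least one test trial remains):
#' chronologically first by default, or a seeded random subset.
#'
#' @param trials tibble with `condition`, `start`, `end` (one row per
#'   trial).
#' @param fraction training fraction in (0, 1) (default 2/3).
#' @param policy `"chronological"` or `"random"`.
#' @param seed seed for the random policy.
#' @param min_trials minimum trials per retained condition (default 3).
#' @return the input with a `split` column (`"train"`, `"test"`,
#'   `"dropped"`).
#' @export
split_trials <- function(trials, fraction = 2 / 3,
                         policy = c("chronological", "random"),
                         seed = NULL, min_trials = 3) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  policy <- match.arg(policy)
  local_seed(seed, {
    trials$split <- "dropped"
    for (k in unique(trials$condition)) {
      idx <- which(trials$condition == k)
      m <- length(idx)
      if (m < min_trials) next
      n_train <- min(ceiling(fraction * m), m - 1)
      ord <- idx[order(trials$start[idx])]
      tr <- switch(policy,
        chronological = ord[seq_len(n_train)],
        random = sort(sample(idx, n_train))
      )
      trials$split[idx] <- "test"
      trials$split[tr] <- "train"
    }
    trials
  })
}

#' Decode one trial by held-out contrast minimization
#'
#' For each candidate condition, the trial's contrast is the sum over
#' units of the fitted model's least-squares contrast restricted to the
#' trial window; the decoded condition minimizes it. Ties are broken
#' toward the first candidate in `models` order (logged).
#'
#' @param models named list (one element per candidate condition); each
#'   element is a list of per-unit fits (`"poisson_fit"` or
#'   `"hawkes_fit"` objects).
#' @param spike_list all units' spike trains (full session; histories may
#'   extend before the trial).
#' @param trial one-row tibble/list with `start`, `end`.
#' @return list with `k_hat` and the named `contrasts` vector.
#' @export
decode_trial <- function(models, spike_list, trial) {
  if (length(models) < 1) abort("no candidate models")
  iv <- tibble::tibble(start = trial$start, end = trial$end)
  first <- models[[1]][[1]]
  contrasts <- if (inherits(first, "hawkes_fit")) {
    des <- build_design(spike_list, iv)
    vapply(models, function(fits) {
      sum(vapply(fits, function(f) {
        contrast_from_design(f$theta, des$G, des$b[, f$target])
      }, numeric(1)))
    }, numeric(1))
  } else {
    D <- interval_duration(iv)
    counts <- vapply(spike_list, function(s) count_in_intervals(s, iv),
                     numeric(1))
    vapply(models, function(fits) {
      sum(vapply(seq_along(fits), function(n) {
        nu <- fits[[n]]$rate
        -2 * counts[n] * nu + nu^2 * D
      }, numeric(1)))
    }, numeric(1))
  }
  k_hat <- names(contrasts)[which.min(contrasts)]
  if (sum(contrasts == min(contrasts)) > 1) {
    inform("decode_trial: tie broken toward the first candidate condition")
  }
  list(k_hat = k_hat, contrasts = contrasts)
}

#' Cross-validated decoding power of a session
#'
#' Fits per-condition models of the requested class on the training
#' trials of every retained condition, decodes all held-out trials, and
#' reports the proportion of correct guesses together with the
#' random-guess reference `1 / NbPaths` and the covariates used by
#' downstream regressions (number of paths, number of units, mean firing
#' rate).
#'
#' @param spike_list list of the included units' spike trains (full
#'   session).
#' @param traversals classified traversal table.
#' @param model `"poisson"` or `"hawkes"`.
#' @inheritParams split_trials
#' @param session_duration session length in seconds (for the mean-rate
#'   covariate; defaults to the last spike time).
#' @return object of class `"decoding_result"`: per-trial predictions,
#'   `power`, `reference`, covariates and the split used.
#' @export
session_decoding_power <- function(spike_list, traversals,
                                   model = c("poisson", "hawkes"),
                                   fraction = 2 / 3,
                                   policy = "chronological", seed = NULL,
                                   min_trials = 3,
                                   session_duration = NULL) {
  model <- match.arg(model)
  trials <- build_condition_intervals(traversals)
  trials <- split_trials(trials, fraction, policy, seed, min_trials)
  kept <- trials[trials$split != "dropped", , drop = FALSE]
  conds <- unique(kept$condition)
  if (length(conds) < 2) {
    abort("need at least 2 conditions with enough trials to decode")
  }
  if (sum(kept$split == "test") == 0) abort("no test trials")
  fits <- lapply(conds, function(k) {
    iv <- kept[kept$condition == k & kept$split == "train",
               c("start", "end")]
    iv <- dplyr::arrange(iv, .data$start)
    if (model == "poisson") {
      lapply(spike_list, fit_poisson, intervals = iv)
    } else {
      des <- build_design(spike_list, iv)
      lapply(seq_along(spike_list), function(n) fit_hawkes(des, target = n))
    }
  })
  names(fits) <- conds
  test <- kept[kept$split == "test", , drop = FALSE]
  test <- dplyr::arrange(test, .data$start)
  preds <- lapply(seq_len(nrow(test)), function(j) {
    decode_trial(fits, spike_list, test[j, ])
  })
  test$predicted <- vapply(preds, function(p) p$k_hat, character(1))
  power <- mean(test$predicted == test$condition)
  if (is.null(session_duration)) {
    session_duration <- max(c(0, unlist(spike_list, use.names = FALSE)))
  }
  mean_rate <- mean(vapply(spike_list, length, numeric(1))) /
    max(session_duration, 1e-12)
  structure(
    list(
      trials = test[, c("condition", "start", "end", "predicted")],
      contrasts = lapply(preds, function(p) p$contrasts),
      power = power, reference = 1 / length(conds), model = model,
      n_paths = length(conds), n_units = length(spike_list),
      mean_rate = mean_rate, split = trials
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "%s decoding: power %.3f over %d test trials (%d paths, reference %.3f)\n",
    x$model, x$power, nrow(x$trials), x$n_paths, x$reference
  ))
  invisible(x)
}
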