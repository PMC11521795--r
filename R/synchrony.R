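# Pairwise spike synchrony at maze intersections: coincidence counting in
# 500 ms trials, trial-permutation p-values, and KS comparisons of the
# resulting p-value distributions.

#' Count spike coincidences within trials
#'
#' A coincidence is an unordered pair of spikes, one from each unit,
#' inside the same trial window and at most `delta` apart (boundary
#' inclusive, sliding window, not binned). Cross-trial pairs are never
#' counted.
#'
#' @param train_a,train_b sorted spike-time vectors.
#' @param trials disjoint trial windows (tibble with `start`, `end`).
#' @param delta coincidence window in seconds (default 0.020).
#' @return integer coincidence count.
#' @export
count_coincidences <- function(train_a, train_b, trials, delta = 0.020) {
  iv <- as_intervals(trials)
  if (!intervals_disjoint(iv)) abort("trials must be disjoint")
  total <- 0L
  for (j in seq_len(nrow(iv))) {
    a <- train_a[train_a >= iv$start[j] & train_a < iv$end[j]]
    b <- train_b[train_b >= iv$start[j] & train_b < iv$end[j]]
    if (length(a) && length(b)) {
      total <- total + sum(abs(outer(a, b, "-")) <= delta + 1e-12)
    }
  }
  total
}

# Coincidence counts for every (trial of a) x (trial of b) re-pairing,
# with spike times re-expressed relative to each trial's window start so
# that window offsets cancel.
coincidence_matrix <- function(train_a, train_b, trials, delta = 0.020) {
  iv <- as_intervals(trials)
  n <- nrow(iv)
  rel <- function(train) {
    lapply(seq_len(n), function(j) {
      train[train >= iv$start[j] & train < iv$end[j]] - iv$start[j]
    })
  }
  ra <- rel(train_a)
  rb <- rel(train_b)
  C <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    if (length(ra[[i]]) == 0) next
    for (j in seq_len(n)) {
      if (length(rb[[j]]) == 0) next
      C[i, j] <- sum(abs(outer(ra[[i]], rb[[j]], "-")) <= delta + 1e-12)
    }
  }
  C
}

#' Trial-permutation synchrony test for a pair of units
#'
#' The observed within-trial coincidence count is compared to the null
#' distribution obtained by re-pairing trial i of unit a with trial
#' pi(i) of unit b for uniformly random permutations pi (identity
#' allowed). The one-sided (excess coincidences) p-value uses the add-one
#' rule `p = (1 + #{perm >= obs}) / (n_perm + 1)`, which keeps the test
#' valid and bounds p below by `1 / (n_perm + 1)`.
#'
#' @inheritParams count_coincidences
#' @param n_perm number of permutations (default 50000).
#' @param seed optional seed.
#' @return one-row tibble: `n_trials`, `observed`, `p_value`, `n_perm`.
#' @export
test_synchrony <- function(train_a, train_b, trials, n_perm = 50000,
                           delta = 0.020, seed = NULL) {
  iv <- as_intervals(trials)
  n <- nrow(iv)
  if (n < 2) {
    inform("test_synchrony: fewer than 2 trials, test undefined")
    return(tibble::tibble(n_trials = n, observed = NA_integer_,
                          p_value = NA_real_, n_perm = n_perm))
  }
  C <- coincidence_matrix(train_a, train_b, trials, delta)
  obs <- sum(diag(C))
  rows <- seq_len(n)
  local_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      cnt <- sum(C[cbind(rows, sample.int(n))])
      if (cnt >= obs) exceed <- exceed + 1L
    }
    tibble::tibble(
      n_trials = n, observed = obs,
      p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm
    )
  })
}

#' KS tests on grouped synchrony p-value distributions
#'
#' Per group, a one-sided Kolmogorov-Smirnov test of uniformity (D+;
#' alternative: the empirical CDF lies above the diagonal, i.e. p-values
#' are stochastically small). Additionally, for every combination of the
#' non-region grouping variables, a one-sided two-sample KS test that the
#' first region's p-values are stochastically smaller than the second's.
#' All p-values are BH-adjusted jointly.
#'
#' @param pvals tibble containing a `p_value` column and grouping
#'   columns.
#' @param group_cols names of the grouping columns (default all except
#'   `p_value`).
#' @param region_col grouping column holding the two populations for the
#'   two-sample comparisons (default `"region"` if present).
#' @return tibble: `test`, `group`, `n`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
sync_ks_tests <- function(pvals, group_cols = NULL, region_col = NULL) {
  if (is.null(group_cols)) group_cols <- setdiff(names(pvals), "p_value")
  if (is.null(region_col) && "region" %in% group_cols) region_col <- "region"
  key <- function(df, cols) {
    if (length(cols) == 0) rep("all", nrow(df)) else
      do.call(paste, c(df[cols], sep = ":"))
  }
  out <- list()
  grp <- key(pvals, group_cols)
  for (g in unique(grp)) {
    x <- pvals$p_value[grp == g]
    if (length(x) < 5) warn(sprintf("group %s has fewer than 5 p-values", g))
    kt <- suppressWarnings(
      ks.test(x, "punif", alternative = "greater", exact = FALSE)
    )
    out[[length(out) + 1]] <- tibble::tibble(
      test = "uniformity", group = g, n = length(x),
      statistic = unname(kt$statistic), p_value = kt$p.value
    )
  }
  if (!is.null(region_col)) {
    other <- setdiff(group_cols, region_col)
    regions <- sort(unique(pvals[[region_col]]))
    if (length(regions) == 2) {
      og <- key(pvals, other)
      for (g in unique(og)) {
        x <- pvals$p_value[og == g & pvals[[region_col]] == regions[1]]
        y <- pvals$p_value[og == g & pvals[[region_col]] == regions[2]]
        if (length(x) == 0 || length(y) == 0) next
        kt <- suppressWarnings(
          ks.test(x, y, alternative = "greater", exact = FALSE)
        )
        out[[length(out) + 1]] <- tibble::tibble(
          test = paste0("two_sample_", regions[1], "_vs_", regions[2]),
          group = g, n = length(x) + length(y),
          statistic = unname(kt$statistic), p_value = kt$p.value
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}
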