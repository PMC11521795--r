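# Chi-squared multinomial detection of coding neurons.
#
# Under the null of a constant firing rate, the per-condition spike counts
# (N_1, ..., N_K) are multinomial with probabilities p_k proportional to
# the condition durations d_k and total n = sum(N_k). The chi-squared
# statistic sum (N_k - n p_k)^2 / (n p_k) with K - 1 degrees of freedom
# tests departures from this null; the test is valid when every expected
# count n p_k is at least 5, which drives the merge/drop policy below.

#' Build a per-condition spike-count table
#'
#' Three analysis modes:
#' \describe{
#'   \item{task_event}{K = 30 conditions, the five 100 ms bins of the six
#'     500 ms task events; `d_k = 0.1 * n_passages(event)`.}
#'   \item{left_right}{K = 2 conditions, spikes on the central stem split
#'     by the upcoming turn; `d_k` = total stem-run time per turn.}
#'   \item{full_path}{K <= 12 conditions, one per elementary path actually
#'     taken; `d_k` = total time spent in traversals of that path
#'     (untaken paths are omitted).}
#' }
#'
#' @param spikes numeric vector of one unit's sorted spike times.
#' @param frames behavioral frames from [behavior_frames()].
#' @param mode one of `"task_event"`, `"left_right"`, `"full_path"`.
#' @return tibble of class `"condition_counts"` with columns `condition`,
#'   `n_spikes`, `duration_s` and attributes `mode`, `merge_group`.
#' @export
build_condition_table <- function(spikes, frames,
                                  mode = c("task_event", "left_right",
                                           "full_path")) {
  mode <- match.arg(mode)
  if (mode == "task_event") {
    bins <- frames$bins
    if (is.null(bins) || nrow(bins) == 0) {
      abort("task_event mode requires event windows")
    }
    n_pass <- table(frames$events$event)
    grid <- tidyr::crossing(event = task_events(), bin = 1:5)
    counts <- vapply(seq_len(nrow(grid)), function(r) {
      sel <- bins[bins$event == grid$event[r] & bins$bin == grid$bin[r],
                  c("start", "end")]
      count_in_intervals(spikes, sel)
    }, numeric(1))
    pass <- as.numeric(n_pass[grid$event])
    pass[is.na(pass)] <- 0
    out <- tibble::tibble(
      condition = paste0(grid$event, ".", grid$bin),
      n_spikes = counts, duration_s = 0.1 * pass
    )
    out <- out[out$duration_s > 0, , drop = FALSE]
    merge_group <- sub("\\..*$", "", out$condition)
  } else if (mode == "left_right") {
    stem <- frames$stem
    if (is.null(stem) || nrow(stem) == 0) {
      abort("left_right mode requires central-stem runs")
    }
    out <- dplyr::bind_rows(lapply(c("left", "right"), function(side) {
      iv <- stem[stem$turn == side, c("start", "end")]
      tibble::tibble(
        condition = side,
        n_spikes = count_in_intervals(spikes, iv),
        duration_s = interval_duration(iv)
      )
    }))
    out <- out[out$duration_s > 0, , drop = FALSE]
    merge_group <- NULL
  } else {
    trav <- frames$traversals
    trav <- trav[trav$label != "unclassified", , drop = FALSE]
    if (nrow(trav) == 0) abort("full_path mode requires classified traversals")
    labs <- unique(trav$label)
    out <- dplyr::bind_rows(lapply(labs, function(lb) {
      iv <- trav[trav$label == lb, c("start_s", "end_s")]
      names(iv) <- c("start", "end")
      tibble::tibble(
        condition = lb,
        n_spikes = count_in_intervals(spikes, iv),
        duration_s = interval_duration(iv)
      )
    }))
    merge_group <- NULL
  }
  structure(out, mode = mode, merge_group = merge_group,
            class = c("condition_counts", class(out)))
}

expected_counts <- function(counts) {
  n <- sum(counts$n_spikes)
  p <- counts$duration_s / sum(counts$duration_s)
  n * p
}

#' Apply the expected-count validity policy
#'
#' While any expected count `n p_k` falls below 5: in `task_event` mode
#' the 100 ms bins are first merged into their six parent events and the
#' unit is discarded if the rule is still violated; in `left_right` mode
#' the unit is discarded; in `full_path` mode the condition with the
#' smallest expected count is dropped (durations renormalize), and the
#' unit is discarded once fewer than two conditions remain.
#'
#' @param counts a `"condition_counts"` table.
#' @param min_expected validity threshold on expected counts (default 5).
#' @return the (possibly merged or reduced) table, with attributes
#'   `status` (`"tested"` or `"discarded"`) and `policy_trace`.
#' @export
apply_validity_policy <- function(counts, min_expected = 5) {
  mode <- attr(counts, "mode")
  trace <- character(0)
  finish <- function(x, status) {
    attr(x, "status") <- status
    attr(x, "policy_trace") <- trace
    x
  }
  if (sum(counts$n_spikes) == 0 || nrow(counts) < 2) {
    trace <- c(trace, "no spikes or fewer than 2 conditions")
    return(finish(counts, "discarded"))
  }
  if (all(expected_counts(counts) >= min_expected)) {
    return(finish(counts, "tested"))
  }
  if (mode == "task_event") {
    grp <- attr(counts, "merge_group")
    merged <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(
        condition = grp, n_spikes = counts$n_spikes,
        duration_s = counts$duration_s
      ), .data$condition),
      n_spikes = sum(.data$n_spikes),
      duration_s = sum(.data$duration_s), .groups = "drop"
    )
    merged <- structure(merged, mode = mode, merge_group = NULL,
                        class = class(counts))
    trace <- c(trace, "merged 100 ms bins into 6 event conditions")
    if (nrow(merged) >= 2 && all(expected_counts(merged) >= min_expected)) {
      return(finish(merged, "tested"))
    }
    trace <- c(trace, "expected counts still below threshold after merge")
    return(finish(merged, "discarded"))
  }
  if (mode == "left_right") {
    trace <- c(trace, "expected count below threshold with 2 conditions")
    return(finish(counts, "discarded"))
  }
  # full_path: drop offending conditions one at a time
  cur <- counts
  repeat {
    e <- expected_counts(cur)
    if (all(e >= min_expected)) {
      return(finish(cur, "tested"))
    }
    if (nrow(cur) <= 2) {
      trace <- c(trace, "rule violated with only two paths left")
      return(finish(cur, "discarded"))
    }
    drop <- which.min(e)
    trace <- c(trace, paste0("dropped path ", cur$condition[drop]))
    cur <- cur[-drop, , drop = FALSE]
  }
}

#' Chi-squared multinomial test of constant firing across conditions
#'
#' @param counts a validated `"condition_counts"` table (see
#'   [apply_validity_policy()]); discarded tables yield a row with status
#'   `"discarded"` and no p-value.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `status`,
#'   `policy_trace`, `n_conditions`, `n_spikes`.
#' @export
chi_square_multinomial_test <- function(counts) {
  status <- attr(counts, "status") %||% "tested"
  trace <- paste(attr(counts, "policy_trace"), collapse = "; ")
  n <- sum(counts$n_spikes)
  if (status == "discarded" || n == 0 || nrow(counts) < 2) {
    return(tibble::tibble(
      statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
      status = "discarded", policy_trace = trace,
      n_conditions = nrow(counts), n_spikes = n
    ))
  }
  e <- expected_counts(counts)
  stat <- sum((counts$n_spikes - e)^2 / e)
  df <- nrow(counts) - 1L
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    status = "tested", policy_trace = trace,
    n_conditions = nrow(counts), n_spikes = n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment with coding flags
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed,
#'   passed through unflagged).
#' @param alpha FDR level (default 0.05).
#' @return tibble with `p_value`, `p_adjusted`, `coding`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(p_value = numeric(0), p_adjusted = numeric(0),
                          coding = logical(0)))
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(
    p_value = p_values, p_adjusted = adj,
    coding = !is.na(adj) & adj < alpha
  )
}

#' Detect coding units in one analysis mode
#'
#' Runs the chi-squared condition pipeline (count table, validity policy,
#' test) for every unit and applies Benjamini-Hochberg correction across
#' all tested units.
#'
#' @param spikes tibble with `unit_id`, `time_s`.
#' @param frames behavioral frames from [behavior_frames()].
#' @param mode analysis mode (see [build_condition_table()]).
#' @param alpha FDR level for the coding flag.
#' @param unit_ids units to test (default: all units present in `spikes`).
#' @return tibble, one row per unit: test results, `p_adjusted`, `coding`.
#' @export
detect_coding_units <- function(spikes, frames, mode, alpha = 0.05,
                                unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  trains <- split(spikes$time_s, factor(spikes$unit_id, levels = unit_ids))
  res <- dplyr::bind_rows(lapply(seq_along(unit_ids), function(j) {
    tab <- apply_validity_policy(build_condition_table(trains[[j]], frames, mode))
    out <- chi_square_multinomial_test(tab)
    out$unit_id <- unit_ids[j]
    out
  }))
  adj <- bh_adjust(res$p_value, alpha)
  res$p_adjusted <- adj$p_adjusted
  res$coding <- adj$coding
  res$mode <- mode
  res[, c("unit_id", "mode", "statistic", "df", "p_value", "p_adjusted",
          "coding", "status", "n_conditions", "n_spikes", "policy_trace")]
}
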