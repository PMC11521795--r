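# Behavior: zone timelines -> elementary paths, performance, learning
# stages, and the six 500 ms task-event windows.
#
# The continuous T-maze is summarised by four zones: the two feeders F1/F2
# at the ends of the goal arms and the two intersections A (base of the
# central stem) and B (choice point at the top of the stem). A zone
# timeline records zone *entries*; a zone is occupied from its entry until
# the next entry.

#' Default elementary-path taxonomy
#'
#' The 12 stereotyped feeder-to-feeder trajectories on the continuous
#' T-maze: 2 correct alternations plus 10 incorrect paths (same-side
#' returns, base/top crossings, reverse-stem returns and feeder u-turns),
#' each encoded as a node sequence over the zones F1, A, B, F2.
#'
#' @param mean_durations optional named numeric vector of mean traversal
#'   durations in seconds (used by the synthetic-data generator).
#' @return A tibble with columns `label`, `nodes` (list of character
#'   vectors), `correct` and `mean_duration`.
#' @export
#' @examples
#' path_taxonomy()
path_taxonomy <- function(mean_durations = NULL) {
  tax <- tibble::tibble(
    label = c(
      "correct_1", "correct_2",
      "return_1", "return_2",
      "cross_base_1", "cross_base_2",
      "cross_top_1", "cross_top_2",
      "reverse_1", "reverse_2",
      "uturn_1", "uturn_2"
    ),
    nodes = list(
      c("F1", "A", "B", "F2"), c("F2", "A", "B", "F1"),
      c("F1", "A", "B", "F1"), c("F2", "A", "B", "F2"),
      c("F1", "A", "F2"), c("F2", "A", "F1"),
      c("F1", "B", "F2"), c("F2", "B", "F1"),
      c("F1", "B", "A", "F1"), c("F2", "B", "A", "F2"),
      c("F1", "A", "F1"), c("F2", "A", "F2")
    ),
    correct = rep(c(TRUE, FALSE), c(2, 10)),
    mean_duration = c(6, 6, 6, 6, 5, 5, 5, 5, 6, 6, 4, 4)
  )
  if (!is.null(mean_durations)) {
    tax$mean_duration[match(names(mean_durations), tax$label)] <- mean_durations
  }
  tax
}

taxonomy_feeders <- function(taxonomy) {
  unique(c(
    vapply(taxonomy$nodes, function(x) x[[1]], character(1)),
    vapply(taxonomy$nodes, function(x) x[[length(x)]], character(1))
  ))
}

validate_taxonomy <- function(taxonomy) {
  if (!all(c("label", "nodes", "correct") %in% names(taxonomy))) {
    abort("taxonomy needs columns `label`, `nodes`, `correct`")
  }
  keys <- vapply(taxonomy$nodes, paste, character(1), collapse = ">")
  if (anyDuplicated(keys)) {
    abort("taxonomy contains duplicate node sequences")
  }
  feeders <- taxonomy_feeders(taxonomy)
  firsts <- vapply(taxonomy$nodes, function(x) x[[1]], character(1))
  lasts <- vapply(taxonomy$nodes, function(x) x[[length(x)]], character(1))
  if (!all(firsts %in% feeders) || !all(lasts %in% feeders)) {
    abort("taxonomy node sequences must start and end at a feeder zone")
  }
  invisible(taxonomy)
}

#' Classify a zone timeline into elementary path traversals
#'
#' Segments the timeline at feeder-zone entries and matches each
#' feeder-to-feeder node sequence exactly against the taxonomy. Segments
#' matching no taxonomy entry are labeled `"unclassified"` and are excluded
#' from all downstream analyses. A traversal starts when the rat leaves the
#' initial feeder (the entry time of the segment's second zone) and ends at
#' the entry into the final feeder.
#'
#' @param zones tibble with columns `time_s` (strictly increasing) and
#'   `zone_id`.
#' @param taxonomy path taxonomy as produced by [path_taxonomy()].
#' @return tibble with columns `trial_id`, `label`, `correct`, `start_s`,
#'   `end_s`.
#' @export
classify_paths <- function(zones, taxonomy = path_taxonomy()) {
  validate_taxonomy(taxonomy)
  if (nrow(zones) == 0) {
    return(tibble::tibble(
      trial_id = integer(0), label = character(0), correct = logical(0),
      start_s = numeric(0), end_s = numeric(0)
    ))
  }
  if (is.unsorted(zones$time_s, strictly = TRUE)) {
    abort("zone entry times must be strictly increasing")
  }
  feeders <- taxonomy_feeders(taxonomy)
  keys <- vapply(taxonomy$nodes, paste, character(1), collapse = ">")
  fidx <- which(zones$zone_id %in% feeders)
  if (length(fidx) < 2) {
    return(tibble::tibble(
      trial_id = integer(0), label = character(0), correct = logical(0),
      start_s = numeric(0), end_s = numeric(0)
    ))
  }
  out <- vector("list", length(fidx) - 1)
  for (s in seq_len(length(fidx) - 1)) {
    i <- fidx[s]
    j <- fidx[s + 1]
    seq_key <- paste(zones$zone_id[i:j], collapse = ">")
    hit <- match(seq_key, keys)
    label <- if (is.na(hit)) "unclassified" else taxonomy$label[hit]
    correct <- if (is.na(hit)) FALSE else taxonomy$correct[hit]
    start_s <- if (j - i >= 1) zones$time_s[i + 1] else zones$time_s[i]
    out[[s]] <- tibble::tibble(
      trial_id = s, label = label, correct = correct,
      start_s = start_s, end_s = zones$time_s[j]
    )
  }
  dplyr::bind_rows(out)
}

#' Session performance in paths per minute
#'
#' @param traversals output of [classify_paths()].
#' @param duration session duration in seconds.
#' @return one-row tibble with counts and rates of correct and incorrect
#'   paths (unclassified segments are excluded).
#' @export
compute_performance <- function(traversals, duration) {
  if (duration <= 0) abort("duration must be positive")
  cls <- traversals[traversals$label != "unclassified", , drop = FALSE]
  n_cor <- sum(cls$correct)
  n_inc <- sum(!cls$correct)
  tibble::tibble(
    n_correct = n_cor, n_incorrect = n_inc,
    correct_per_min = n_cor / duration * 60,
    incorrect_per_min = n_inc / duration * 60
  )
}

#' Assign learning stages from per-session performance
#'
#' Rule-based labeling of the four learning stages from the evolution of
#' correct and incorrect path rates over chronologically ordered sessions:
#' stage 1 while the correct:incorrect ratio stays at or below `r1`;
#' stage 2 while the correct rate rises and the incorrect rate falls
#' (sign of the centered 3-session slope); stage 3 once both slopes are
#' flat (absolute value below `slope_tol`); stage 4 once the incorrect
#' share of paths drops to `q4` or below. Stages are forced to be monotone
#' non-decreasing over sessions.
#'
#' @param performance tibble with columns `correct_per_min` and
#'   `incorrect_per_min`, one row per session in chronological order.
#' @param r1 stage-1 ratio threshold (default 1.25).
#' @param q4 stage-4 incorrect-share threshold (default 0.1).
#' @param slope_tol flatness tolerance for the centered 3-session slope, in
#'   paths per minute per session (default 0.05).
#' @return the input with a `stage` column (integer 1-4).
#' @export
assign_learning_stages <- function(performance, r1 = 1.25, q4 = 0.1,
                                   slope_tol = 0.05) {
  cr <- performance$correct_per_min
  ir <- performance$incorrect_per_min
  n <- length(cr)
  if (n < 3) {
    warn("fewer than 3 sessions: stages assigned by ratio thresholds only")
    cs <- is <- rep(NA_real_, n)
  } else {
    slope3 <- function(x) {
      s <- rep(NA_real_, length(x))
      s[2:(length(x) - 1)] <- (x[3:length(x)] - x[1:(length(x) - 2)]) / 2
      s
    }
    cs <- slope3(cr)
    is <- slope3(ir)
  }
  ratio <- ifelse(ir > 0, cr / ir, Inf)
  share <- ifelse(cr + ir > 0, ir / (cr + ir), NA_real_)
  cand <- integer(n)
  for (k in seq_len(n)) {
    cand[k] <- if (ratio[k] <= r1) {
      1L
    } else if (!is.na(share[k]) && share[k] <= q4) {
      4L
    } else if (!is.na(cs[k]) && abs(cs[k]) < slope_tol && abs(is[k]) < slope_tol) {
      3L
    } else if (!is.na(cs[k]) && cs[k] > 0 && is[k] < 0) {
      2L
    } else {
      1L
    }
  }
  performance$stage <- as.integer(cummax(cand))
  performance
}

#' Extract the six 500 ms task-event windows from a zone timeline
#'
#' Per passage through intersection A or B of occupancy `[t0, t1)` the
#' event window is the central 500 ms `[(t0+t1)/2 - 0.25, (t0+t1)/2 +
#' 0.25)`; per entry into a feeder (reward) zone at `t` the reward window
#' R is `[t, t + 0.5)`; per exit from a feeder zone at `t` the movement
#' onset window O is `[t - 0.5, t)`. Each window carries five contiguous
#' 100 ms bins (see [event_bins()]). Passages shorter than `min_passage`
#' are skipped. Overlapping windows from jittery zone data are kept and
#' flagged.
#'
#' @param zones tibble with `time_s`, `zone_id`.
#' @param duration session duration (closes the final occupancy).
#' @param min_passage minimum zone occupancy in seconds (default 0.5).
#' @return tibble with columns `event`, `passage_id`, `start`, `end`,
#'   `overlap`.
#' @export
extract_event_windows <- function(zones, duration = NULL,
                                  min_passage = 0.5) {
  if (nrow(zones) == 0) {
    return(tibble::tibble(
      event = character(0), passage_id = integer(0),
      start = numeric(0), end = numeric(0), overlap = logical(0)
    ))
  }
  t0 <- zones$time_s
  t1 <- c(zones$time_s[-1], if (is.null(duration)) NA_real_ else duration)
  occ <- t1 - t0
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(zones))) {
    z <- zones$zone_id[k]
    if (is.na(occ[k])) next
    if (z %in% c("A", "B")) {
      if (occ[k] < min_passage) {
        skipped <- skipped + 1L
        next
      }
      mid <- (t0[k] + t1[k]) / 2
      rows[[length(rows) + 1]] <- tibble::tibble(
        event = z, start = mid - 0.25, end = mid + 0.25
      )
    } else if (z %in% c("F1", "F2")) {
      idx <- if (z == "F1") "1" else "2"
      if (occ[k] < min_passage) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        event = paste0("R", idx), start = t0[k], end = t0[k] + 0.5
      )
      if (!is.na(t1[k]) && (k < nrow(zones))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          event = paste0("O", idx), start = t1[k] - 0.5, end = t1[k]
        )
      }
    }
  }
  if (skipped > 0) {
    inform(sprintf("extract_event_windows: skipped %d passages shorter than %.3g s",
                   skipped, min_passage))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      event = character(0), passage_id = integer(0),
      start = numeric(0), end = numeric(0), overlap = logical(0)
    ))
  }
  win <- dplyr::bind_rows(rows)
  win <- dplyr::arrange(win, .data$start)
  win$overlap <- FALSE
  if (nrow(win) > 1) {
    ov <- c(FALSE, win$start[-1] < win$end[-nrow(win)] - 1e-12)
    win$overlap <- ov | c(ov[-1], FALSE)
  }
  win <- dplyr::group_by(win, .data$event)
  win <- dplyr::mutate(win, passage_id = dplyr::row_number())
  win <- dplyr::ungroup(win)
  win[, c("event", "passage_id", "start", "end", "overlap")]
}

#' Expand event windows into their five 100 ms bins
#'
#' @param windows output of [extract_event_windows()].
#' @return tibble with one row per (window, bin): `event`, `passage_id`,
#'   `bin` (1-5), `start`, `end`.
#' @export
event_bins <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(
      event = character(0), passage_id = integer(0), bin = integer(0),
      start = numeric(0), end = numeric(0)
    ))
  }
  out <- tidyr::crossing(windows[, c("event", "passage_id", "start")],
                         bin = 1:5)
  out <- dplyr::arrange(out, .data$event, .data$passage_id, .data$bin)
  # compute both edges from the window start with the same expression so
  # that adjacent bins share edges bitwise (0.3 + 0.1 > 0.4 in floating
  # point would otherwise make them micro-overlap)
  base <- out$start
  out$start <- base + 0.1 * (out$bin - 1)
  out$end <- base + 0.1 * out$bin
  out[, c("event", "passage_id", "bin", "start", "end")]
}

#' Central-stem runs with the upcoming turn
#'
#' For the left/right analysis: each consecutive A-then-B zone entry pair
#' defines a stem run `[t_A, t_B)`; the upcoming turn is read from the
#' first arm (feeder) zone entered after B (`F1` = left, `F2` = right).
#' Runs after which the rat returns to A without entering an arm are
#' dropped.
#'
#' @param zones tibble with `time_s`, `zone_id`.
#' @return tibble with columns `start`, `end`, `turn` ("left"/"right").
#' @export
stem_runs <- function(zones) {
  z <- zones$zone_id
  t <- zones$time_s
  out <- list()
  for (k in seq_len(length(z) - 1)) {
    if (z[k] == "A" && z[k + 1] == "B") {
      nxt <- if (k + 2 <= length(z)) z[k + 2] else NA_character_
      turn <- if (identical(nxt, "F1")) "left" else if (identical(nxt, "F2")) "right" else NA_character_
      if (!is.na(turn)) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = t[k], end = t[k + 1], turn = turn
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          turn = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Derive all behavioral frames of a session in one call
#'
#' Convenience wrapper producing the traversal table, task-event windows
#' (with bins) and central-stem runs used by the downstream analyses.
#'
#' @inheritParams classify_paths
#' @inheritParams extract_event_windows
#' @return list with elements `traversals`, `events`, `bins`, `stem`,
#'   `duration`.
#' @export
behavior_frames <- function(zones, duration, taxonomy = path_taxonomy()) {
  windows <- extract_event_windows(zones, duration)
  list(
    traversals = classify_paths(zones, taxonomy),
    events = windows,
    bins = event_bins(windows),
    stem = stem_runs(zones),
    duration = duration
  )
}
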