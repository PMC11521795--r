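test_that("taxonomy has 12 unique feeder-to-feeder paths", {
  tax <- path_taxonomy()
  expect_equal(nrow(tax), 12)
  expect_equal(sum(tax$correct), 2)
  keys <- vapply(tax$nodes, paste, character(1), collapse = ">")
  expect_equal(anyDuplicated(keys), 0L)
  firsts <- vapply(tax$nodes, function(x) x[[1]], character(1))
  lasts <- vapply(tax$nodes, function(x) x[[length(x)]], character(1))
  expect_true(all(firsts %in% c("F1", "F2")))
  expect_true(all(lasts %in% c("F1", "F2")))
})

test_that("classify_paths labels a hand-built timeline and flags the rest", {
  # correct_1 (F1 A B F2), then uturn_2 (F2 A F2), then an unknown detour
  zones <- tibble::tibble(
    time_s = c(0, 2, 4, 6, 8, 10, 12, 14, 16),
    zone_id = c("F1", "A", "B", "F2", "A", "F2", "B", "A", "F1")
  )
  trav <- classify_paths(zones)
  expect_equal(trav$label, c("correct_1", "uturn_2", "unclassified"))
  expect_equal(trav$correct, c(TRUE, FALSE, FALSE))
  # traversal starts when the rat leaves the feeder (second zone entry)
  expect_equal(trav$start_s, c(2, 8, 12))
  expect_equal(trav$end_s, c(6, 10, 16))
})

test_that("compute_performance arithmetic is exact", {
  trav <- tibble::tibble(
    label = c("correct_1", "correct_2", "return_1", "unclassified"),
    correct = c(TRUE, TRUE, FALSE, FALSE)
  )
  perf <- compute_performance(trav, duration = 600)
  expect_equal(perf$n_correct, 2)
  expect_equal(perf$n_incorrect, 1)
  expect_equal(perf$correct_per_min, 2 / 600 * 60)
  expect_equal(perf$incorrect_per_min, 0.1)
})

test_that("learning stages follow the rules and are monotone", {
  perf <- tibble::tibble(
    correct_per_min   = c(0.5, 0.5, 0.9, 1.3, 1.5, 1.5, 1.9, 2.0),
    incorrect_per_min = c(0.5, 0.5, 0.6, 0.4, 0.3, 0.3, 0.1, 0.1)
  )
  staged <- assign_learning_stages(perf)
  # equal rates pin stage 1 even though the curves are flat there
  expect_equal(staged$stage[1:2], c(1L, 1L))
  expect_equal(max(staged$stage), 4L)
  expect_true(all(diff(staged$stage) >= 0))
  # incorrect share 0.1/2.1 <= 0.1 at the end -> stage 4
  expect_equal(staged$stage[8], 4L)
})

test_that("event windows follow the stated 500 ms conventions", {
  # A passage [10.0, 10.8): central 500 ms window [10.15, 10.65)
  zones <- tibble::tibble(
    time_s = c(0, 10, 10.8, 12, 13, 14),
    zone_id = c("F1", "A", "B", "A", "B", "F2")
  )
  win <- extract_event_windows(zones, duration = 20)
  a <- win[win$event == "A", ]
  expect_equal(nrow(a), 2)
  expect_equal(a$start[1], 10.15)
  expect_equal(a$end[1], 10.65)
  # feeder F1 occupancy [0, 10): reward window [0, 0.5),
  # movement-onset window [9.5, 10)
  expect_equal(win$start[win$event == "R1"], 0)
  expect_equal(win$end[win$event == "R1"], 0.5)
  expect_equal(win$start[win$event == "O1"], 9.5)
  expect_equal(win$end[win$event == "O1"], 10)
  # F2 entered at 14 and still occupied at session end: R2 only, no O2
  expect_equal(sum(win$event == "R2"), 1)
  expect_equal(sum(win$event == "O2"), 0)
  expect_false(any(win$overlap))
})

test_that("short passages are skipped with a message", {
  zones <- tibble::tibble(
    time_s = c(0, 5, 5.3, 8),
    zone_id = c("F1", "A", "B", "F2")
  )
  expect_message(
    win <- extract_event_windows(zones, duration = 20),
    "skipped"
  )
  expect_false("A" %in% win$event)
})

test_that("event bins tile each window in five 100 ms steps", {
  win <- tibble::tibble(event = "A", passage_id = 1L,
                        start = 2, end = 2.5, overlap = FALSE)
  bins <- event_bins(win)
  expect_equal(nrow(bins), 5)
  expect_equal(bins$start, 2 + 0.1 * (0:4))
  expect_equal(bins$end, bins$start + 0.1)
})

test_that("stem runs read the upcoming turn from the next arm entry", {
  zones <- tibble::tibble(
    time_s = c(0, 1, 2, 3, 5, 6, 7, 9, 10, 11),
    zone_id = c("F1", "A", "B", "F2", "A", "B", "F1", "A", "B", "A")
  )
  runs <- stem_runs(zones)
  expect_equal(nrow(runs), 2)  # last run returns to A: dropped
  expect_equal(runs$turn, c("right", "left"))
  expect_equal(runs$start, c(1, 5))
  expect_equal(runs$end, c(2, 6))
})
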