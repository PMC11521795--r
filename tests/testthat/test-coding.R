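# A small reusable session for condition tables: 20 passages per event
# A and B, nothing else.
coding_frames <- local({
  win <- tibble::tibble(
    event = rep(c("A", "B"), each = 20),
    passage_id = rep(1:20, 2),
    start = c(seq(0, by = 10, length.out = 20),
              seq(5, by = 10, length.out = 20))
  )
  win$end <- win$start + 0.5
  win$overlap <- FALSE
  list(events = win, bins = event_bins(win))
})

test_that("task-event condition table uses d_k = 0.1 * passages", {
  spikes <- c(0.05, 0.15, 0.16, 5.02, 15.45)
  tab <- build_condition_table(spikes, coding_frames, mode = "task_event")
  # only events with passages are kept: A and B -> 10 conditions
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$duration_s == 0.1 * 20))
  expect_equal(tab$n_spikes[tab$condition == "A.1"], 1)
  expect_equal(tab$n_spikes[tab$condition == "A.2"], 2)
  expect_equal(tab$n_spikes[tab$condition == "B.1"], 1)
  expect_equal(tab$n_spikes[tab$condition == "B.5"], 1)
  expect_equal(sum(tab$n_spikes), 5)
})

test_that("expected counts and the chi-squared statistic match stats::chisq.test", {
  tab <- tibble::tibble(
    condition = c("a", "b", "c"),
    n_spikes = c(30, 50, 40),
    duration_s = c(10, 10, 20)
  )
  tab <- structure(tab, mode = "full_path",
                   class = c("condition_counts", class(tab)))
  e <- striatnet:::expected_counts(tab)
  expect_equal(e, 120 * c(0.25, 0.25, 0.5))
  res <- chi_square_multinomial_test(apply_validity_policy(tab))
  oracle <- suppressWarnings(
    chisq.test(tab$n_spikes, p = c(0.25, 0.25, 0.5))
  )
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, oracle$p.value)
  expect_equal(res$status, "tested")
})

test_that("task_event validity policy merges bins into events first", {
  # 2 spikes total: every 100 ms bin has expected < 5, but after merging
  # into A/B the expecteds are 1 each -> still below 5 -> discarded
  frames_small <- coding_frames
  tab <- build_condition_table(c(0.05, 5.05), frames_small, "task_event")
  out <- apply_validity_policy(tab)
  expect_equal(attr(out, "status"), "discarded")
  expect_true(any(grepl("merged", attr(out, "policy_trace"))))
  # 40 spikes: per-bin expected 4 (< 5) but per-event expected 20,
  # so the merge rescues the unit
  spikes <- sort(c(seq(0.01, 0.49, length.out = 20),
                   seq(5.01, 5.49, length.out = 20)))
  tab2 <- build_condition_table(spikes, frames_small, "task_event")
  out2 <- apply_validity_policy(tab2)
  expect_equal(attr(out2, "status"), "tested")
  expect_equal(nrow(out2), 2)  # merged to events A, B
  res <- chi_square_multinomial_test(out2)
  expect_equal(res$df, 1L)
})

test_that("full_path policy drops the smallest expected condition", {
  tab <- tibble::tibble(
    condition = c("p1", "p2", "p3"),
    n_spikes = c(50, 50, 1),
    duration_s = c(50, 50, 1)
  )
  tab <- structure(tab, mode = "full_path",
                   class = c("condition_counts", class(tab)))
  out <- apply_validity_policy(tab)
  expect_equal(attr(out, "status"), "tested")
  expect_setequal(out$condition, c("p1", "p2"))
  expect_true(any(grepl("dropped path p3", attr(out, "policy_trace"))))
  # left_right never merges or drops: straight to discard
  lr <- tibble::tibble(condition = c("left", "right"),
                       n_spikes = c(3, 2), duration_s = c(5, 5))
  lr <- structure(lr, mode = "left_right",
                  class = c("condition_counts", class(lr)))
  expect_equal(attr(apply_validity_policy(lr), "status"), "discarded")
})

test_that("bh_adjust agrees with step-up enumeration", {
  set.seed(31)
  p <- c(runif(40), runif(10, 0, 1e-4))
  adj <- bh_adjust(p, alpha = 0.05)
  expect_equal(adj$coding, oracle_bh_reject(p, 0.05))
  expect_equal(adj$p_adjusted, p.adjust(p, "BH"))
})

test_that("detect_coding_units flags modulated units and keeps silent ones out", {
  frames <- coding_frames
  set.seed(18)
  spikes <- dplyr::bind_rows(
    # unit 1: strongly tuned to bin A.1
    tibble::tibble(unit_id = 1L,
                   time_s = sort(c(seq(0.001, 0.099, length.out = 60),
                                   runif(60, 0, 200)))),
    # unit 2: homogeneous
    tibble::tibble(unit_id = 2L, time_s = sort(runif(400, 0, 200))),
    # unit 3: nearly silent -> discarded by the validity rule
    tibble::tibble(unit_id = 3L, time_s = c(1, 2))
  )
  res <- detect_coding_units(spikes, frames, mode = "task_event")
  expect_equal(nrow(res), 3)
  expect_true(res$coding[res$unit_id == 1])
  expect_equal(res$status[res$unit_id == 3], "discarded")
  expect_true(is.na(res$p_value[res$unit_id == 3]))
})
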