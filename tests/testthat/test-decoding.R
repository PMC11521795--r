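test_that("trial splitting takes ceiling(2/3 m) chronological trials", {
  trials <- tibble::tibble(
    condition = rep(c("a", "b", "c"), c(12, 4, 2)),
    start = c(seq(0, 110, by = 10), seq(200, 230, by = 10), c(300, 310))
  )
  trials$end <- trials$start + 5
  sp <- split_trials(trials)
  a <- sp[sp$condition == "a", ]
  expect_equal(sum(a$split == "train"), 8)   # ceiling(2/3 * 12)
  expect_equal(sum(a$split == "test"), 4)
  # training trials are the chronologically first ones
  expect_true(max(a$start[a$split == "train"]) <
                min(a$start[a$split == "test"]))
  b <- sp[sp$condition == "b", ]
  expect_equal(sum(b$split == "train"), 3)   # ceiling(8/3) = 3, leaves 1 test
  expect_equal(sum(b$split == "test"), 1)
  # conditions under min_trials are dropped entirely
  expect_true(all(sp$split[sp$condition == "c"] == "dropped"))
  # the random policy is seeded and keeps the same counts
  r1 <- split_trials(trials, policy = "random", seed = 4)
  r2 <- split_trials(trials, policy = "random", seed = 4)
  expect_identical(r1, r2)
  expect_equal(sum(r1$split == "train" & r1$condition == "a"), 8)
})

test_that("session eligibility applies both rules", {
  trav <- tibble::tibble(label = rep(c("correct_1", "correct_2"), c(5, 4)))
  coding <- tibble::tibble(coding = c(TRUE, TRUE, FALSE))
  ok <- session_eligibility(trav, coding)
  expect_true(ok$eligible)
  few <- session_eligibility(trav, tibble::tibble(coding = c(TRUE, FALSE)))
  expect_false(few$eligible)
  expect_match(few$reasons, "coding units")
  mono <- session_eligibility(
    tibble::tibble(label = rep("correct_1", 8)), coding)
  expect_false(mono$eligible)
  expect_match(mono$reasons, "distinct paths")
})

test_that("decode_trial picks the candidate with the smaller contrast", {
  # two Poisson models; the trial's count decides
  mk <- function(rate) structure(list(rate = rate), class = "poisson_fit")
  models <- list(low = list(mk(2)), high = list(mk(10)))
  trial_hi <- list(start = 0, end = 2)
  spikes_hi <- list(seq(0.05, 1.95, length.out = 20))  # 10 Hz
  expect_equal(decode_trial(models, spikes_hi, trial_hi)$k_hat, "high")
  spikes_lo <- list(c(0.3, 1.2, 1.8))
  expect_equal(decode_trial(models, spikes_lo, trial_hi)$k_hat, "low")
})

test_that("rate-coded sessions decode almost perfectly with Poisson models", {
  trav <- tibble::tibble(
    label = rep(c("correct_1", "correct_2"), 6),
    start_s = (0:11) * 10,
    end_s = (0:11) * 10 + 6
  )
  iv1 <- trav[trav$label == "correct_1", c("start_s", "end_s")]
  iv2 <- trav[trav$label == "correct_2", c("start_s", "end_s")]
  names(iv1) <- names(iv2) <- c("start", "end")
  spike_list <- lapply(1:3, function(u) {
    sort(c(gen_homogeneous_poisson(3, iv1, seed = 50 + u),
           gen_homogeneous_poisson(15, iv2, seed = 70 + u)))
  })
  res <- session_decoding_power(spike_list, trav, model = "poisson",
                                session_duration = 120)
  expect_s3_class(res, "decoding_result")
  expect_equal(res$reference, 0.5)
  expect_equal(nrow(res$trials), 4)  # 2 test trials per condition
  expect_equal(res$power, 1)
  # tidy/glance accessors
  expect_true(all(tidy(res)$correct))
  expect_equal(glance(res)$n_paths, 2)
})

test_that("hawkes decoding runs end to end on a small session", {
  trav <- tibble::tibble(
    label = rep(c("correct_1", "correct_2"), 6),
    start_s = (0:11) * 8,
    end_s = (0:11) * 8 + 5
  )
  spec <- list(
    correct_1 = list(mu = c(10, 2), a = array(0, dim = c(2, 2, 6))),
    correct_2 = list(mu = c(2, 10), a = array(0, dim = c(2, 2, 6)))
  )
  tr <- gen_hawkes_session(
    spec,
    tibble::tibble(start = trav$start_s, end = trav$end_s,
                   condition = trav$label),
    seed = 9
  )
  spike_list <- split(tr$time_s, factor(tr$unit_id, levels = 1:2))
  res <- session_decoding_power(spike_list, trav, model = "hawkes",
                                session_duration = 80)
  expect_equal(res$model, "hawkes")
  expect_equal(nrow(res$trials), 4)
  expect_gte(res$power, 0.75)  # strongly rate-separated conditions
})
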