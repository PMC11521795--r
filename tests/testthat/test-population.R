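test_that("bin firing rates follow f = count / (0.1 * passages)", {
  win <- tibble::tibble(
    event = c("A", "A", "B"), passage_id = c(1L, 2L, 1L),
    start = c(0, 10, 5), end = c(0.5, 10.5, 5.5), overlap = FALSE
  )
  frames <- list(events = win, bins = event_bins(win))
  spikes <- c(0.05, 10.05, 10.06, 5.45)
  rates <- bin_firing_rates(spikes, frames)
  expect_equal(nrow(rates), 30)
  # A.1 holds 3 spikes over 2 passages: 3 / 0.2 = 15 Hz
  expect_equal(rates$rate[rates$event == "A" & rates$bin == 1], 15)
  expect_equal(rates$rate[rates$event == "B" & rates$bin == 5], 10)
  expect_equal(rates$rate[rates$event == "A" & rates$bin == 3], 0)
  # events with no passages give missing bins
  expect_true(all(is.na(rates$rate[rates$event == "R1"])))
  expect_equal(rates$bin_index, 1:30)
})

test_that("z-scoring centers and scales; flat profiles are excluded", {
  z <- zscore_profile(c(1, 2, 3, 4))
  expect_equal(mean(z$z), 0)
  expect_equal(sd(z$z), 1)
  expect_false(attr(z, "excluded"))
  flat <- zscore_profile(c(2, 2, 2))
  expect_true(attr(flat, "excluded"))
  expect_true(all(is.na(flat$z)))
})

test_that("population curves use the Bonferroni multiplier 3.71", {
  # [PAPER] 8 curves x 30 bins -> qnorm(1 - 0.05 / 480) = 3.71
  profiles <- tidyr::crossing(
    group = paste0("g", 1:8), unit_id = 1:3, bin_index = 1:30
  )
  set.seed(4)
  profiles$z <- rnorm(nrow(profiles))
  curves <- population_curves(profiles)
  q <- attr(curves, "multiplier")
  expect_equal(q, qnorm(1 - 0.05 / (2 * 240)))
  expect_equal(round(q, 2), 3.71)
  one <- curves[curves$group == "g1" & curves$bin_index == 1, ]
  sub <- profiles[profiles$group == "g1" & profiles$bin_index == 1, ]
  expect_equal(one$mean_z, mean(sub$z))
  expect_equal(one$hi - one$mean_z, q * sd(sub$z) / sqrt(3))
  # single-unit groups get NA bands
  solo <- population_curves(
    tibble::tibble(group = "s", unit_id = 1, bin_index = 1:30,
                   z = rnorm(30)))
  expect_true(all(is.na(solo$lo)))
})

test_that("entropy closed forms hold exactly", {
  # all z-scores in one bin -> (1) * log(1 / 0.5) = log 2
  expect_equal(zscore_entropy(rep(0.1, 7))$value, log(2), tolerance = 1e-12)
  # one count per bin -> 18 * (1/18) * log((1/18) / 0.5) = log(1/9)
  centers <- seq(-3.25, 5.25, by = 0.5)
  expect_equal(zscore_entropy(centers)$value, log(1 / 9), tolerance = 1e-12)
  expect_equal(length(zscore_entropy(centers)$counts), 18L)
})

test_that("out-of-range z-scores clip into the terminal bins", {
  e <- zscore_entropy(c(-10, -3.6, 6, 100))
  expect_equal(e$counts[1], 2)
  expect_equal(e$counts[18], 2)
  expect_equal(e$n_total, 4)
})

test_that("fractional weights reproduce the Gaussian large-sample limit", {
  # [DERIVED] feeding exact standard-normal bin masses as weights must
  # equal the direct sum over Phi differences
  edges <- seq(-3.5, 5.5, by = 0.5)
  mass <- diff(pnorm(edges))
  mass[1] <- mass[1] + pnorm(-3.5)    # clipped lower tail
  mass[18] <- mass[18] + pnorm(5.5, lower.tail = FALSE)
  centers <- seq(-3.25, 5.25, by = 0.5)
  got <- zscore_entropy(centers, weights = mass)$value
  expect_equal(got, oracle_entropy_from_masses(mass), tolerance = 1e-6)
  # and a large finite sample converges to it
  set.seed(12)
  emp <- zscore_entropy(rnorm(2e5))$value
  expect_lt(abs(emp - got), 0.02)
})

test_that("entropy stage contrasts bootstrap by unit blocks", {
  set.seed(9)
  profiles <- dplyr::bind_rows(
    tidyr::crossing(region = "DMS", stage = c(1L, 2L), unit_id = 1:15) |>
      dplyr::mutate(unit_id = unit_id + 100 * stage)
  )
  profiles <- tidyr::uncount(profiles, 30)
  # stage 2 z-scores more dispersed than stage 1
  profiles$z <- rnorm(nrow(profiles), sd = ifelse(profiles$stage == 2, 2, 0.3))
  res <- entropy_stage_contrast(profiles, n_boot = 200, seed = 3)
  expect_equal(nrow(res), 2)
  expect_equal(res$delta[res$stage == 1], 0)
  expect_true(is.finite(res$lo[2]) && res$lo[2] <= res$hi[2])
  # a region without units at the reference stage is an error
  broken <- dplyr::bind_rows(
    profiles,
    dplyr::mutate(profiles[profiles$stage == 2, ], region = "DLS")
  )
  expect_error(
    entropy_stage_contrast(broken, n_boot = 100, seed = 1),
    "stage-1"
  )
})
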