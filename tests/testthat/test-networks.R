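test_that("lag-bin predictors follow the left-closed convention, lag 0 excluded", {
  train <- c(0)
  # worked boundary: a spike at T = 0 makes x_{m,2}(t) = 1 exactly for
  # t in [0.010, 0.020)
  x <- striatnet:::lag_bin_counts(train, c(0.0100, 0.0150, 0.0199999))
  expect_equal(x[, 2], c(1, 1, 1))
  expect_equal(rowSums(x), c(1, 1, 1))
  x2 <- striatnet:::lag_bin_counts(train, c(0.0050, 0.0200, 0.0599, 0.0600))
  expect_equal(x2[1, ], c(1, 0, 0, 0, 0, 0))
  expect_equal(x2[2, ], c(0, 0, 1, 0, 0, 0))
  expect_equal(x2[3, ], c(0, 0, 0, 0, 0, 1))
  expect_equal(sum(x2[4, ]), 0)  # lag 60 ms is outside the support
  # lag 0: the spike does not predict itself
  expect_equal(sum(striatnet:::lag_bin_counts(train, 0)), 0)
  # agreement with the brute-force oracle on random data
  set.seed(2)
  tr <- sort(runif(50, 0, 1))
  ts <- runif(20, 0, 1.1)
  got <- striatnet:::lag_bin_counts(tr, ts)
  want <- t(vapply(ts, function(t) oracle_lag_counts(tr, t), numeric(6)))
  expect_equal(got, want)
})

test_that("fit_poisson is the stated closed form", {
  iv <- tibble::tibble(start = c(0, 10), end = c(5, 12))
  spikes <- c(1, 2, 3, 10.5, 11.5, 20)
  f <- fit_poisson(spikes, iv)
  expect_equal(f$rate, 5 / 7)
  expect_equal(f$contrast, -25 / 7)
  expect_equal(model_contrast(f, spikes, iv), -25 / 7)
  # a non-optimal rate always has a larger contrast
  worse <- f
  worse$rate <- f$rate + 0.3
  expect_gt(model_contrast(worse, spikes, iv), f$contrast)
})

test_that("the Gram matrix has exact simple entries", {
  spike_list <- list(c(0.5), numeric(0))
  iv <- tibble::tibble(start = 0, end = 2)
  des <- build_design(spike_list, iv)
  # constant predictor: G[1,1] = |K|
  expect_equal(des$G[1, 1], 2)
  # unit 1's bin-i predictor is 1 on [0.5 + 0.01 (i-1), 0.5 + 0.01 i)
  expect_equal(diag(des$G)[2:7], rep(0.01, 6))
  expect_equal(des$G[1, 2:7], rep(0.01, 6))
  # silent unit 2 contributes nothing
  expect_true(all(des$G[, 8:13] == 0))
})

test_that("design and fit match the fine-grid quadrature oracle", {
  # all spike times on the 0.1 ms lattice with distinct residues mod 10 ms,
  # so both the sweep and the grid integrate the same step function exactly
  spike_list <- list(
    c(0.0501, 0.1232, 0.3073, 0.5554, 0.7015,
      0.9996, 1.2347, 1.4558, 1.7779, 1.9012),
    c(0.0623, 0.1304, 0.3145, 0.6016, 0.7057,
      1.0028, 1.2409, 1.5021, 1.8092, 1.9213)
  )
  iv <- tibble::tibble(start = 0, end = 2)
  des <- build_design(spike_list, iv)
  ora <- oracle_design(spike_list, 2, target = 2)
  expect_equal(des$G, ora$G, tolerance = 1e-9)
  expect_equal(unname(des$b[, 2]), unname(ora$b), tolerance = 1e-9)
  fit <- fit_hawkes(des, target = 2)
  theta_o <- solve(ora$G, ora$b)
  expect_equal(unname(fit$theta), unname(theta_o), tolerance = 1e-7)
  # kernel layout: a[source, bin]
  expect_equal(fit$a[1, ], unname(theta_o[2:7]), tolerance = 1e-7)
  expect_equal(fit$mu, unname(theta_o[1]), tolerance = 1e-7)
})

test_that("silent targets give all-zero fits without ridge noise", {
  spike_list <- list(sort(runif(30, 0, 5)), numeric(0))
  iv <- tibble::tibble(start = 0, end = 5)
  des <- build_design(spike_list, iv)
  f <- fit_hawkes(des, target = 2)
  expect_equal(f$theta, rep(0, 13))
  expect_false(f$ridged)
})

test_that("evaluation restricts to the intervals but history does not", {
  # unit 1 spikes just before the interval still shape unit 2's predictors
  spike_list <- list(c(0.995), c(1.002))
  iv <- tibble::tibble(start = 1, end = 2)
  des <- build_design(spike_list, iv, target = 2)
  # at T = 1.002, the lag to 0.995 is 7 ms -> bin 1 of unit 1
  expect_equal(des$b[2], 1)
  # and the target spike itself is counted: b[1] = #spikes in K
  expect_equal(des$b[1], 1)
})

test_that("the full network fit recovers layout and the interaction table", {
  set.seed(33)
  spike_list <- lapply(1:3, function(u) sort(runif(200, 0, 100)))
  trav <- tibble::tibble(
    label = rep(c("p", "q"), each = 4),
    start_s = c(0, 12, 24, 36, 50, 62, 74, 86),
    end_s = c(10, 22, 34, 46, 60, 72, 84, 96)
  )
  net <- fit_hawkes_network(spike_list, build_condition_intervals(trav))
  expect_setequal(names(net$conditions), c("p", "q"))
  expect_equal(dim(net$conditions$p$a), c(3, 3, 6))
  st <- interaction_strengths(net)
  expect_equal(nrow(st), 2 * 9)
  expect_equal(
    st$strength[st$condition == "p" & st$source == 1 & st$target == 2],
    sum(abs(net$conditions$p$a[1, 2, ]))
  )
  gr <- interaction_graph(st, probs = 0.70)
  # type-1 quantile keeps (close to) the top 30 % of edges
  expect_equal(sum(gr$binary), sum(st$strength > quantile(st$strength, 0.7, type = 1)))
  expect_true(all(gr$binary %in% c(0L, 1L)))
  # tidiers return well-formed tables
  td <- tidy(net)
  expect_equal(nrow(td), 18)
  gl <- glance(net)
  expect_equal(gl$n_parameters, rep(3 + 6 * 9, 2))
})

test_that("overlapping traversals are rejected", {
  trav <- tibble::tibble(label = c("p", "q"),
                         start_s = c(0, 5), end_s = c(6, 10))
  expect_error(build_condition_intervals(trav), "overlap")
})
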