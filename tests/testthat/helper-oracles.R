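# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive quantities with different code paths (brute-force
# loops, dense outer products, fine-grid quadrature, numerical
# optimization) so that agreement with the package is informative.

# Lagged spike counts by brute force: x_{m,i}(t) = #{T in train :
# t - T in [0.01 (i - 1), 0.01 i)}, lag 0 excluded.
oracle_lag_counts <- function(train, t) {
  lag <- t - train
  vapply(1:6, function(i) {
    lo <- 0.01 * (i - 1)
    hi <- 0.01 * i
    if (i == 1) sum(lag > 0 & lag < hi) else sum(lag >= lo & lag < hi)
  }, numeric(1))
}

# Predictor matrix (1, x_{1,1..6}, x_{2,1..6}, ...) at a vector of times,
# via dense outer differences rather than sorted searches.
oracle_predictors <- function(spike_list, t) {
  p <- 1L + 6L * length(spike_list)
  X <- matrix(0, nrow = length(t), ncol = p)
  X[, 1] <- 1
  for (m in seq_along(spike_list)) {
    cols <- 1L + (m - 1L) * 6L + 1:6
    X[, cols] <- t(vapply(t, function(tt)
      oracle_lag_counts(spike_list[[m]], tt), numeric(6)))
  }
  X
}

# Fine-grid quadrature design on a single interval [0, duration): the
# Gram matrix integrates the piecewise-constant predictors over grid
# cells of width dt (exact when all spike times are multiples of dt),
# and b sums the predictors at the target spikes.
oracle_design <- function(spike_list, duration, target, dt = 1e-4) {
  mids <- (seq_len(round(duration / dt)) - 0.5) * dt
  Xg <- oracle_predictors(spike_list, mids)
  ts <- spike_list[[target]]
  ts <- ts[ts >= 0 & ts < duration]
  Xs <- oracle_predictors(spike_list, ts)
  list(
    G = crossprod(Xg) * dt,
    b = colSums(Xs),
    grid = Xg, dt = dt, spike_predictors = Xs
  )
}

# Least-squares contrast by quadrature, and its minimizer by BFGS.
oracle_contrast_fn <- function(des) {
  function(theta) {
    lam_grid <- drop(des$grid %*% theta)
    lam_spk <- drop(des$spike_predictors %*% theta)
    -2 * sum(lam_spk) + sum(lam_grid^2) * des$dt
  }
}

oracle_contrast_gr <- function(des) {
  function(theta) {
    drop(-2 * des$b + 2 * crossprod(des$grid, des$grid %*% theta) * des$dt)
  }
}

# Minimize the quadrature contrast numerically with conjugate gradients
# and exact line searches, using only matrix-vector products with the
# grid predictors (BFGS stalls on this ill-conditioned quadratic). In
# exact arithmetic this terminates in at most p steps.
oracle_minimize <- function(des, tol = 1e-13, max_iter = 1000) {
  Gv <- function(v) drop(crossprod(des$grid, des$grid %*% v)) * des$dt
  theta <- rep(0, ncol(des$grid))
  r <- des$b - Gv(theta)
  p <- r
  rs <- sum(r^2)
  for (it in seq_len(max_iter)) {
    if (sqrt(rs) <= tol * max(1, sqrt(sum(des$b^2)))) break
    Gp <- Gv(p)
    alpha <- rs / sum(p * Gp)
    theta <- theta + alpha * p
    r <- r - alpha * Gp
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  theta
}

# Stationary rates of a stable Hawkes network from the branching
# structure: r = (I - A^T)^{-1} mu with A[m, n] the kernel L1 mass.
oracle_stationary_rates <- function(mu, a) {
  A <- apply(abs(a), c(1, 2), sum) * 0.01
  solve(diag(length(mu)) - t(A), mu)
}

# Benjamini-Hochberg step-up by direct enumeration.
oracle_bh_reject <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(n) / n)
  rej <- logical(n)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Binned z-score entropy recomputed directly from bin masses.
oracle_entropy_from_masses <- function(mass) {
  mass <- mass / sum(mass)
  pos <- mass[mass > 0]
  sum(pos * log(pos / 0.5))
}

# A directed-ring kernel array: unit m excites unit (m %% N) + 1 with
# total L1 mass `mass` spread evenly over the six 10 ms plateaus.
ring_kernels <- function(n_units, mass) {
  a <- array(0, dim = c(n_units, n_units, 6))
  for (m in seq_len(n_units)) {
    # L1 mass = 0.01 * sum_i a_i, so each plateau is mass / (0.01 * 6)
    a[m, (m %% n_units) + 1, ] <- mass / (0.01 * 6)
  }
  a
}

# Equally spaced, disjoint trial windows.
make_trials <- function(n, duration, gap, t0 = 0) {
  starts <- t0 + (seq_len(n) - 1) * (duration + gap)
  tibble::tibble(start = starts, end = starts + duration)
}
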