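# Per-condition Poisson and multivariate Hawkes intensity models fitted
# by the least-squares contrast
#
#     C(lambda) = -2 * sum_{T in K} lambda(T) + integral_K lambda(t)^2 dt,
#
# with evaluation times restricted to the union K of intervals where the
# condition holds, but predictor histories taken from the full session.
# The Hawkes intensity of target unit n is
#
#     lambda_n(t) = mu_n + sum_m sum_i a[m, n, i] * x_{m,i}(t),
#
# where x_{m,i}(t) counts spikes of unit m at lags in [10(i-1), 10i) ms
# (lag 0 excluded, so a spike never predicts itself). Because lambda is
# linear in theta = (mu, a), minimizing C is the linear system
# G theta = b with G the Gram matrix of the piecewise-constant predictors
# over K and b the predictor sums at the target spikes in K. G is
# integrated exactly by sweeping the breakpoints (spike times plus lag-bin
# edges) inside K.

KERNEL_BINS <- 6L
KERNEL_BIN_WIDTH <- 0.01

#' Per-condition time intervals from classified traversals
#'
#' @param traversals tibble from [classify_paths()] (unclassified rows are
#'   ignored).
#' @return tibble with `condition`, `start`, `end` (one row per trial).
#' @export
build_condition_intervals <- function(traversals) {
  trav <- traversals[traversals$label != "unclassified", , drop = FALSE]
  out <- tibble::tibble(
    condition = trav$label, start = trav$start_s, end = trav$end_s
  )
  chk <- dplyr::arrange(out, .data$start)
  if (nrow(chk) > 1 && any(chk$start[-1] < chk$end[-nrow(chk)] - 1e-12)) {
    abort("traversals overlap")
  }
  out
}

#' Fit a Poisson (constant-intensity) model on condition intervals
#'
#' The least-squares contrast `-2 N nu + nu^2 D` is minimized in closed
#' form by `nu = N / D` (spike count over total condition duration); the
#' optimal contrast is `-N^2 / D`.
#'
#' @param spikes the target unit's spike times.
#' @param intervals the condition's intervals (tibble `start`, `end`).
#' @return object of class `"poisson_fit"`: list with `rate`, `n`,
#'   `duration`, `contrast`.
#' @export
fit_poisson <- function(spikes, intervals) {
  iv <- as_intervals(intervals)
  D <- interval_duration(iv)
  if (D <= 0) abort("zero total duration")
  N <- count_in_intervals(spikes, iv)
  structure(
    list(rate = N / D, n = N, duration = D, contrast = -N^2 / D),
    class = "poisson_fit"
  )
}

# Predictor evaluation: for sorted spike vector `train` and evaluation
# times `t`, the count of spikes at lags in [w(i-1), wi) excluding lag 0.
# U_j = #{T <= t - j*w}; bin i >= 2: U_{i-1} - U_i; bin 1 uses the strict
# count #{T < t} so simultaneous spikes (lag 0) never enter.
lag_bin_counts <- function(train, t, n_bins = KERNEL_BINS,
                           w = KERNEL_BIN_WIDTH) {
  U <- vapply(0:n_bins, function(j) findInterval(t - j * w, train),
              numeric(length(t)))
  if (length(t) == 1) U <- matrix(U, nrow = 1)
  U0s <- findInterval(t, train, left.open = TRUE)
  X <- U[, 1:n_bins, drop = FALSE] - U[, 2:(n_bins + 1), drop = FALSE]
  X[, 1] <- U0s - U[, 2]
  X
}

# Breakpoint grid of the piecewise-constant predictors inside the
# intervals: interval edges plus every spike time shifted by the lag-bin
# edges. Returns midpoints and segment lengths.
predictor_segments <- function(all_spikes, intervals) {
  iv <- as_intervals(intervals)
  mids <- numeric(0)
  lens <- numeric(0)
  shifts <- KERNEL_BIN_WIDTH * (0:KERNEL_BINS)
  for (r in seq_len(nrow(iv))) {
    s <- iv$start[r]
    e <- iv$end[r]
    cand <- all_spikes[all_spikes > s - 0.061 & all_spikes < e]
    bp <- outer(cand, shifts, "+")
    bp <- bp[bp > s & bp < e]
    edges <- sort(unique(c(s, bp, e)))
    mids <- c(mids, (edges[-1] + edges[-length(edges)]) / 2)
    lens <- c(lens, diff(edges))
  }
  list(mids = mids, lens = lens)
}

#' Build the least-squares design system for Hawkes estimation
#'
#' Computes the Gram matrix `G` of the constant-plus-lagged-count
#' predictors over the condition intervals (exact piecewise-constant
#' integration) and the moment vectors `b` for every unit (sums of the
#' predictors at that unit's spikes inside the intervals). Histories use
#' all session spikes; only evaluation times are restricted.
#'
#' @param spike_list list of sorted spike-time vectors, one per unit.
#' @param intervals condition intervals (tibble `start`, `end`).
#' @param target optional unit index; when given, the returned `b` is that
#'   unit's moment vector instead of the full matrix.
#' @return list of class `"hawkes_design"`: `G` (`(1+6N) x (1+6N)`), `b`
#'   (vector if `target` given, else `(1+6N) x N` matrix), `n_units`,
#'   `duration`, `n_target_spikes`.
#' @export
build_design <- function(spike_list, intervals, target = NULL) {
  iv <- as_intervals(intervals)
  if (!intervals_disjoint(iv)) abort("intervals must be disjoint")
  if (nrow(iv) == 0) abort("empty interval set")
  N <- length(spike_list)
  p <- 1L + KERNEL_BINS * N
  all_spikes <- sort(unlist(spike_list, use.names = FALSE))
  seg <- predictor_segments(all_spikes, iv)
  X <- matrix(0, nrow = length(seg$mids), ncol = p)
  X[, 1] <- 1
  for (m in seq_len(N)) {
    cols <- 1L + (m - 1L) * KERNEL_BINS + seq_len(KERNEL_BINS)
    X[, cols] <- lag_bin_counts(spike_list[[m]], seg$mids)
  }
  G <- crossprod(X, X * seg$lens)
  eval_b <- function(u) {
    ts <- spikes_in_intervals(spike_list[[u]], iv)
    if (length(ts) == 0) return(numeric(p))
    xb <- matrix(0, nrow = length(ts), ncol = p)
    xb[, 1] <- 1
    for (m in seq_len(N)) {
      cols <- 1L + (m - 1L) * KERNEL_BINS + seq_len(KERNEL_BINS)
      xb[, cols] <- lag_bin_counts(spike_list[[m]], ts)
    }
    colSums(xb)
  }
  if (!is.null(target)) {
    b <- eval_b(target)
    nts <- count_in_intervals(spike_list[[target]], iv)
  } else {
    b <- vapply(seq_len(N), eval_b, numeric(p))
    nts <- vapply(seq_len(N), function(u)
      count_in_intervals(spike_list[[u]], iv), numeric(1))
  }
  structure(
    list(G = G, b = b, n_units = N, target = target,
         duration = interval_duration(iv), n_target_spikes = nts),
    class = "hawkes_design"
  )
}

solve_normal_equations <- function(G, b, ridge_scale = 1e-8) {
  theta <- tryCatch(solve(G, b), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(theta) || any(!is.finite(theta))) {
    lam <- ridge_scale * sum(diag(G)) / nrow(G)
    theta <- solve(G + diag(lam, nrow(G)), b)
    ridged <- TRUE
    inform("singular Gram matrix: ridge fallback applied")
  }
  list(theta = theta, ridged = ridged)
}

unpack_theta <- function(theta, n_units) {
  a <- matrix(theta[-1], nrow = KERNEL_BINS, ncol = n_units)
  list(mu = theta[1], a = t(a))  # a[source m, bin i]
}

#' Fit one target unit's Hawkes parameters from a design system
#'
#' Solves the normal equations `G theta = b`; a singular Gram matrix
#' (e.g. silent units) triggers a logged ridge fallback
#' (`1e-8 * trace(G) / dim`). Negative coefficients are permitted
#' (inhibition, with rectified-intensity interpretation).
#'
#' @param design a `"hawkes_design"` built with a `target`, or pass
#'   `target` to select a column of a full design.
#' @param target unit index when `design` holds all moment vectors.
#' @return object of class `"hawkes_fit"`: `mu` (Hz), `a` (`N x 6` matrix
#'   of plateau values, rows = source unit), `theta`, `target`, `ridged`,
#'   `n_units`.
#' @export
fit_hawkes <- function(design, target = NULL) {
  stopifnot(inherits(design, "hawkes_design"))
  if (is.null(target)) target <- design$target
  b <- if (is.matrix(design$b)) design$b[, target] else design$b
  ns <- if (length(design$n_target_spikes) > 1)
    design$n_target_spikes[target] else design$n_target_spikes
  if (ns == 0 && all(b == 0)) {
    th <- numeric(nrow(design$G))
    up <- unpack_theta(th, design$n_units)
    return(structure(
      list(mu = up$mu, a = up$a, theta = th, target = target,
           ridged = FALSE, n_units = design$n_units),
      class = "hawkes_fit"
    ))
  }
  sol <- solve_normal_equations(design$G, b)
  up <- unpack_theta(sol$theta, design$n_units)
  structure(
    list(mu = up$mu, a = up$a, theta = sol$theta, target = target,
         ridged = sol$ridged, n_units = design$n_units),
    class = "hawkes_fit"
  )
}

#' Fit the full per-condition Hawkes network
#'
#' One design system per condition (shared Gram matrix), one linear solve
#' per target unit: `N + 6 N^2` parameters per condition, self-edges
#' included.
#'
#' @param spike_list list of sorted spike-time vectors, one per unit.
#' @param condition_intervals tibble `condition`, `start`, `end` (see
#'   [build_condition_intervals()]).
#' @return object of class `"hawkes_network"`: per condition `mu` (length
#'   N) and `a` (`N x N x 6`, `a[m, n, i]` = kernel m -> n on lag bin i).
#' @export
fit_hawkes_network <- function(spike_list, condition_intervals) {
  N <- length(spike_list)
  conds <- unique(condition_intervals$condition)
  fits <- lapply(conds, function(k) {
    iv <- condition_intervals[condition_intervals$condition == k,
                              c("start", "end")]
    des <- build_design(spike_list, iv)
    mu <- numeric(N)
    a <- array(0, dim = c(N, N, KERNEL_BINS))
    ridged <- logical(N)
    for (n in seq_len(N)) {
      f <- fit_hawkes(des, target = n)
      mu[n] <- f$mu
      a[, n, ] <- f$a
      ridged[n] <- f$ridged
    }
    list(mu = mu, a = a, ridged = ridged,
         duration = des$duration, n_spikes = des$n_target_spikes)
  })
  names(fits) <- conds
  structure(
    list(conditions = fits, n_units = N),
    class = "hawkes_network"
  )
}

#' Interaction strengths of a fitted Hawkes network
#'
#' The strength of edge m -> n is the L1 norm of its six plateau
#' coefficients, `sum_i |a[m, n, i]|` (Hz).
#'
#' @param network a `"hawkes_network"`.
#' @return tibble: `condition`, `source`, `target`, `strength`.
#' @export
interaction_strengths <- function(network) {
  stopifnot(inherits(network, "hawkes_network"))
  N <- network$n_units
  dplyr::bind_rows(lapply(names(network$conditions), function(k) {
    S <- apply(abs(network$conditions[[k]]$a), c(1, 2), sum)
    tibble::tibble(
      condition = k,
      source = rep(seq_len(N), times = N),
      target = rep(seq_len(N), each = N),
      strength = as.vector(S)
    )
  }))
}

#' Binarize interaction strengths at a pooled quantile threshold
#'
#' Edges whose strength exceeds the stated quantile of all pooled
#' estimated strengths (type-1 quantile, so with all-distinct strengths
#' exactly the top `1 - probs` fraction is kept) are set to 1.
#'
#' @param strengths tibble from [interaction_strengths()] (possibly
#'   pooled over sessions/conditions), or a `"hawkes_network"`.
#' @param probs quantile level (default 0.70).
#' @param threshold optional explicit threshold overriding the quantile.
#' @return the strengths tibble with a `binary` column; attribute
#'   `threshold` records the value used.
#' @export
interaction_graph <- function(strengths, probs = 0.70, threshold = NULL) {
  if (inherits(strengths, "hawkes_network")) {
    strengths <- interaction_strengths(strengths)
  }
  if (nrow(strengths) == 0) abort("empty edge set")
  if (is.null(threshold)) {
    threshold <- unname(quantile(strengths$strength, probs, type = 1))
  }
  strengths$binary <- as.integer(strengths$strength > threshold)
  attr(strengths, "threshold") <- threshold
  strengths
}

#' Evaluate the least-squares contrast of a fitted model
#'
#' `C = -2 sum_{target spikes in intervals} lambda(T) +
#' integral_intervals lambda(t)^2 dt`, with the intensity evaluated from
#' the fitted parameters using the full-session spike history and exact
#' piecewise integration.
#'
#' @param object a `"poisson_fit"` or `"hawkes_fit"`.
#' @param spike_list for Hawkes fits, the list of all units' spike
#'   trains; for Poisson fits, the target unit's spike-time vector.
#' @param intervals evaluation intervals (tibble `start`, `end`).
#' @param ... unused.
#' @return numeric contrast value.
#' @export
model_contrast <- function(object, spike_list, intervals, ...) {
  UseMethod("model_contrast")
}

#' @export
model_contrast.poisson_fit <- function(object, spike_list, intervals, ...) {
  iv <- as_intervals(intervals)
  N <- count_in_intervals(spike_list, iv)
  D <- interval_duration(iv)
  -2 * N * object$rate + object$rate^2 * D
}

#' @export
model_contrast.hawkes_fit <- function(object, spike_list, intervals, ...) {
  des <- build_design(spike_list, intervals, target = object$target)
  contrast_from_design(object$theta, des$G, des$b)
}

contrast_from_design <- function(theta, G, b) {
  drop(-2 * crossprod(theta, b) + crossprod(theta, G %*% theta))
}
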