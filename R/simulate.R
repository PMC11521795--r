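# Synthetic-data generator: behavior sessions, Poisson and Hawkes spike
# trains, and two-cluster waveform feature tables, all with ground-truth
# manifests so every downstream stage is testable without recordings.

#' Simulation configuration
#'
#' Assembles and validates all knobs of the synthetic-data generator. The
#' defaults describe a plausible recording session on the continuous
#' T-maze: a 20 min session, traversal durations drawn around the
#' taxonomy's per-path means, feeder dwell times of at least 1 s between
#' traversals (well beyond the 60 ms Hawkes kernel support, so trial
#' histories are independent), and MSN-like/FSI-like waveform feature
#' clusters separated by several standard deviations.
#'
#' @param seed integer master seed; expanded into per-stream child seeds.
#' @param n_units number of units to simulate.
#' @param session_duration session length in seconds (default 1200).
#' @param path_menu tibble with `label`, `nodes`, `correct`,
#'   `mean_duration` and `prob` (selection probability; must sum to 1).
#' @param inter_trial_gap minimum feeder dwell between traversals in
#'   seconds (must be at least 0.5).
#' @param baseline_rates per-unit baseline rates in Hz (recycled).
#' @param event_gains optional `n_units x 30` matrix of multiplicative
#'   gains, one per 100 ms bin of the six task events (event-major order
#'   A, B, R1, R2, O1, O2).
#' @param hawkes_spec optional per-condition list; each element is
#'   `list(mu = <Hz vector>, a = <N x N x 6 array>)` with `a[m, n, i]` the
#'   plateau value (Hz per spike) of the kernel from unit m to unit n on
#'   lag bin i. Condition names must be path labels.
#' @param unit_cluster_spec list with elements `msn` and `fsi`, each
#'   `list(mean = c(log_rate, pv_us, w_us), sd = ...)`.
#' @param p_correct_by_stage probability that a drawn trial is a correct
#'   path, per learning stage 1-4.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_units = 12L,
                       session_duration = 1200,
                       path_menu = NULL,
                       inter_trial_gap = 1.0,
                       baseline_rates = 5,
                       event_gains = NULL,
                       hawkes_spec = NULL,
                       unit_cluster_spec = default_unit_cluster_spec(),
                       p_correct_by_stage = c(0.5, 0.7, 0.8, 0.95)) {
  if (is.null(path_menu)) {
    path_menu <- path_taxonomy()
    path_menu$prob <- rep(1 / nrow(path_menu), nrow(path_menu))
  }
  validate_taxonomy(path_menu)
  if (!"prob" %in% names(path_menu)) {
    path_menu$prob <- rep(1 / nrow(path_menu), nrow(path_menu))
  }
  if (any(path_menu$prob < 0) || abs(sum(path_menu$prob) - 1) > 1e-8) {
    abort("path_menu$prob must be nonnegative and sum to 1")
  }
  if (inter_trial_gap < 0.5) {
    abort("inter_trial_gap must be >= 0.5 s (exceeds the 60 ms kernel support)")
  }
  baseline_rates <- rep_len(baseline_rates, n_units)
  if (any(baseline_rates < 0)) abort("baseline_rates must be nonnegative")
  if (!is.null(event_gains)) {
    event_gains <- matrix(event_gains, nrow = n_units, ncol = 30)
    if (any(event_gains < 0)) abort("event_gains must be nonnegative")
  }
  if (!is.null(hawkes_spec)) {
    for (k in names(hawkes_spec)) {
      check_hawkes_stability(hawkes_spec[[k]], k)
      if (length(hawkes_spec[[k]]$mu) != n_units ||
          dim(hawkes_spec[[k]]$a)[1] != n_units) {
        abort(sprintf("hawkes_spec condition %s does not match n_units", k))
      }
    }
  }
  for (cl in c("msn", "fsi")) {
    if (any(unit_cluster_spec[[cl]]$sd <= 0)) {
      abort("unit_cluster_spec standard deviations must be positive")
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_units = as.integer(n_units),
      session_duration = session_duration, path_menu = path_menu,
      inter_trial_gap = inter_trial_gap, baseline_rates = baseline_rates,
      event_gains = event_gains, hawkes_spec = hawkes_spec,
      unit_cluster_spec = unit_cluster_spec,
      p_correct_by_stage = p_correct_by_stage
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_unit_cluster_spec <- function() {
  list(
    msn = list(mean = c(log_rate = log(1.5), pv_us = 500, w_us = 300),
               sd = c(0.5, 40, 30)),
    fsi = list(mean = c(log_rate = log(15), pv_us = 250, w_us = 150),
               sd = c(0.5, 30, 20))
  )
}

# Branching matrix K[m, n] = integral of |h_{m->n}| = 0.01 * sum_i |a_mni|.
kernel_branching_matrix <- function(a) {
  apply(abs(a), c(1, 2), sum) * 0.01
}

#' Kernel L1 mass (integral of the absolute kernel)
#'
#' The branching ratio of an edge: `0.01 * sum_i |a[m,n,i]|`. Distinct
#' from the interaction strength used for graphs, which is the plain sum
#' of plateau values (see [interaction_strengths()]).
#'
#' @param a `N x N x 6` kernel coefficient array.
#' @return `N x N` matrix of kernel masses.
#' @export
kernel_mass <- function(a) kernel_branching_matrix(a)

check_hawkes_stability <- function(spec, condition = "?") {
  if (length(dim(spec$a)) != 3 || dim(spec$a)[3] != 6) {
    abort(sprintf("condition %s: `a` must be an N x N x 6 array", condition))
  }
  K <- kernel_branching_matrix(spec$a)
  rho <- max(Mod(eigen(K, only.values = TRUE)$values))
  if (rho >= 1) {
    abort(sprintf(
      "condition %s is unstable: kernel branching spectral radius %.3f >= 1",
      condition, rho
    ))
  }
  invisible(rho)
}

#' Generate a synthetic behavior session
#'
#' Draws a chain of elementary paths from the configured menu. Each trial
#' is drawn among the menu paths starting at the rat's current feeder; the
#' correct/incorrect mix depends on the learning stage through
#' `p_correct_by_stage`. Traversal durations are gamma-distributed around
#' each path's mean duration (CV 20%), zone entries are spread evenly over
#' the traversal, and consecutive traversals are separated by a feeder
#' dwell of at least `inter_trial_gap` seconds.
#'
#' @param config a [sim_config()].
#' @param stage learning-stage label 1-4, or `NULL` to use the raw menu
#'   probabilities.
#' @return object of class `"behavior_session"`: list with `zones` (tibble
#'   `time_s`, `zone_id`), `duration`, `stage` and the ground-truth trial
#'   table `truth` (`trial_id`, `label`, `correct`, `start_s`, `end_s`).
#' @export
gen_behavior_session <- function(config, stage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  menu <- config$path_menu
  local_seed(child_seed(config$seed, 0L), {
    p_cor <- if (is.null(stage)) NA_real_ else config$p_correct_by_stage[[stage]]
    firsts <- vapply(menu$nodes, function(x) x[[1]], character(1))
    feeder <- "F1"
    t <- 0
    zone_t <- 0
    zone_id <- feeder
    truth <- list()
    trial <- 0L
    repeat {
      gap <- config$inter_trial_gap + rexp(1, rate = 2)
      avail <- which(firsts == feeder)
      if (length(avail) == 0) break
      w <- menu$prob[avail]
      if (!is.na(p_cor)) {
        cor_av <- menu$correct[avail]
        w <- ifelse(cor_av, p_cor * w / max(sum(w[cor_av]), 1e-12),
                    (1 - p_cor) * w / max(sum(w[!cor_av]), 1e-12))
      }
      pick <- avail[sample.int(length(avail), 1, prob = w)]
      nodes <- menu$nodes[[pick]]
      dur <- rgamma(1, shape = 25, rate = 25 / menu$mean_duration[pick])
      t_start <- t + gap
      if (t_start + dur > config$session_duration) break
      legs <- length(nodes) - 1
      entries <- t_start + dur * seq_len(legs) / legs
      zone_t <- c(zone_t, entries)
      zone_id <- c(zone_id, nodes[-1])
      trial <- trial + 1L
      truth[[trial]] <- tibble::tibble(
        trial_id = trial, label = menu$label[pick],
        correct = menu$correct[pick],
        start_s = entries[1], end_s = entries[legs]
      )
      feeder <- nodes[length(nodes)]
      t <- entries[legs]
    }
    structure(
      list(
        session_id = sprintf("sim-%d", config$seed),
        zones = tibble::tibble(time_s = zone_t, zone_id = zone_id),
        duration = config$session_duration,
        stage = stage,
        truth = if (trial > 0) dplyr::bind_rows(truth) else
          tibble::tibble(trial_id = integer(0), label = character(0),
                         correct = logical(0), start_s = numeric(0),
                         end_s = numeric(0))
      ),
      class = "behavior_session"
    )
  })
}

#' Homogeneous Poisson spike train on a union of intervals
#'
#' @param rate firing rate in Hz (nonnegative).
#' @param intervals disjoint half-open intervals (tibble/matrix with
#'   `start`, `end`).
#' @param seed optional seed (caller RNG state is restored).
#' @return sorted numeric vector of spike times.
#' @export
gen_homogeneous_poisson <- function(rate, intervals, seed = NULL) {
  if (rate < 0) abort("rate must be nonnegative")
  iv <- as_intervals(intervals)
  if (!intervals_disjoint(iv)) abort("intervals must be disjoint")
  local_seed(seed, {
    lens <- iv$end - iv$start
    D <- sum(lens)
    n <- rpois(1, rate * D)
    if (n == 0 || D == 0) return(numeric(0))
    u <- runif(n, 0, D)
    cum <- cumsum(lens)
    idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    idx <- pmin(idx, length(lens))
    sort(iv$start[idx] + (u - c(0, cum)[idx]))
  })
}

#' Event-modulated inhomogeneous Poisson spike train
#'
#' Piecewise-constant intensity: `baseline * gain` inside each 100 ms
#' task-event bin, `baseline` elsewhere in the session.
#'
#' @param baseline baseline rate in Hz.
#' @param gains numeric vector of 30 nonnegative gains (event-major order
#'   A, B, R1, R2, O1, O2 with five 100 ms bins each), or a 6 x 5 matrix.
#' @param bins event bins as produced by [event_bins()].
#' @param duration session duration in seconds.
#' @param seed optional seed.
#' @return sorted numeric vector of spike times.
#' @export
gen_event_modulated_train <- function(baseline, gains, bins, duration,
                                      seed = NULL) {
  if (nrow(bins) == 0) abort("session has no event windows")
  if (is.matrix(gains)) {
    stopifnot(all(dim(gains) == c(6, 5)))
    gains <- t(gains)  # 5 x 6, [bin, event]
  } else {
    gains <- matrix(rep_len(gains, 30), nrow = 5)  # event-major vector
  }
  if (any(gains < 0)) abort("gains must be nonnegative")
  ev_idx <- match(bins$event, task_events())
  rate_bin <- baseline * gains[cbind(bins$bin, ev_idx)]
  local_seed(seed, {
    spikes <- numeric(0)
    for (g in unique(rate_bin)) {
      sel <- bins[rate_bin == g, c("start", "end")]
      spikes <- c(spikes, gen_homogeneous_poisson(g, sel))
    }
    comp <- interval_complement(
      dplyr::arrange(bins[, c("start", "end")], .data$start), 0, duration
    )
    spikes <- c(spikes, gen_homogeneous_poisson(baseline, comp))
    sort(spikes)
  })
}

# Ogata thinning for a multivariate Hawkes process with piecewise-constant
# kernels on six 10 ms lag bins. The intensity upper bound is recomputed
# locally: each in-window past spike of unit m contributes at most
# max_i a+[m, n, i] to unit n, and spikes never re-enter the 60 ms window,
# so the bound stays valid between accepted events. Negative coefficients
# are supported via rectified intensity max(0, lambda) (approximate).
sim_hawkes_thinning <- function(mu, a, duration, rectify = any(a < 0)) {
  N <- length(mu)
  support <- 0.06
  # A2[(m-1)*6 + i, n] = a[m, n, i]
  A2 <- matrix(0, nrow = N * 6, ncol = N)
  for (m in seq_len(N)) {
    for (i in 1:6) A2[(m - 1) * 6 + i, ] <- a[m, , i]
  }
  s_bound <- vapply(seq_len(N), function(m) {
    sum(apply(matrix(pmax(a[m, , ], 0), nrow = N), 1, max))
  }, numeric(1))
  B0 <- sum(pmax(mu, 0))
  times <- numeric(512)
  units <- integer(512)
  nsp <- 0L
  lo <- 1L
  t <- 0
  B <- B0
  if (B0 <= 0 && all(s_bound <= 0)) {
    return(tibble::tibble(unit_id = integer(0), time_s = numeric(0)))
  }
  while (t < duration) {
    if (B <= 0) break
    t <- t + rexp(1, rate = B)
    if (t >= duration) break
    while (lo <= nsp && times[lo] <= t - support) lo <- lo + 1L
    if (lo <= nsp) {
      idx <- lo:nsp
      lags <- t - times[idx]
      bins <- floor(lags / 0.01) + 1
      ok <- bins >= 1 & bins <= 6
      if (any(ok)) {
        rows <- (units[idx[ok]] - 1L) * 6L + as.integer(bins[ok])
        lam <- mu + colSums(A2[rows, , drop = FALSE])
      } else {
        lam <- mu
      }
    } else {
      lam <- mu
    }
    if (rectify) lam <- pmax(lam, 0)
    tot <- sum(lam)
    if (tot > B + 1e-9) {
      # defensive: bound violated only by numerical slack
      B <- tot
    }
    if (runif(1) <= tot / B) {
      u <- sample.int(N, 1, prob = lam)
      nsp <- nsp + 1L
      if (nsp > length(times)) {
        times <- c(times, numeric(length(times)))
        units <- c(units, integer(length(units)))
      }
      times[nsp] <- t
      units[nsp] <- u
      B <- B0 + sum(s_bound[units[lo:nsp]])
    }
  }
  tibble::tibble(unit_id = units[seq_len(nsp)], time_s = times[seq_len(nsp)])
}

#' Simulate condition-dependent multivariate Hawkes spike trains
#'
#' Within each trial, spikes are generated by Ogata thinning from the
#' intensity `mu[n] + sum_m sum_{T < t} h_{m->n}(t - T)` with the trial's
#' condition parameters. History does not cross trials; with the enforced
#' inter-trial gap exceeding the 60 ms kernel support this is exact for
#' nonnegative kernels.
#'
#' @param spec per-condition list of `list(mu, a)` (see [sim_config()]).
#' @param trials tibble with `start`, `end`, `condition`.
#' @param seed optional seed.
#' @return tibble with `unit_id`, `time_s`, sorted by time.
#' @export
gen_hawkes_session <- function(spec, trials, seed = NULL) {
  for (k in names(spec)) check_hawkes_stability(spec[[k]], k)
  missing_k <- setdiff(unique(trials$condition), names(spec))
  if (length(missing_k) > 0) {
    abort(paste0("no Hawkes spec for condition(s): ",
                 paste(missing_k, collapse = ", ")))
  }
  local_seed(seed, {
    out <- vector("list", nrow(trials))
    for (j in seq_len(nrow(trials))) {
      sp <- spec[[trials$condition[j]]]
      tr <- sim_hawkes_thinning(sp$mu, sp$a, trials$end[j] - trials$start[j])
      tr$time_s <- tr$time_s + trials$start[j]
      out[[j]] <- tr
    }
    res <- dplyr::bind_rows(out)
    dplyr::arrange(res, .data$time_s)
  })
}

#' Generate a two-cluster unit waveform feature table
#'
#' Draws MSN-like and FSI-like units from Gaussian clusters in
#' (log firing rate, peak-valley distance, width at half height) space.
#'
#' @param spec cluster spec (see [default_unit_cluster_spec()]).
#' @param n_msn,n_fsi cluster sizes (`n_msn` must be positive; `n_fsi`
#'   may be zero for a single-cluster table).
#' @param seed optional seed.
#' @return tibble `unit_id`, `log_rate`, `pv_us`, `w_us`, `true_type`.
#' @export
gen_unit_feature_table <- function(spec = default_unit_cluster_spec(),
                                   n_msn = 40, n_fsi = 15, seed = NULL) {
  if (n_msn <= 0 || n_fsi < 0) {
    abort("n_msn must be positive and n_fsi nonnegative")
  }
  local_seed(seed, {
    draw <- function(cl, n, type) {
      if (n == 0) return(NULL)
      tibble::tibble(
        log_rate = rnorm(n, cl$mean[1], cl$sd[1]),
        pv_us = rnorm(n, cl$mean[2], cl$sd[2]),
        w_us = rnorm(n, cl$mean[3], cl$sd[3]),
        true_type = type
      )
    }
    out <- dplyr::bind_rows(
      draw(spec$msn, n_msn, "MSN"),
      draw(spec$fsi, n_fsi, "FSI")
    )
    out$unit_id <- seq_len(nrow(out))
    out[, c("unit_id", "log_rate", "pv_us", "w_us", "true_type")]
  })
}

#' Simulate a full session bundle with ground truth
#'
#' Generates a behavior session and one spike train per unit. If the
#' configuration carries a `hawkes_spec`, spikes inside classified trials
#' come from the per-condition Hawkes populations and spikes outside
#' trials from baseline-rate Poisson units; otherwise units are
#' event-modulated Poisson with the configured gains (or homogeneous if no
#' gains are set). A waveform feature table and a ground-truth manifest
#' are attached.
#'
#' @inheritParams gen_behavior_session
#' @return list of class `"session_bundle"` with `zones`, `spikes`
#'   (tibble `unit_id`, `time_s`), `units`, `duration`, `config` and
#'   `manifest`.
#' @export
simulate_session <- function(config, stage = NULL) {
  beh <- gen_behavior_session(config, stage)
  n <- config$n_units
  if (!is.null(config$hawkes_spec)) {
    trials <- beh$truth[beh$truth$label %in% names(config$hawkes_spec),
                        c("start_s", "end_s", "label")]
    names(trials) <- c("start", "end", "condition")
    spikes <- gen_hawkes_session(config$hawkes_spec, trials,
                                 seed = child_seed(config$seed, 1L))
    gaps <- interval_complement(trials[, c("start", "end")], 0, beh$duration)
    for (u in seq_len(n)) {
      bg <- gen_homogeneous_poisson(config$baseline_rates[u], gaps,
                                    seed = child_seed(config$seed, 100L + u))
      spikes <- dplyr::bind_rows(
        spikes, tibble::tibble(unit_id = u, time_s = bg)
      )
    }
    spikes <- dplyr::arrange(spikes, .data$time_s)
  } else {
    bins <- event_bins(extract_event_windows(beh$zones, beh$duration))
    trains <- lapply(seq_len(n), function(u) {
      s <- if (is.null(config$event_gains)) {
        gen_homogeneous_poisson(
          config$baseline_rates[u],
          tibble::tibble(start = 0, end = beh$duration),
          seed = child_seed(config$seed, 100L + u)
        )
      } else {
        gen_event_modulated_train(
          config$baseline_rates[u], config$event_gains[u, ], bins,
          beh$duration, seed = child_seed(config$seed, 100L + u)
        )
      }
      tibble::tibble(unit_id = u, time_s = s)
    })
    spikes <- dplyr::arrange(dplyr::bind_rows(trains), .data$time_s)
  }
  n_fsi <- max(1L, round(n * 0.3))
  units <- gen_unit_feature_table(config$unit_cluster_spec,
                                  n_msn = n - n_fsi, n_fsi = n_fsi,
                                  seed = child_seed(config$seed, 2L))
  truly_modulated <- if (is.null(config$event_gains)) rep(FALSE, n) else
    apply(config$event_gains != 1, 1, any)
  structure(
    list(
      session_id = beh$session_id,
      zones = beh$zones, spikes = spikes, units = units,
      duration = beh$duration, stage = stage, config = config,
      manifest = list(
        trials = beh$truth,
        unit_types = units[, c("unit_id", "true_type")],
        hawkes_spec = config$hawkes_spec,
        event_gains = config$event_gains,
        truly_modulated = truly_modulated
      )
    ),
    class = "session_bundle"
  )
}
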