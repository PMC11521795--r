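# Population activity: per-unit z-score profiles over the 30 task-event
# bins, population average curves with Bonferroni confidence bands, and
# the binned z-score entropy estimator.

#' Mean firing rate per 100 ms task-event bin
#'
#' For bin t of an event with P passages, the rate is
#' `f_t = (spikes in bin t across passages) / (0.1 * P)` Hz. Events with
#' no passages yield missing bins.
#'
#' @param spikes numeric vector of one unit's spike times.
#' @param frames behavioral frames from [behavior_frames()] (or a list
#'   with `events` and `bins`).
#' @return tibble with 30 rows: `event`, `bin`, `bin_index` (1-30 in
#'   canonical event order), `rate` (Hz, NA if the event has no
#'   passages), `n_passages`.
#' @export
bin_firing_rates <- function(spikes, frames) {
  bins <- frames$bins
  n_pass <- table(frames$events$event)
  grid <- tibble::tibble(
    event = rep(task_events(), each = 5),
    bin = rep(1:5, times = 6)
  )
  grid$bin_index <- seq_len(30)
  grid$n_passages <- as.integer(n_pass[grid$event])
  grid$n_passages[is.na(grid$n_passages)] <- 0L
  grid$rate <- vapply(seq_len(30), function(r) {
    if (grid$n_passages[r] == 0) return(NA_real_)
    sel <- bins[bins$event == grid$event[r] & bins$bin == grid$bin[r],
                c("start", "end")]
    count_in_intervals(spikes, sel) / (0.1 * grid$n_passages[r])
  }, numeric(1))
  grid[, c("event", "bin", "bin_index", "rate", "n_passages")]
}

#' Z-score a firing-rate profile over bins
#'
#' `z_t = (f_t - mean(f)) / sd(f)` with the sample standard deviation over
#' bins. Profiles with zero dispersion are marked excluded rather than
#' producing NaNs, and are left out of population curves.
#'
#' @param rates output of [bin_firing_rates()], or a numeric vector of
#'   per-bin rates.
#' @return the input as a tibble with a `z` column; attribute `excluded`
#'   is `TRUE` when `sd(f) = 0`.
#' @export
zscore_profile <- function(rates) {
  if (is.numeric(rates)) {
    rates <- tibble::tibble(bin_index = seq_along(rates), rate = rates)
  }
  f <- rates$rate
  ok <- !is.na(f)
  if (sum(ok) < 2) abort("need at least 2 non-missing bins")
  s <- sd(f[ok])
  if (s == 0) {
    rates$z <- NA_real_
    attr(rates, "excluded") <- TRUE
    return(rates)
  }
  rates$z <- (f - mean(f[ok])) / s
  attr(rates, "excluded") <- FALSE
  rates
}

#' Population mean z-score curves with Bonferroni confidence bands
#'
#' Per group (for example region x learning stage) and per bin, the mean
#' z-score over units with a normal confidence band
#' `mean +/- q * sd / sqrt(n)` where `q = qnorm(1 - alpha / (2 m))` and
#' `m` is the total number of comparisons (number of curves times number
#' of bins; 8 curves x 30 bins = 240 gives the multiplier 3.71).
#'
#' @param profiles tibble with columns `group`, `unit_id`, `bin_index`,
#'   `z` (excluded units should be absent).
#' @param alpha family-wise level (default 0.05).
#' @param n_comparisons number of Bonferroni comparisons; default
#'   `n_groups * n_bins`.
#' @return tibble of class `"population_curves"`: `group`, `bin_index`,
#'   `mean_z`, `lo`, `hi`, `n_units` (bands are NA for single-unit
#'   groups).
#' @export
population_curves <- function(profiles, alpha = 0.05,
                              n_comparisons = NULL) {
  stopifnot(all(c("group", "unit_id", "bin_index", "z") %in% names(profiles)))
  n_groups <- dplyr::n_distinct(profiles$group)
  n_bins <- dplyr::n_distinct(profiles$bin_index)
  if (is.null(n_comparisons)) n_comparisons <- n_groups * n_bins
  q <- qnorm(1 - alpha / (2 * n_comparisons))
  out <- dplyr::summarise(
    dplyr::group_by(profiles, .data$group, .data$bin_index),
    mean_z = mean(.data$z, na.rm = TRUE),
    sd_z = sd(.data$z, na.rm = TRUE),
    n_units = dplyr::n_distinct(.data$unit_id),
    .groups = "drop"
  )
  out$lo <- out$mean_z - q * out$sd_z / sqrt(out$n_units)
  out$hi <- out$mean_z + q * out$sd_z / sqrt(out$n_units)
  out$lo[out$n_units < 2] <- NA_real_
  out$hi[out$n_units < 2] <- NA_real_
  attr(out, "multiplier") <- q
  class(out) <- c("population_curves", class(out))
  out
}

#' Binned z-score entropy estimator
#'
#' The z-score axis `[-3.5, 5.5]` is segmented into 18 bins of width 0.5;
#' with `Nz_I` the count in bin I and `Nz_tot` the total, the estimator is
#' `sum_{I: Nz_I > 0} (Nz_I / Nz_tot) * log(Nz_I / (0.5 * Nz_tot))`
#' (natural log). `Nz_I / (0.5 Nz_tot)` estimates the density inside bin
#' I, so the value is the plug-in estimate of the integral of p log p
#' (the negative differential entropy); the sign convention is kept as
#' defined. Out-of-range z-scores are clipped into the terminal bins so
#' that the counts always sum to `Nz_tot`.
#'
#' @param z numeric vector of z-scores.
#' @param weights optional nonnegative weights (fractional counts are
#'   allowed; the estimator depends only on count ratios).
#' @return object of class `"zscore_entropy"`: list with `value`,
#'   `counts` (length 18), `edges`, `n_total`.
#' @export
zscore_entropy <- function(z, weights = NULL) {
  z <- z[!is.na(z)]
  if (length(z) == 0) abort("empty z-score population")
  edges <- seq(-3.5, 5.5, by = 0.5)
  idx <- findInterval(z, edges)
  idx <- pmin(pmax(idx, 1L), 18L)
  if (is.null(weights)) weights <- rep(1, length(z))
  counts <- vapply(1:18, function(b) sum(weights[idx == b]), numeric(1))
  tot <- sum(counts)
  nz <- counts[counts > 0]
  value <- sum((nz / tot) * log(nz / (0.5 * tot)))
  structure(
    list(value = value, counts = counts, edges = edges, n_total = tot),
    class = "zscore_entropy"
  )
}

#' @export
print.zscore_entropy <- function(x, ...) {
  cat(sprintf("z-score entropy estimate: %.4f nats (n = %s)\n",
              x$value, format(x$n_total)))
  invisible(x)
}

#' Entropy contrasts across learning stages with bootstrap CIs
#'
#' For each region, the difference in z-score entropy between each stage
#' and stage 1, with a percentile bootstrap over units (each unit's
#' z-scores are resampled as a block) and Bonferroni correction of the CI
#' level across the group contrasts.
#'
#' @param profiles tibble with `region`, `stage`, `unit_id`, `z`.
#' @param n_boot bootstrap replicates (default 1000; below 100 warns).
#' @param seed optional seed.
#' @param alpha family-wise CI level (default 0.05).
#' @param n_contrasts Bonferroni divisor; default stages x regions.
#' @return tibble: `region`, `stage`, `entropy`, `delta`, `lo`, `hi`.
#' @export
entropy_stage_contrast <- function(profiles, n_boot = 1000, seed = NULL,
                                   alpha = 0.05, n_contrasts = NULL) {
  if (n_boot < 100) warn("n_boot < 100: bootstrap CIs will be unstable")
  regions <- unique(profiles$region)
  stages <- sort(unique(profiles$stage))
  if (is.null(n_contrasts)) n_contrasts <- length(regions) * length(stages)
  lev <- alpha / n_contrasts
  boot_entropy <- function(df) {
    units <- split(df$z, df$unit_id)
    draw <- units[sample.int(length(units), replace = TRUE)]
    zscore_entropy(unlist(draw, use.names = FALSE))$value
  }
  local_seed(seed, {
    out <- list()
    for (r in regions) {
      base <- profiles[profiles$region == r & profiles$stage == stages[1], ]
      if (nrow(base) == 0) abort(sprintf("region %s lacks stage-1 units", r))
      h1 <- zscore_entropy(base$z)$value
      for (s in stages) {
        cur <- profiles[profiles$region == r & profiles$stage == s, ]
        if (nrow(cur) == 0) next
        hs <- zscore_entropy(cur$z)$value
        deltas <- vapply(seq_len(n_boot), function(b) {
          boot_entropy(cur) - boot_entropy(base)
        }, numeric(1))
        ci <- quantile(deltas, c(lev / 2, 1 - lev / 2), names = FALSE)
        out[[length(out) + 1]] <- tibble::tibble(
          region = r, stage = s, entropy = hs, delta = hs - h1,
          lo = ci[1], hi = ci[2]
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
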