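# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single-target Hawkes fit
#'
#' @param x a `"hawkes_fit"`.
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `source`,
#'   `lag_bin`, `estimate` (the spontaneous rate has `term = "mu"`).
#' @method tidy hawkes_fit
#' @export
tidy.hawkes_fit <- function(x, ...) {
  N <- x$n_units
  dplyr::bind_rows(
    tibble::tibble(term = "mu", source = NA_integer_,
                   lag_bin = NA_integer_, estimate = x$mu),
    tibble::tibble(
      term = "kernel",
      source = rep(seq_len(N), each = KERNEL_BINS),
      lag_bin = rep(seq_len(KERNEL_BINS), times = N),
      estimate = as.vector(t(x$a))
    )
  )
}

#' @rdname tidy.hawkes_fit
#' @method glance hawkes_fit
#' @export
glance.hawkes_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target, n_units = x$n_units,
    n_parameters = length(x$theta), mu = x$mu,
    total_strength = sum(abs(x$a)), ridged = x$ridged
  )
}

#' Tidy a fitted Hawkes network into an edge table
#'
#' @param x a `"hawkes_network"`.
#' @param ... unused.
#' @return tibble: `condition`, `source`, `target`, `strength`.
#' @method tidy hawkes_network
#' @export
tidy.hawkes_network <- function(x, ...) {
  interaction_strengths(x)
}

#' @rdname tidy.hawkes_network
#' @method glance hawkes_network
#' @export
glance.hawkes_network <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$conditions), function(k) {
    ck <- x$conditions[[k]]
    tibble::tibble(
      condition = k, n_units = x$n_units,
      n_parameters = x$n_units + 6 * x$n_units^2,
      duration = ck$duration, mean_mu = mean(ck$mu),
      any_ridged = any(ck$ridged)
    )
  }))
}

#' Tidy a decoding result into per-trial predictions
#'
#' @param x a `"decoding_result"`.
#' @param ... unused.
#' @return tibble with `condition`, `predicted`, `correct` per test
#'   trial.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  out <- tibble::as_tibble(x$trials)
  out$correct <- out$predicted == out$condition
  out
}

#' @rdname tidy.decoding_result
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, power = x$power, reference = x$reference,
    n_paths = x$n_paths, n_units = x$n_units,
    n_test_trials = nrow(x$trials), mean_rate = x$mean_rate
  )
}

#' Tidy a z-score entropy estimate
#'
#' @param x a `"zscore_entropy"`.
#' @param ... unused.
#' @return tibble of bin counts with bin edges.
#' @method tidy zscore_entropy
#' @export
tidy.zscore_entropy <- function(x, ...) {
  tibble::tibble(
    bin = seq_along(x$counts),
    lower = x$edges[-length(x$edges)],
    upper = x$edges[-1],
    count = x$counts
  )
}

#' @rdname tidy.zscore_entropy
#' @method glance zscore_entropy
#' @export
glance.zscore_entropy <- function(x, ...) {
  tibble::tibble(value = x$value, n_total = x$n_total,
                 n_occupied_bins = sum(x$counts > 0))
}
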