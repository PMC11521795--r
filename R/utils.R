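#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform
#' @importFrom stats pchisq qnorm rexp rgamma rnorm rpois runif sd quantile
#'   p.adjust ks.test mahalanobis cov kmeans hclust cutree dist setNames
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream child seeds: adding streams never perturbs
# earlier ones. Kept below 2^31 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 1e9)
  as.integer(((s * 69621 + as.double(stream) * 30269 + 12345) %% 2147483562) + 1)
}

# --- interval helpers ------------------------------------------------------
# Intervals are half-open [start, end) in session-relative seconds.

as_intervals <- function(x) {
  if (is.matrix(x)) {
    x <- tibble::tibble(start = x[, 1], end = x[, 2])
  }
  if (!is.data.frame(x) || !all(c("start", "end") %in% names(x))) {
    abort("intervals must be a data frame with columns `start` and `end`")
  }
  x <- dplyr::arrange(tibble::as_tibble(x)[, c("start", "end")], .data$start)
  if (any(x$end <= x$start)) {
    abort("intervals must satisfy end > start")
  }
  x
}

intervals_disjoint <- function(x) {
  x <- as_intervals(x)
  nrow(x) < 2 || all(x$start[-1] >= x$end[-nrow(x)] - 1e-12)
}

interval_duration <- function(x) {
  x <- as_intervals(x)
  sum(x$end - x$start)
}

# Number of spikes falling inside a set of disjoint intervals.
count_in_intervals <- function(spikes, intervals) {
  if (length(spikes) == 0 || nrow(intervals) == 0) {
    return(0L)
  }
  iv <- as_intervals(intervals)
  edges <- as.vector(rbind(iv$start, iv$end))
  idx <- findInterval(spikes, edges)
  sum(idx %% 2 == 1)
}

# Subset of spikes inside disjoint intervals (order preserved).
spikes_in_intervals <- function(spikes, intervals) {
  if (length(spikes) == 0 || nrow(intervals) == 0) {
    return(numeric(0))
  }
  iv <- as_intervals(intervals)
  edges <- as.vector(rbind(iv$start, iv$end))
  spikes[findInterval(spikes, edges) %% 2 == 1]
}

# Complement of disjoint intervals within [domain_start, domain_end).
interval_complement <- function(intervals, domain_start, domain_end) {
  iv <- as_intervals(intervals)
  iv <- iv[iv$end > domain_start & iv$start < domain_end, , drop = FALSE]
  starts <- c(domain_start, pmin(iv$end, domain_end))
  ends <- c(pmax(iv$start, domain_start), domain_end)
  keep <- ends > starts + 1e-12
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Canonical task-event order used throughout: intersections, rewards, onsets.
task_events <- function() c("A", "B", "R1", "R2", "O1", "O2")
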