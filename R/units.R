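# Waveform-based MSN/FSI classification and L-ratio cluster quality.

#' Extract waveform features: peak-valley distance and half-height width
#'
#' `PV` is the time from the global peak to the next local minimum after
#' it; `W` is the duration over which the amplitude stays at or above half
#' the peak value, with linear interpolation at the crossings. Both are
#' invariant to amplitude scaling.
#'
#' @param amplitude sampled waveform amplitudes.
#' @param dt sampling step (e.g. in microseconds).
#' @return list with `pv` and `w` in the units of `dt`.
#' @export
extract_waveform_features <- function(amplitude, dt) {
  n <- length(amplitude)
  if (n < 3) abort("waveform too short")
  d <- diff(amplitude)
  if (all(d >= 0) || all(d <= 0)) abort("monotone waveform has no peak")
  peak <- which.max(amplitude)
  if (sum(amplitude == amplitude[peak]) > 1) {
    abort("waveform must have a unique global peak")
  }
  # next local minimum after the peak (or the end of the trace)
  valley <- n
  for (i in seq(peak + 1, n)) {
    left_ok <- amplitude[i] < amplitude[i - 1]
    right_ok <- i == n || amplitude[i] <= amplitude[i + 1]
    if (left_ok && right_ok) {
      valley <- i
      break
    }
  }
  pv <- (valley - peak) * dt
  half <- amplitude[peak] / 2
  cross_at <- function(i, j) {
    # linear interpolation of the half-height crossing between samples i, j
    i + (half - amplitude[i]) / (amplitude[j] - amplitude[i])
  }
  left <- peak
  while (left > 1 && amplitude[left - 1] >= half) left <- left - 1
  t_left <- if (left == 1) 1 else cross_at(left - 1, left)
  right <- peak
  while (right < n && amplitude[right + 1] >= half) right <- right + 1
  t_right <- if (right == n) n else
    right + (amplitude[right] - half) / (amplitude[right] - amplitude[right + 1])
  list(pv = pv, w = (t_right - t_left) * dt)
}

#' Classify units into putative MSN and FSI
#'
#' The three features (log firing rate, peak-valley distance, width at
#' half height) are centered and scaled; a Ward-2 hierarchical tree on
#' Euclidean distances is cut into two clusters, whose centroids seed a
#' k-means (k = 2) refinement, making the two-step procedure
#' deterministic. The cluster with higher mean log rate and smaller PV
#' and W (majority vote of the three indicators) is labeled FSI, the
#' other MSN.
#'
#' @param features tibble with `unit_id`, `log_rate`, `pv_us`, `w_us`.
#' @return tibble of class `"unit_classification"` with `unit_id`, `type`
#'   (`"MSN"`/`"FSI"`) and attributes `hclust` (the Ward tree),
#'   `silhouette` (mean silhouette width) and `low_separation` (flag when
#'   silhouette < 0.2).
#' @export
classify_units <- function(features) {
  stopifnot(all(c("unit_id", "log_rate", "pv_us", "w_us") %in% names(features)))
  X <- as.matrix(features[, c("log_rate", "pv_us", "w_us")])
  if (nrow(X) < 2) abort("need at least 2 units to classify")
  if (!all(is.finite(X))) abort("features must be finite")
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  dd <- dist(Xs)
  hc <- hclust(dd, method = "ward.D2")
  ward <- cutree(hc, k = 2)
  centroids <- rbind(colMeans(Xs[ward == 1, , drop = FALSE]),
                     colMeans(Xs[ward == 2, , drop = FALSE]))
  km <- kmeans(Xs, centers = centroids, iter.max = 100)
  cl <- km$cluster
  vote <- function(k) {
    own <- colMeans(X[cl == k, , drop = FALSE])
    oth <- colMeans(X[cl != k, , drop = FALSE])
    (own["log_rate"] > oth["log_rate"]) +
      (own["pv_us"] < oth["pv_us"]) + (own["w_us"] < oth["w_us"])
  }
  if (length(unique(cl)) == 2) {
    fsi_cluster <- if (vote(1) >= 2) 1L else 2L
    type <- ifelse(cl == fsi_cluster, "FSI", "MSN")
  } else {
    type <- rep("MSN", nrow(X))
  }
  sil <- mean_silhouette(as.matrix(dd), cl)
  low <- is.na(sil) || sil < 0.2
  if (low) {
    warn(sprintf("low cluster separation (mean silhouette %.2f); labels emitted anyway",
                 sil))
  }
  out <- tibble::tibble(unit_id = features$unit_id, type = type)
  attr(out, "hclust") <- hc
  attr(out, "features") <- features
  attr(out, "silhouette") <- sil
  attr(out, "low_separation") <- low
  class(out) <- c("unit_classification", class(out))
  out
}

mean_silhouette <- function(D, cl) {
  if (length(unique(cl)) < 2) return(NA_real_)
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    same <- cl == cl[i]
    same[i] <- FALSE
    a <- if (any(same)) mean(D[i, same]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k) {
      mean(D[i, cl == k])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' L-ratio of a cluster and its bootstrap percentile
#'
#' The L-ratio sums, over all non-cluster ("noise") points, the upper-tail
#' chi-squared probability of the squared Mahalanobis distance to the
#' cluster center (df = feature dimension), normalized by the cluster
#' size. Low values indicate a well-separated cluster. The percentile
#' locates the observed L-ratio within the distribution obtained from
#' `n_iter` random same-size clusters drawn from all points excluding the
#' cluster under test.
#'
#' @param cluster_features numeric matrix/data frame of the cluster's
#'   points (rows).
#' @param noise_features all other points from the same recording.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed optional seed.
#' @return list with `l_ratio`, `percentile` (0-100) and `null_l_ratios`.
#' @export
l_ratio_percentile <- function(cluster_features, noise_features,
                               n_iter = 1000, seed = NULL) {
  C <- as.matrix(cluster_features)
  Nz <- as.matrix(noise_features)
  obs <- l_ratio(C, Nz)
  m <- nrow(C)
  local_seed(seed, {
    sims <- vapply(seq_len(n_iter), function(b) {
      idx <- sample.int(nrow(Nz), m)
      l_ratio(Nz[idx, , drop = FALSE], Nz[-idx, , drop = FALSE])
    }, numeric(1))
    list(
      l_ratio = obs,
      percentile = 100 * mean(sims <= obs),
      null_l_ratios = sims
    )
  })
}

#' @rdname l_ratio_percentile
#' @export
l_ratio <- function(cluster_features, noise_features) {
  C <- as.matrix(cluster_features)
  Nz <- as.matrix(noise_features)
  d <- ncol(C)
  if (nrow(C) < d + 1) abort("cluster smaller than feature dimension + 1")
  S <- cov(C)
  if (!is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-12) {
    S <- S + diag(1e-8 * sum(diag(S)) / d, d)
    inform("l_ratio: singular covariance, ridge applied")
  }
  D2 <- mahalanobis(Nz, colMeans(C), S)
  sum(pchisq(D2, df = d, lower.tail = FALSE)) / nrow(C)
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}
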