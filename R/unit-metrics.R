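#' Waveform energy
#'
#' Energy of a discrete signal: the sum of squared moduli of its samples.
#' One of the waveform features used for spike sorting and cluster quality.
#'
#' @param waveform_samples Numeric (or complex) vector, non-empty, finite.
#' @return Scalar energy.
#' @examples
#' waveform_energy(c(1, -1, 2))  # 6
#' @export
waveform_energy <- function(waveform_samples) {
  if (length(waveform_samples) == 0) {
    abort("Waveform is empty.", class = "pc_validation_error")
  }
  if (!all(is.finite(Mod(waveform_samples)))) {
    abort("Waveform samples must be finite.", class = "pc_validation_error")
  }
  sum(Mod(waveform_samples)^2)
}

# Squared Mahalanobis distances of rows of `x` from the cluster defined by
# `mu` and `sigma_inv` (chol-based solve is done by the caller once).
mahal_sq <- function(x, mu, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) {
    # chol() can succeed numerically on a rank-deficient covariance;
    # treat a collapsed pivot as singular too
    tol <- sqrt(.Machine$double.eps) * max(diag(sigma))
    if (any(diag(ch)^2 < tol)) ch <- NULL
  }
  if (is.null(ch)) {
    abort("Cluster feature covariance is singular; cannot compute Mahalanobis distances. Consider a ridge via `ridge`.",
          class = "pc_singular_error")
  }
  d <- sweep(x, 2, mu)
  w <- backsolve(ch, t(d), transpose = TRUE)
  colSums(w^2)
}

cluster_moments <- function(cluster_features, ridge = 0) {
  mu <- colMeans(cluster_features)
  sigma <- stats::cov(cluster_features)
  if (ridge > 0) sigma <- sigma + diag(ridge, ncol(sigma))
  list(mu = mu, sigma = sigma)
}

#' Isolation distance of a spike cluster
#'
#' The squared Mahalanobis distance — with respect to the cluster's own
#' feature mean and covariance — of the n-th closest non-cluster spike,
#' where n is the cluster size.  Higher values indicate better isolation.
#' Undefined (`NA`) when fewer non-cluster spikes than cluster spikes
#' exist; the cell is then reported as missing, not rejected.
#'
#' @param cluster_features Numeric matrix, one row per cluster spike.
#' @param noncluster_features Numeric matrix of all other spikes' features.
#' @param ridge Optional ridge added to the covariance diagonal (default 0:
#'   a singular covariance is an error, not silently regularised).
#' @return Isolation distance, or `NA` if undefined.
#' @export
isolation_distance <- function(cluster_features, noncluster_features,
                               ridge = 0) {
  cluster_features <- as.matrix(cluster_features)
  noncluster_features <- as.matrix(noncluster_features)
  n_c <- nrow(cluster_features)
  if (nrow(noncluster_features) < n_c) return(NA_real_)
  mom <- cluster_moments(cluster_features, ridge)
  d2 <- mahal_sq(noncluster_features, mom$mu, mom$sigma)
  sort(d2, partial = n_c)[n_c]
}

#' L-ratio of a spike cluster
#'
#' `L = sum over non-cluster spikes of (1 - CDF_chisq_df(D^2))`, where
#' `D^2` is the squared Mahalanobis distance from the cluster, divided by
#' the number of spikes in the cluster.  Lower is better.  The chi-square
#' degrees of freedom default to the feature dimensionality; the
#' conventional value for 4-channel two-feature reductions is 8.
#'
#' @inheritParams isolation_distance
#' @param df Chi-square degrees of freedom (default: feature dimension).
#' @return The L-ratio.
#' @export
l_ratio <- function(cluster_features, noncluster_features,
                    df = ncol(as.matrix(cluster_features)), ridge = 0) {
  cluster_features <- as.matrix(cluster_features)
  noncluster_features <- as.matrix(noncluster_features)
  mom <- cluster_moments(cluster_features, ridge)
  d2 <- mahal_sq(noncluster_features, mom$mu, mom$sigma)
  sum(1 - pchisq(d2, df = df)) / nrow(cluster_features)
}

#' Cluster quality summary
#'
#' @inheritParams isolation_distance
#' @param df Chi-square degrees of freedom for the L-ratio.
#' @return A tibble with `isolation_distance`, `l_ratio`, `n_spikes`,
#'   `feature_dim`.
#' @export
cluster_quality <- function(cluster_features, noncluster_features,
                            df = ncol(as.matrix(cluster_features)),
                            ridge = 0) {
  cluster_features <- as.matrix(cluster_features)
  tibble::tibble(
    isolation_distance = isolation_distance(cluster_features,
                                            noncluster_features, ridge),
    l_ratio = l_ratio(cluster_features, noncluster_features, df, ridge),
    n_spikes = nrow(cluster_features),
    feature_dim = ncol(cluster_features)
  )
}

#' Mean firing rate under a locomotion mask
#'
#' Spike count during masked epochs divided by total masked time.  With no
#' mask, the whole session counts.
#'
#' @param train A [spike_train()].
#' @param speed Optional `speed_series` carrying the epoch grid.
#' @param mask Optional logical epoch mask (with `speed`).
#' @param session_duration Session duration in s, required when no mask is
#'   given.
#' @return Rate in Hz.
#' @export
mean_firing_rate <- function(train, speed = NULL, mask = NULL,
                             session_duration = NULL) {
  if (is.null(mask)) {
    if (is.null(session_duration)) {
      abort("Provide `session_duration` or a mask.", class = "pc_format_error")
    }
    if (session_duration <= 0) {
      abort("Zero session time: rate undefined.", class = "pc_validation_error")
    }
    return(length(train$spike_times) / session_duration)
  }
  ed <- attr(speed, "epoch_duration")
  masked_time <- sum(mask) * ed
  if (masked_time <= 0) {
    abort("Zero masked time: rate undefined.", class = "pc_validation_error")
  }
  n <- sum(mask_at_times(train$spike_times, speed, mask))
  n / masked_time
}

#' Pyramidal-cell classification
#'
#' A cluster is classified as a pyramidal neuron if all four criteria hold
#' (strict inequalities): isolation distance > 15, L-ratio < 0.2, mean
#' waveform width > 250 microseconds, and locomotion-masked mean firing
#' rate < 5 Hz.  A missing quality metric yields `FALSE` with the reason
#' recorded in the `"reasons"` attribute.
#'
#' @param train A [spike_train()] with `mean_waveform_width` set.
#' @param quality A row from [cluster_quality()].
#' @param rate Locomotion-masked mean firing rate in Hz (see
#'   [mean_firing_rate()]).
#' @param iso_min,lratio_max,width_min,rate_max Classification thresholds.
#' @return Logical scalar; attribute `reasons` lists failed criteria.
#' @export
classify_pyramidal <- function(train, quality, rate,
                               iso_min = 15, lratio_max = 0.2,
                               width_min = 250, rate_max = 5) {
  reasons <- character(0)
  if (is.na(quality$isolation_distance)) {
    reasons <- c(reasons, "isolation distance undefined")
  } else if (!(quality$isolation_distance > iso_min)) {
    reasons <- c(reasons, sprintf("Iso-D <= %g", iso_min))
  }
  if (is.na(quality$l_ratio) || !(quality$l_ratio < lratio_max)) {
    reasons <- c(reasons, sprintf("L-ratio >= %g", lratio_max))
  }
  if (is.na(train$mean_waveform_width) ||
      !(train$mean_waveform_width > width_min)) {
    reasons <- c(reasons, sprintf("width <= %g us", width_min))
  }
  if (is.na(rate) || !(rate < rate_max)) {
    reasons <- c(reasons, sprintf("rate >= %g Hz", rate_max))
  }
  structure(length(reasons) == 0, reasons = reasons)
}

#' Activity criterion
#'
#' A pyramidal cell counts as active in a session if its locomotion-masked
#' mean firing rate is strictly greater than 0.1 Hz and strictly less than
#' 5 Hz.
#'
#' @param rate Locomotion-masked mean rate in Hz.
#' @param rate_min,rate_max Bounds (strict).
#' @return Logical.
#' @export
is_active <- function(rate, rate_min = 0.1, rate_max = 5) {
  !is.na(rate) & rate > rate_min & rate < rate_max
}

# greedy maximal burst grouping: a burst is a maximal run of spikes whose
# consecutive ISIs are all < threshold; every other spike is a single.
burst_groups <- function(spike_times, isi_threshold_ms = 10) {
  n <- length(spike_times)
  if (n < 2) {
    return(list(n_bursts = 0L, n_singles = n, spikes_in_bursts = 0L))
  }
  short <- diff(spike_times) * 1000 < isi_threshold_ms
  r <- rle(short)
  n_bursts <- sum(r$values)
  spikes_in_bursts <- sum(r$lengths[r$values] + 1L)
  list(n_bursts = as.integer(n_bursts),
       n_singles = as.integer(n - spikes_in_bursts),
       spikes_in_bursts = as.integer(spikes_in_bursts))
}

#' Burst probability
#'
#' Bursts are maximal groups of two or more spikes whose consecutive
#' interspike intervals are all below the threshold (default 10 ms); all
#' remaining spikes are singles.  The burst probability is
#' `N_B / (N_B + N_S)` with `N_B` the number of bursts and `N_S` the
#' number of single spikes.
#'
#' @param train A [spike_train()] or numeric vector of spike times (s).
#' @param isi_threshold ISI threshold in milliseconds.
#' @return A tibble with `n_bursts`, `n_singles`, `burst_probability`,
#'   `isi_threshold`.
#' @examples
#' burst_probability(c(0, 0.005, 0.205, 0.210, 0.215, 0.415))
#' @export
burst_probability <- function(train, isi_threshold = 10) {
  st <- if (is_spike_train(train)) train$spike_times else as.numeric(train)
  g <- burst_groups(st, isi_threshold)
  denom <- g$n_bursts + g$n_singles
  tibble::tibble(
    n_bursts = g$n_bursts,
    n_singles = g$n_singles,
    burst_probability = if (denom > 0) g$n_bursts / denom else NA_real_,
    isi_threshold = isi_threshold
  )
}

#' Fraction of spikes fired in bursts
#'
#' Alternative burstiness definition: spikes belonging to bursts divided by
#' total spikes.  Reported alongside [burst_probability()].
#'
#' @inheritParams burst_probability
#' @return Fraction in `[0, 1]`, `NA` for an empty train.
#' @export
burst_spike_fraction <- function(train, isi_threshold = 10) {
  st <- if (is_spike_train(train)) train$spike_times else as.numeric(train)
  if (length(st) == 0) return(NA_real_)
  g <- burst_groups(st, isi_threshold)
  g$spikes_in_bursts / length(st)
}
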