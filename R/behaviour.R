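#' Per-epoch running speed
#'
#' Position samples are binned into non-overlapping epochs (default 500 ms)
#' and the speed of each epoch is the path length travelled within it
#' divided by the epoch duration.  This matches the epoch grid used for LFP
#' power binning and is robust to tracking jitter compared with an
#' instantaneous derivative.  Epochs containing fewer than two position
#' samples have undefined speed (`NA`) and are flagged.
#'
#' @param traj A [trajectory()].
#' @param epoch_duration Epoch length in seconds (default 0.5).
#' @return A tibble of class `"speed_series"` with columns `epoch_start`
#'   (s), `speed` (cm/s, `NA` if undefined) and `defined`; attribute
#'   `epoch_duration`.
#' @examples
#' trj <- simulate_trajectory(60, seed = 1)
#' head(compute_speed(trj))
#' @export
compute_speed <- function(traj, epoch_duration = 0.5) {
  if (!is_trajectory(traj)) {
    abort("`traj` must be a trajectory.", class = "pc_format_error")
  }
  t0 <- traj$time[1]
  total <- traj$time[length(traj$time)] - t0
  n_epochs <- max(1L, ceiling(total / epoch_duration - 1e-9))
  idx <- pmin(floor((traj$time - t0) / epoch_duration) + 1L, n_epochs)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  # attribute each step to the epoch of its starting sample
  step_epoch <- idx[-length(idx)]
  dist <- numeric(n_epochs)
  sums <- rowsum(step, step_epoch)
  dist[as.integer(rownames(sums))] <- sums[, 1]
  counts <- tabulate(idx, nbins = n_epochs)
  speed <- dist / epoch_duration
  speed[counts < 2] <- NA_real_
  tibble::new_tibble(
    list(epoch_start = t0 + (seq_len(n_epochs) - 1) * epoch_duration,
         speed = speed,
         defined = counts >= 2),
    nrow = n_epochs,
    class = "speed_series",
    epoch_duration = epoch_duration
  )
}

#' Locomotion mask over speed epochs
#'
#' Epochs with speed strictly greater than the threshold (default 3 cm/s)
#' count as locomotion; everything else — including epochs exactly at the
#' threshold and undefined epochs — does not.
#'
#' @param speed A `speed_series` from [compute_speed()].
#' @param threshold Speed threshold in cm/s (strict inequality).
#' @return Logical vector, one element per epoch.
#' @export
movement_mask <- function(speed, threshold = 3) {
  !is.na(speed$speed) & speed$speed > threshold
}

# Map arbitrary event times onto epoch membership of a logical epoch mask.
mask_at_times <- function(times, speed, mask) {
  ed <- attr(speed, "epoch_duration")
  idx <- floor((times - speed$epoch_start[1]) / ed) + 1L
  ok <- idx >= 1L & idx <= nrow(speed)
  out <- logical(length(times))
  out[ok] <- mask[idx[ok]]
  out
}

#' Path length of a trajectory
#'
#' Sum of successive-sample Euclidean displacements, optionally restricted
#' to epochs selected by a locomotion mask (steps whose starting sample
#' falls in a masked-out epoch are dropped).
#'
#' @param traj A [trajectory()].
#' @param mask Optional logical epoch mask from [movement_mask()]; requires
#'   `speed` to interpret epoch boundaries.
#' @param speed The `speed_series` the mask refers to (required with `mask`).
#' @return Path length in cm.
#' @export
path_length <- function(traj, mask = NULL, speed = NULL) {
  if (!is_trajectory(traj)) {
    abort("`traj` must be a trajectory.", class = "pc_format_error")
  }
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (is.null(mask)) return(sum(step))
  if (is.null(speed)) {
    abort("`speed` is required to interpret `mask`.", class = "pc_format_error")
  }
  keep <- mask_at_times(traj$time[-nrow(traj)], speed, mask)
  sum(step[keep])
}

# bin index grid shared by coverage and the spatial maps: square bins of
# side `bin_size` anchored at the arena centre; a bin belongs to the arena
# if its centre lies inside the disc.
arena_grid <- function(arena_radius, bin_size) {
  n_half <- ceiling(arena_radius / bin_size)
  edges <- seq(-n_half * bin_size, n_half * bin_size, by = bin_size)
  centers <- edges[-length(edges)] + bin_size / 2
  in_disc <- outer(centers^2, centers^2, `+`) < arena_radius^2  # [x, y]
  list(edges = edges, centers = centers, in_disc = in_disc,
       n = length(centers))
}

bin_positions <- function(x, y, grid) {
  ix <- findInterval(x, grid$edges, rightmost.closed = TRUE)
  iy <- findInterval(y, grid$edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= grid$n & iy >= 1 & iy <= grid$n
  list(ix = ix, iy = iy, ok = ok)
}

#' Arena coverage
#'
#' Percentage of arena bins visited, where a bin counts as visited if the
#' animal spent at least `min_occupancy` seconds in it (the same criterion
#' that admits a bin into the rate map) and the denominator is the set of
#' bins whose centre lies inside the arena disc.
#'
#' @param traj A [trajectory()].
#' @param bin_size Bin side in cm (default 2.5).
#' @param min_occupancy Minimum dwell time in s for a bin to count (0.1).
#' @return Coverage in percent.
#' @export
coverage <- function(traj, bin_size = 2.5, min_occupancy = 0.1) {
  if (!is_trajectory(traj)) {
    abort("`traj` must be a trajectory.", class = "pc_format_error")
  }
  grid <- arena_grid(attr(traj, "arena_radius"), bin_size)
  occ <- occupancy_grid(traj, grid)
  visited <- occ >= min_occupancy & grid$in_disc
  100 * sum(visited) / sum(grid$in_disc)
}

# seconds spent per bin; each sample contributes the interval to the next
# sample (the last sample contributes nothing), so total occupancy equals
# the session duration.
occupancy_grid <- function(traj, grid, keep = NULL) {
  dt <- c(diff(traj$time), 0)
  if (!is.null(keep)) dt[!keep] <- 0
  b <- bin_positions(traj$x, traj$y, grid)
  occ <- matrix(0, grid$n, grid$n)
  ok <- b$ok & dt > 0
  if (any(ok)) {
    flat <- (b$iy[ok] - 1L) * grid$n + b$ix[ok]
    sums <- rowsum(dt[ok], flat)
    occ[as.integer(rownames(sums))] <- sums[, 1]
  }
  occ
}

#' Post-immobility activity epochs
#'
#' Finds maximal runs of supra-threshold (locomotion) epochs that are
#' immediately preceded by at least one sub-threshold epoch and last at
#' least `run_duration` seconds, and returns the first `run_duration`
#' seconds of each.  These windows are where LFP band power is estimated.
#'
#' @param speed A `speed_series`.
#' @param run_duration Minimum (and returned) run length in s (default 4).
#' @param threshold Locomotion threshold in cm/s.
#' @return A tibble with columns `start`, `end` (s), one row per epoch.
#' @export
post_immobility_activity_epochs <- function(speed, run_duration = 4,
                                            threshold = 3) {
  mv <- movement_mask(speed, threshold)
  ed <- attr(speed, "epoch_duration")
  need <- ceiling(run_duration / ed)
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (k == 1) next                       # no preceding immobility
    if (r$lengths[k] < need) next
    s0 <- speed$epoch_start[starts[k]]
    out[[length(out) + 1]] <- c(s0, s0 + run_duration)
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

#' Time spent per speed bin
#'
#' Histogram of defined-epoch time over speed bins of fixed width
#' (default 3 cm/s, bins `[0,3), [3,6), ...`).  Total time is conserved:
#' the bin times sum to the number of defined epochs times the epoch
#' duration.
#'
#' @param speed A `speed_series`.
#' @param bin_width Speed bin width in cm/s.
#' @return A tibble with columns `speed_lo`, `speed_hi`, `time` (s).
#' @export
time_in_speed_bins <- function(speed, bin_width = 3) {
  ed <- attr(speed, "epoch_duration")
  v <- speed$speed[speed$defined]
  if (length(v) == 0) {
    return(tibble::tibble(speed_lo = 0, speed_hi = bin_width, time = 0))
  }
  idx <- floor(v / bin_width)
  n_bins <- max(idx) + 1
  counts <- tabulate(idx + 1L, nbins = n_bins)
  tibble::tibble(
    speed_lo = (seq_len(n_bins) - 1) * bin_width,
    speed_hi = seq_len(n_bins) * bin_width,
    time = counts * ed
  )
}
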