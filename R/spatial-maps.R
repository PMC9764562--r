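#' Occupancy map
#'
#' Time spent per 2.5-cm square bin, computed from (optionally
#' locomotion-masked) position samples on a grid anchored at the arena
#' centre.  Bins occupied for less than `min_occupancy` seconds are treated
#' as unvisited, and bins whose centre falls outside the arena disc are
#' never valid.
#'
#' @param traj A [trajectory()].
#' @param speed,mask Optional `speed_series` and logical epoch mask; when
#'   given, only samples in masked epochs contribute occupancy.
#' @param bin_size Bin side in cm.
#' @param min_occupancy Validity threshold in s.
#' @return A list of class `"occupancy_map"`: `occupancy` (matrix, seconds,
#'   indexed `[x, y]`), `valid` (logical matrix), `centers`, `bin_size`.
#' @export
occupancy_map <- function(traj, speed = NULL, mask = NULL, bin_size = 2.5,
                          min_occupancy = 0.1) {
  if (!is_trajectory(traj)) {
    abort("`traj` must be a trajectory.", class = "pc_format_error")
  }
  grid <- arena_grid(attr(traj, "arena_radius"), bin_size)
  keep <- if (!is.null(mask)) mask_at_times(traj$time, speed, mask) else NULL
  occ <- occupancy_grid(traj, grid, keep = keep)
  structure(
    list(occupancy = occ, valid = occ >= min_occupancy & grid$in_disc,
         centers = grid$centers, bin_size = bin_size,
         in_disc = grid$in_disc),
    class = "occupancy_map"
  )
}

# Gaussian kernel sums of a set of points evaluated at all bin centres.
# Returns a grid$n x grid$n matrix [x, y].  Chunked to bound memory.
kernel_sum_at_bins <- function(px, py, weights, centers, h) {
  n <- length(centers)
  out <- matrix(0, n, n)
  if (length(px) == 0) return(out)
  gx_all <- exp(-outer(centers, px, function(c, p) (c - p)^2) / (2 * h^2)) # n x N
  gy_all <- exp(-outer(centers, py, function(c, p) (c - p)^2) / (2 * h^2))
  # sum_i w_i * gx[, i] %o% gy[, i]  ==  gx %*% diag(w) %*% t(gy)
  gx_all %*% (weights * t(gy_all))
}

#' Gaussian-kernel firing-rate map
#'
#' Smoothed firing rate evaluated at each valid bin centre as the ratio of
#' a Gaussian kernel sum over spike positions to the kernel-weighted
#' occupancy integral, with kernel `g(x) = exp(-x^2/2)` and smoothing
#' width `h` (default 2.5 cm).  The occupancy integral is approximated by
#' a Riemann sum over the position samples at their native sampling
#' interval.  Bins are valid if occupied at least `min_occupancy` seconds
#' (raw, unsmoothed occupancy) and inside the arena.
#'
#' Spike positions are obtained by linear interpolation of the trajectory
#' at spike times.  When `speed` and `mask` are supplied, both spikes and
#' position samples are restricted to locomotion epochs.
#'
#' @param traj A [trajectory()].
#' @param train A [spike_train()] or numeric spike times (s).
#' @param speed,mask Optional locomotion mask (see [movement_mask()]).
#' @param bin_size Bin side in cm.
#' @param h Kernel smoothing width in cm.
#' @param min_occupancy Bin validity threshold in s.
#' @param denominator Optional precomputed kernel occupancy matrix (the
#'   trajectory-only part), as returned in the `kernel_occupancy` field;
#'   reuse it across cells sharing one trajectory.
#' @return A list of class `"rate_map"`: `rate` (Hz matrix `[x, y]`, `NA`
#'   outside valid bins), `occupancy` (raw seconds), `valid`, `centers`,
#'   `bin_size`, `h`, `n_spikes`, `kernel_occupancy`.
#' @export
rate_map <- function(traj, train, speed = NULL, mask = NULL, bin_size = 2.5,
                     h = 2.5, min_occupancy = 0.1, denominator = NULL) {
  om <- occupancy_map(traj, speed, mask, bin_size, min_occupancy)
  st <- if (is_spike_train(train)) train$spike_times else as.numeric(train)
  keep_sample <- if (!is.null(mask)) {
    mask_at_times(traj$time, speed, mask)
  } else rep(TRUE, nrow(traj))
  if (!is.null(mask)) st <- st[mask_at_times(st, speed, mask)]
  sx <- stats::approx(traj$time, traj$x, xout = st, rule = 2)$y
  sy <- stats::approx(traj$time, traj$y, xout = st, rule = 2)$y

  if (is.null(denominator)) {
    dt <- c(diff(traj$time), 0)
    dt[!keep_sample] <- 0
    denominator <- kernel_sum_at_bins(traj$x[dt > 0], traj$y[dt > 0],
                                      dt[dt > 0], om$centers, h)
  }
  numerator <- kernel_sum_at_bins(sx, sy, rep(1, length(sx)), om$centers, h)
  rate <- numerator / denominator
  valid <- om$valid & is.finite(rate)
  rate[!valid] <- NA_real_
  structure(
    list(rate = rate, occupancy = om$occupancy, valid = valid,
         centers = om$centers, bin_size = bin_size, h = h,
         n_spikes = length(sx), kernel_occupancy = denominator),
    class = "rate_map"
  )
}

#' Assemble a rate map from explicit grids
#'
#' Constructor for tests, toy examples and externally produced maps: takes
#' occupancy and rate matrices directly.
#'
#' @param occupancy Matrix of seconds per bin.
#' @param rate Matrix of rates (Hz), same shape.
#' @param bin_size Bin side in cm.
#' @param valid Optional logical matrix; default: occupancy > 0 and finite
#'   rate.
#' @return A `"rate_map"`.
#' @export
make_rate_map <- function(occupancy, rate, bin_size = 2.5, valid = NULL) {
  occupancy <- as.matrix(occupancy)
  rate <- as.matrix(rate)
  if (!all(dim(occupancy) == dim(rate))) {
    abort("`occupancy` and `rate` must have identical shape.",
          class = "pc_format_error")
  }
  if (is.null(valid)) valid <- occupancy > 0 & is.finite(rate)
  rate[!valid] <- NA_real_
  n <- nrow(occupancy)
  centers <- (seq_len(n) - (n + 1) / 2) * bin_size
  structure(
    list(rate = rate, occupancy = occupancy, valid = valid,
         centers = centers, bin_size = bin_size, h = NA_real_,
         n_spikes = NA_integer_, kernel_occupancy = NULL),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map: %dx%d bins of %.2g cm, %d valid, peak %.3g Hz>\n",
              nrow(x$rate), ncol(x$rate), x$bin_size, sum(x$valid),
              suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

# occupancy probabilities P_i and rates R_i over valid bins
map_pr <- function(map) {
  occ <- map$occupancy[map$valid]
  if (sum(occ) <= 0) {
    abort("Map has no valid occupancy.", class = "pc_validation_error")
  }
  list(p = occ / sum(occ), r = map$rate[map$valid])
}

#' Skaggs spatial information
#'
#' `SI = sum_i P_i (R_i / R) log2(R_i / R)` in bits per spike, where `P_i`
#' is the occupancy probability of bin i, `R_i` its firing rate, and
#' `R = sum_i P_i R_i` the overall mean rate.  Bins with zero rate
#' contribute zero (the `x log x -> 0` limit).
#'
#' @param map A `"rate_map"`.
#' @return SI in bits/spike; error if the overall rate is zero.
#' @export
spatial_information <- function(map) {
  pr <- map_pr(map)
  R <- sum(pr$p * pr$r)
  if (R <= 0) {
    abort("Overall rate is zero: spatial information undefined.",
          class = "pc_validation_error")
  }
  rel <- pr$r / R
  terms <- pr$p * rel * log2(rel)
  terms[pr$r == 0] <- 0
  sum(terms)
}

#' Spatial sparsity
#'
#' `(sum_i P_i R_i)^2 / sum_i P_i R_i^2`; 1 for spatially uniform firing,
#' approaching the occupancy share of the active region for compact
#' firing.
#'
#' @param map A `"rate_map"`.
#' @return Sparsity in `(0, 1]`.
#' @export
sparsity <- function(map) {
  pr <- map_pr(map)
  denom <- sum(pr$p * pr$r^2)
  if (denom <= 0) {
    abort("All rates zero: sparsity undefined.", class = "pc_validation_error")
  }
  sum(pr$p * pr$r)^2 / denom
}

#' Percentage of active bins
#'
#' Number of visited bins containing at least one (raw, unsmoothed) spike
#' position, divided by the number of visited bins.
#'
#' @param map A `"rate_map"` built by [rate_map()] (for its validity grid).
#' @param traj,train,speed,mask As in [rate_map()]; spike positions are
#'   re-derived raw so the statistic does not depend on smoothing.
#' @return Percentage in `[0, 100]`.
#' @export
percent_active_bins <- function(map, traj, train, speed = NULL, mask = NULL) {
  st <- if (is_spike_train(train)) train$spike_times else as.numeric(train)
  if (!is.null(mask)) st <- st[mask_at_times(st, speed, mask)]
  n_visited <- sum(map$valid)
  if (n_visited == 0) return(NA_real_)
  if (length(st) == 0) return(0)
  sx <- stats::approx(traj$time, traj$x, xout = st, rule = 2)$y
  sy <- stats::approx(traj$time, traj$y, xout = st, rule = 2)$y
  grid <- arena_grid(attr(traj, "arena_radius"), map$bin_size)
  b <- bin_positions(sx, sy, grid)
  hit <- matrix(FALSE, grid$n, grid$n)
  hit[cbind(b$ix[b$ok], b$iy[b$ok])] <- TRUE
  100 * sum(hit & map$valid) / n_visited
}

# connected components of a logical matrix (4- or 8-connectivity)
label_components <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dx = -1:1, dy = -1:1))[-5, ]
  }
  for (start in which(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (s - 1L) %% nr + 1L; j <- (s - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- c(stack, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  lab
}

#' Detect place fields
#'
#' A place field is a connected component (4-connectivity by default) of at
#' least `min_bins` valid bins whose firing rate exceeds
#' `threshold_frac` times the map maximum.  The main field is the
#' component containing the global peak bin (option: the largest field).
#' Field area is bin count times the bin area.
#'
#' @param map A `"rate_map"`.
#' @param min_bins Minimum component size (default 9).
#' @param threshold_frac Rate threshold as a fraction of the map maximum.
#' @param connectivity 4 (edge-sharing, default) or 8.
#' @param main Rule for the main field: `"peak"` (contains the global
#'   maximum) or `"largest"`.
#' @return A tibble with one row per field: `field_id`, `n_bins`,
#'   `area_cm2`, `peak_rate`, `is_main`.
#' @export
detect_place_fields <- function(map, min_bins = 9, threshold_frac = 0.2,
                                connectivity = 4, main = c("peak", "largest")) {
  main <- match.arg(main)
  empty <- tibble::tibble(field_id = integer(0), n_bins = integer(0),
                          area_cm2 = numeric(0), peak_rate = numeric(0),
                          is_main = logical(0))
  if (sum(map$valid) == 0) return(empty)
  mx <- max(map$rate[map$valid])
  if (!is.finite(mx) || mx <= 0) return(empty)
  supra <- map$valid & !is.na(map$rate) & map$rate > threshold_frac * mx
  lab <- label_components(supra, connectivity)
  if (max(lab) == 0) return(empty)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_bins)
  if (length(keep) == 0) return(empty)
  peak_bin <- which(map$rate == mx & map$valid)[1]
  fields <- purrr::map_dfr(seq_along(keep), function(k) {
    id <- keep[k]
    tibble::tibble(
      field_id = k,
      n_bins = sizes[id],
      area_cm2 = sizes[id] * map$bin_size^2,
      peak_rate = max(map$rate[lab == id], na.rm = TRUE),
      component = id
    )
  })
  is_main <- if (main == "peak" && lab[peak_bin] %in% keep) {
    fields$component == lab[peak_bin]
  } else {
    fields$n_bins == max(fields$n_bins) &
      seq_len(nrow(fields)) == which.max(fields$n_bins)
  }
  fields$is_main <- is_main
  fields$component <- NULL
  fields
}

#' Between-session rate-map stability
#'
#' Pearson correlation between two rate maps over the bins valid in both,
#' Fisher z-transformed (`z = atanh(r)`, with `|r|` clipped to
#' `1 - 1e-7`).  Cells are only eligible if their spatial information
#' exceeds `si_threshold` bits/spike in *both* sessions; otherwise the
#' pair is excluded (reported `NA` with a reason), not scored zero.
#'
#' @param map_a,map_b Two `"rate_map"`s on the same grid.
#' @param si_threshold SI inclusion threshold in bits/spike.
#' @param min_joint_bins Minimum number of jointly valid bins.
#' @return A one-row tibble: `r`, `z`, `n_bins`, `included`, `reason`.
#' @export
map_stability <- function(map_a, map_b, si_threshold = 0.5,
                          min_joint_bins = 10) {
  if (!all(dim(map_a$rate) == dim(map_b$rate))) {
    abort("Maps must share one grid.", class = "pc_format_error")
  }
  excluded <- function(reason) {
    tibble::tibble(r = NA_real_, z = NA_real_, n_bins = NA_integer_,
                   included = FALSE, reason = reason)
  }
  si_a <- tryCatch(spatial_information(map_a), error = function(e) NA_real_)
  si_b <- tryCatch(spatial_information(map_b), error = function(e) NA_real_)
  if (is.na(si_a) || si_a <= si_threshold) return(excluded("SI_a <= threshold"))
  if (is.na(si_b) || si_b <= si_threshold) return(excluded("SI_b <= threshold"))
  joint <- map_a$valid & map_b$valid
  if (sum(joint) < min_joint_bins) return(excluded("too few joint bins"))
  a <- map_a$rate[joint]; b <- map_b$rate[joint]
  if (sd(a) == 0 || sd(b) == 0) return(excluded("constant map"))
  r <- cor(a, b)
  tibble::tibble(r = r, z = fisher_z(r), n_bins = sum(joint),
                 included = TRUE, reason = NA_character_)
}
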