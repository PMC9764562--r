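#' Session schedule within the two-day protocol
#'
#' The recording protocol is three 10-min sessions per day over two
#' consecutive days, giving six sessions.  `session_schedule()` validates a
#' (day, session-in-day) pair and derives the overall session index
#' `3 * (day - 1) + session_in_day`; `schedule_from_index()` inverts it.
#'
#' @param day Day of the protocol, 1 or 2.
#' @param session_in_day Session within the day, 1 to 3.
#' @return A list of class `"session_schedule"` with fields `day`,
#'   `session_in_day` and `session_index` (1 to 6).
#' @examples
#' session_schedule(2, 1)$session_index  # 4
#' @export
session_schedule <- function(day, session_in_day) {
  day <- as.integer(day)
  session_in_day <- as.integer(session_in_day)
  if (!day %in% 1:2) abort("`day` must be 1 or 2.", class = "pc_validation_error")
  if (!session_in_day %in% 1:3) {
    abort("`session_in_day` must be 1, 2 or 3.", class = "pc_validation_error")
  }
  structure(
    list(day = day, session_in_day = session_in_day,
         session_index = 3L * (day - 1L) + session_in_day),
    class = "session_schedule"
  )
}

#' @rdname session_schedule
#' @param session_index Overall session index, 1 to 6.
#' @export
schedule_from_index <- function(session_index) {
  session_index <- as.integer(session_index)
  if (!session_index %in% 1:6) {
    abort("`session_index` must be in 1..6.", class = "pc_validation_error")
  }
  session_schedule(day = (session_index - 1L) %/% 3L + 1L,
                   session_in_day = (session_index - 1L) %% 3L + 1L)
}

#' Construct a trajectory from position samples
#'
#' A trajectory is a tibble of timestamped 2-D positions in arena-centred
#' Cartesian coordinates (cm), nominally sampled at 50 Hz.  Timestamps must
#' be strictly increasing.  Points outside the arena (beyond
#' `arena_radius + tolerance`) and irregular sampling gaps are flagged, not
#' repaired: tracking artefacts are the caller's problem to inspect.
#'
#' @param data A data frame with numeric columns `time` (s), `x`, `y` (cm).
#' @param arena_radius Arena radius in cm (default 31, i.e. a 62-cm cylinder).
#' @param tolerance Radial slack in cm before a point is flagged out-of-arena.
#' @return A tibble of class `"trajectory"` with columns `time`, `x`, `y` and
#'   logical `out_of_arena`; attributes `arena_radius` and `gap_indices`
#'   (sample indices followed by a gap > 2x the median interval).
#' @examples
#' trj <- trajectory(data.frame(time = c(0, 0.02, 0.04), x = 0, y = 0))
#' attr(trj, "arena_radius")
#' @export
trajectory <- function(data, arena_radius = 31, tolerance = 1) {
  required <- c("time", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing trajectory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pc_format_error")
  }
  data <- tibble::as_tibble(data)[required]
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("Trajectory columns time, x, y must be numeric.",
          class = "pc_format_error")
  }
  if (nrow(data) == 0) {
    abort("Trajectory has no samples.", class = "pc_validation_error")
  }
  if (anyNA(data$time) || any(diff(data$time) <= 0)) {
    abort("Trajectory timestamps must be strictly increasing.",
          class = "pc_validation_error")
  }
  r <- sqrt(data$x^2 + data$y^2)
  data$out_of_arena <- !is.na(r) & r > arena_radius + tolerance
  if (any(data$out_of_arena)) {
    warn(sprintf("%d position sample(s) outside arena radius %.1f cm (flagged).",
                 sum(data$out_of_arena), arena_radius))
  }
  gaps <- integer(0)
  if (nrow(data) > 2) {
    dt <- diff(data$time)
    gaps <- which(dt > 2 * median(dt))
    if (length(gaps) > 0) {
      warn(sprintf("%d sampling gap(s) flagged (interval > 2x median).",
                   length(gaps)))
    }
  }
  structure(data,
            class = c("trajectory", class(tibble::tibble())),
            arena_radius = arena_radius,
            gap_indices = gaps)
}

#' @rdname trajectory
#' @param x Object to test.
#' @export
is_trajectory <- function(x) inherits(x, "trajectory")

traj_duration <- function(traj) {
  diff(range(traj$time))
}

#' Construct a spike train for one cluster
#'
#' Holds the spike times of a single sorted cluster together with the
#' per-spike waveform feature vectors used by the cluster-quality metrics,
#' and the cluster's mean waveform width.
#'
#' @param spike_times Numeric vector of spike times in seconds (sorted on
#'   construction).
#' @param cluster_id Cluster identifier (coerced to character).
#' @param features Optional numeric matrix, one row per spike, of waveform
#'   features (equal dimensionality across spikes).
#' @param mean_waveform_width Mean waveform width in microseconds (> 0), or
#'   `NA` if unknown.
#' @param genotype Opaque group label (e.g. `"WT"`), or `NA`.
#' @param session Optional [session_schedule()].
#' @return A list of class `"spike_train"`.
#' @export
spike_train <- function(spike_times, cluster_id = "c1", features = NULL,
                        mean_waveform_width = NA_real_, genotype = NA_character_,
                        session = NULL) {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) {
    abort("Spike times must be finite.", class = "pc_validation_error")
  }
  ord <- order(spike_times)
  spike_times <- spike_times[ord]
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != length(spike_times)) {
      abort("`features` must have one row per spike.", class = "pc_format_error")
    }
    features <- features[ord, , drop = FALSE]
  }
  if (!is.na(mean_waveform_width) && mean_waveform_width <= 0) {
    abort("`mean_waveform_width` must be positive.", class = "pc_validation_error")
  }
  structure(
    list(cluster_id = as.character(cluster_id), spike_times = spike_times,
         features = features, mean_waveform_width = mean_waveform_width,
         genotype = genotype, session = session),
    class = "spike_train"
  )
}

#' @rdname spike_train
#' @param x Object to test.
#' @export
is_spike_train <- function(x) inherits(x, "spike_train")

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes%s>\n", x$cluster_id,
              length(x$spike_times),
              if (is.null(x$features)) "" else
                sprintf(", %d features", ncol(x$features))))
  invisible(x)
}

#' Construct a single-channel LFP recording
#'
#' @param samples Numeric voltage series (finite).
#' @param fs Sampling rate in Hz (nominal 4800).  Must exceed twice the
#'   highest analysed frequency (102 Hz).
#' @param session Optional [session_schedule()].
#' @return A list of class `"lfp_recording"` with fields `samples`, `fs`,
#'   `session`.
#' @export
lfp_recording <- function(samples, fs = 4800, session = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    abort("LFP samples must be finite.", class = "pc_validation_error")
  }
  if (fs <= 2 * 102) {
    abort("LFP sampling rate must exceed 204 Hz (2x the 102 Hz band edge).",
          class = "pc_validation_error")
  }
  structure(list(samples = samples, fs = fs, session = session),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording: %d samples at %g Hz (%.1f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Bundle one session's trajectory, spike trains and LFP
#'
#' Validates that all components share one session clock: spike times must
#' fall within the trajectory time range (with 1 s slack).  Misalignment is
#' an error, never silently repaired.
#'
#' @param trajectory A [trajectory()].
#' @param spike_trains A list of [spike_train()] objects.
#' @param lfp An optional [lfp_recording()].
#' @param animal_id,genotype Metadata labels.
#' @param session Optional [session_schedule()].
#' @return A list of class `"session_dataset"`.
#' @export
session_dataset <- function(trajectory, spike_trains = list(), lfp = NULL,
                            animal_id = NA_character_, genotype = NA_character_,
                            session = NULL) {
  if (!is_trajectory(trajectory)) {
    abort("`trajectory` must be a trajectory object.", class = "pc_format_error")
  }
  if (is_spike_train(spike_trains)) spike_trains <- list(spike_trains)
  t_rng <- range(trajectory$time)
  for (st in spike_trains) {
    if (!is_spike_train(st)) {
      abort("`spike_trains` must contain spike_train objects.",
            class = "pc_format_error")
    }
    if (length(st$spike_times) > 0 &&
        (min(st$spike_times) < t_rng[1] - 1 ||
         max(st$spike_times) > t_rng[2] + 1)) {
      abort(sprintf("Cluster %s has spikes outside the session clock.",
                    st$cluster_id),
            class = "pc_validation_error")
    }
  }
  if (!is.null(lfp) && !inherits(lfp, "lfp_recording")) {
    abort("`lfp` must be an lfp_recording.", class = "pc_format_error")
  }
  names(spike_trains) <- vapply(spike_trains, `[[`, character(1), "cluster_id")
  structure(
    list(trajectory = trajectory, spike_trains = spike_trains, lfp = lfp,
         animal_id = animal_id, genotype = genotype, session = session),
    class = "session_dataset"
  )
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("<session_dataset %s/%s: %d clusters, %.0f s%s>\n",
              x$animal_id, x$genotype, length(x$spike_trains),
              traj_duration(x$trajectory),
              if (is.null(x$lfp)) ", no LFP" else ""))
  invisible(x)
}
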