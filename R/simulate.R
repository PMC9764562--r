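#' Specification of a synthetic place cell
#'
#' Ground-truth parameters for one simulated cell: a Gaussian spatial
#' tuning curve (centre, width, peak and baseline rate), doublet-burst
#' structure, von Mises phase locking per band, and the waveform summary
#' used by the cluster-quality metrics.
#'
#' @param field_center Length-2 numeric, field centre in cm (inside arena).
#' @param field_sigma Tuning width in cm.
#' @param peak_rate,baseline_rate Firing rates in Hz
#'   (`peak_rate > baseline_rate >= 0`).
#' @param burst_doublet_prob Probability that a spike is followed by an
#'   injected doublet at 4-8 ms ISI.
#' @param phase_kappa Named numeric: von Mises concentration per band.
#' @param preferred_phase Named numeric: preferred phase per band, radians
#'   (trough = 0 convention).
#' @param feature_center Numeric vector: mean waveform-feature vector of
#'   the cluster.
#' @param feature_sd Per-feature standard deviation.
#' @param waveform_width Mean waveform width in microseconds.
#' @param arena_radius Arena radius used for the containment check.
#' @return A list of class `"cell_spec"`.
#' @export
cell_spec <- function(field_center = c(0, 0), field_sigma = 8,
                      peak_rate = 5, baseline_rate = 0.1,
                      burst_doublet_prob = 0.2,
                      phase_kappa = c(theta = 0.4, slow_gamma = 0.2,
                                      medium_gamma = 0.1),
                      preferred_phase = c(theta = pi, slow_gamma = pi,
                                          medium_gamma = pi),
                      feature_center = rnorm(8, sd = 10),
                      feature_sd = 1,
                      waveform_width = 320,
                      arena_radius = 31) {
  if (peak_rate <= baseline_rate || baseline_rate < 0) {
    abort("Need peak_rate > baseline_rate >= 0.", class = "pc_validation_error")
  }
  if (sqrt(sum(field_center^2)) >= arena_radius) {
    abort("field_center must lie inside the arena.", class = "pc_validation_error")
  }
  if (any(phase_kappa < 0)) {
    abort("phase_kappa must be >= 0.", class = "pc_validation_error")
  }
  structure(list(field_center = field_center, field_sigma = field_sigma,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 burst_doublet_prob = burst_doublet_prob,
                 phase_kappa = phase_kappa, preferred_phase = preferred_phase,
                 feature_center = feature_center, feature_sd = feature_sd,
                 waveform_width = waveform_width,
                 arena_radius = arena_radius),
            class = "cell_spec")
}

#' Across-day effect structure
#'
#' Multiplicative changes applied to every cell of a genotype on day 2:
#' the experience-dependent pattern is a rate decrease together with a
#' tuning-width decrease (hence higher spatial information), an optional
#' preferred-theta-phase shift, and an optional displacement of the field
#' centre (partial remapping between days).  Identity values give the
#' no-change pattern.
#'
#' @param rate_multiplier_day2,sigma_multiplier_day2 Positive multipliers
#'   applied to peak/baseline rate and to field sigma on day 2.
#' @param theta_phase_shift_day2 Radians added to the preferred theta
#'   phase on day 2.
#' @param field_shift_day2 Displacement of the field centre on day 2, cm.
#' @param genotype Group tag carried through to the datasets.
#' @return A list of class `"effect_spec"`.
#' @export
effect_spec <- function(rate_multiplier_day2 = 1, sigma_multiplier_day2 = 1,
                        theta_phase_shift_day2 = 0, field_shift_day2 = 0,
                        genotype = "WT") {
  if (rate_multiplier_day2 <= 0 || sigma_multiplier_day2 <= 0) {
    abort("Day-2 multipliers must be positive.", class = "pc_validation_error")
  }
  structure(list(rate_multiplier_day2 = rate_multiplier_day2,
                 sigma_multiplier_day2 = sigma_multiplier_day2,
                 theta_phase_shift_day2 = theta_phase_shift_day2,
                 field_shift_day2 = field_shift_day2,
                 genotype = genotype),
            class = "effect_spec")
}

#' Simulate a foraging trajectory
#'
#' Smooth random foraging in a circular arena: speed follows an
#' Ornstein-Uhlenbeck process around the target mean (clipped at zero) and
#' heading diffuses, with a steering term that turns the animal away from
#' the wall; positions are reflected at the wall if a step would leave the
#' disc.  Defaults emulate a 10-min session tracked at 50 Hz in a 62-cm
#' cylinder with a mean running speed near 10 cm/s.
#'
#' @param duration Session length in s.
#' @param fs Position sampling rate in Hz.
#' @param arena_radius Arena radius in cm.
#' @param speed_params List: `mean` (target mean speed, cm/s), `sd`
#'   (stationary OU sd), `tau` (OU time constant, s), `heading_tau`
#'   (heading decorrelation time, s).
#' @param seed Optional RNG seed (integer).
#' @return A [trajectory()].
#' @examples
#' trj <- simulate_trajectory(60, seed = 42)
#' @export
simulate_trajectory <- function(duration, fs = 50, arena_radius = 31,
                                speed_params = list(mean = 10, sd = 4,
                                                    tau = 2, heading_tau = 3),
                                seed = NULL) {
  if (duration <= 0) abort("duration must be > 0.", class = "pc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  sp <- utils::modifyList(list(mean = 10, sd = 4, tau = 2, heading_tau = 3),
                          speed_params)
  n <- round(duration * fs) + 1L
  dt <- 1 / fs
  x <- numeric(n); y <- numeric(n)
  # random start well inside the disc
  r0 <- sqrt(runif(1)) * 0.7 * arena_radius
  a0 <- runif(1, 0, 2 * pi)
  x[1] <- r0 * cos(a0); y[1] <- r0 * sin(a0)
  v <- max(sp$mean, 0)
  heading <- runif(1, 0, 2 * pi)
  sig_v <- sp$sd * sqrt(2 * dt / max(sp$tau, dt))
  sig_h <- sqrt(2 * dt / max(sp$heading_tau, dt))
  ev <- rnorm(n) * sig_v
  eh <- rnorm(n) * sig_h
  for (k in 2:n) {
    v <- v + (sp$mean - v) * dt / max(sp$tau, dt) + ev[k]
    if (v < 0) v <- 0
    # steer away from the wall as it approaches
    r <- sqrt(x[k - 1]^2 + y[k - 1]^2)
    if (r > 0.93 * arena_radius) {
      inward <- atan2(-y[k - 1], -x[k - 1])
      turn <- circ_diff(inward, heading)
      heading <- heading + turn * dt * 8 * (r / arena_radius - 0.93) / 0.07
    }
    heading <- heading + eh[k]
    xn <- x[k - 1] + v * cos(heading) * dt
    yn <- y[k - 1] + v * sin(heading) * dt
    rn <- sqrt(xn^2 + yn^2)
    if (rn > arena_radius) {        # reflect off the wall
      xn <- xn * (2 * arena_radius - rn) / rn
      yn <- yn * (2 * arena_radius - rn) / rn
      heading <- atan2(yn - y[k - 1], xn - x[k - 1])
    }
    x[k] <- xn; y[k] <- yn
  }
  trajectory(tibble::tibble(time = (seq_len(n) - 1) * dt, x = x, y = y),
             arena_radius = arena_radius)
}

# mass of a Gaussian field inside the arena disc (unit amplitude),
# evaluated on a 1-cm grid; used to renormalise day-2 tuning so the rate
# multiplier scales the session-mean rate exactly even for wall-truncated
# fields
field_disc_mass <- function(center, sigma, arena_radius) {
  g <- seq(-arena_radius, arena_radius, by = 1)
  d2x <- (g - center[1])^2
  d2y <- (g - center[2])^2
  in_disc <- outer(g^2, g^2, `+`) <= arena_radius^2
  sum(exp(-outer(d2x, d2y, `+`) / (2 * sigma^2))[in_disc])
}

# Gaussian tuning rate at given positions
tuning_rate <- function(x, y, spec) {
  d2 <- (x - spec$field_center[1])^2 + (y - spec$field_center[2])^2
  spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) *
    exp(-d2 / (2 * spec$field_sigma^2))
}

#' Simulate an inhomogeneous-Poisson place cell
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose rate is
#' the Gaussian tuning curve evaluated along the trajectory:
#' `rate(t) = baseline + (peak - baseline) * exp(-d(t)^2 / (2 sigma^2))`.
#' The rate is piecewise constant over the position sampling intervals
#' (the finest scale at which position is known), which makes the draw
#' exact: per-interval counts are Poisson, spike times uniform within the
#' interval.  Burst structure is then injected by following each original
#' spike, with probability `burst_doublet_prob`, by a doublet spike at a
#' 4-8 ms interval.  Per-spike waveform features are drawn from the
#' cluster's Gaussian feature distribution.
#'
#' @param traj A [trajectory()].
#' @param spec A [cell_spec()].
#' @param seed Optional RNG seed.
#' @param cluster_id,genotype Labels for the returned train.
#' @return A [spike_train()] with features and waveform width attached.
#' @export
simulate_place_cell <- function(traj, spec, seed = NULL, cluster_id = "sim",
                                genotype = NA_character_) {
  if (!is_trajectory(traj) || nrow(traj) < 2) {
    abort("Need a trajectory with >= 2 samples.", class = "pc_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rate <- tuning_rate(traj$x, traj$y, spec)
  dt <- diff(traj$time)
  lam <- rate[-length(rate)] * dt
  counts <- rpois(length(lam), lam)
  idx <- rep.int(seq_along(counts), counts)
  st <- traj$time[idx] + runif(length(idx)) * dt[idx]
  if (spec$burst_doublet_prob > 0 && length(st) > 0) {
    dbl <- runif(length(st)) < spec$burst_doublet_prob
    extra <- st[dbl] + runif(sum(dbl), 0.004, 0.008)
    st <- c(st, extra[extra <= traj$time[nrow(traj)]])
  }
  st <- sort(st)
  d <- length(spec$feature_center)
  feats <- matrix(rnorm(length(st) * d, sd = spec$feature_sd),
                  ncol = d, byrow = TRUE)
  feats <- sweep(feats, 2, spec$feature_center, `+`)
  spike_train(st, cluster_id = cluster_id, features = feats,
              mean_waveform_width = spec$waveform_width, genotype = genotype)
}

# 1/f-ish background: white Gaussian noise shaped by 1/sqrt(f) in the
# frequency domain (flat below 1 Hz to avoid the DC blow-up).
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a CA1-like LFP
#'
#' Sum of three band-limited oscillations — theta, slow gamma and medium
#' gamma carriers (8, 38, 75 Hz) with slow frequency jitter — plus
#' 1/f-like background noise.  Oscillation amplitudes can be coupled to
#' running speed via a trajectory.  Carriers deliberately avoid the
#' 48-52 Hz mains region.
#'
#' @param duration Length in s.
#' @param fs Sampling rate in Hz (default 4800).
#' @param theta_amp,sgamma_amp,mgamma_amp Carrier amplitudes.
#' @param noise_sd Standard deviation of the 1/f background.
#' @param speed_coupling Fractional amplitude modulation per unit of
#'   normalised speed (0 = uncoupled).
#' @param traj Optional [trajectory()] supplying the speed signal.
#' @param freq_jitter_sd Slow (0.1 Hz low-passed) frequency jitter, Hz.
#' @param seed Optional RNG seed.
#' @return An [lfp_recording()].
#' @export
simulate_lfp <- function(duration, fs = 4800, theta_amp = 1,
                         sgamma_amp = 0.4, mgamma_amp = 0.25,
                         noise_sd = 0.5, speed_coupling = 0, traj = NULL,
                         freq_jitter_sd = 0.3, seed = NULL) {
  if (fs <= 2 * 102) {
    abort("fs too low for the analysed bands.", class = "pc_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  slow_jitter <- function(sd_hz) {
    if (sd_hz <= 0) return(numeric(n) + 0)
    m <- max(4L, round(duration * 0.5))   # ~0.5 Hz control points
    stats::approx(seq(0, duration, length.out = m), rnorm(m, sd = sd_hz),
                  xout = t)$y
  }
  carrier <- function(f0, amp, jit_sd) {
    if (amp == 0) return(numeric(n))
    ph <- 2 * pi * cumsum(f0 + slow_jitter(jit_sd)) / fs
    amp * cos(ph)
  }
  gain <- rep(1, n)
  if (speed_coupling != 0) {
    if (is.null(traj)) {
      abort("speed_coupling needs a trajectory.", class = "pc_format_error")
    }
    sp <- compute_speed(traj)
    v <- stats::approx(sp$epoch_start, sp$speed, xout = t, rule = 2)$y
    v[is.na(v)] <- 0
    gain <- 1 + speed_coupling * (v / max(mean(v, na.rm = TRUE), 1e-9) - 1)
    gain[gain < 0] <- 0
  }
  x <- gain * (carrier(8, theta_amp, freq_jitter_sd) +
                 carrier(38, sgamma_amp, 2 * freq_jitter_sd) +
                 carrier(75, mgamma_amp, 3 * freq_jitter_sd))
  if (noise_sd > 0) x <- x + noise_sd * pink_noise(n, fs)
  lfp_recording(x, fs = fs)
}

#' Simulate spikes phase-locked to an LFP band
#'
#' Band-filters the LFP, extracts its instantaneous phase (trough = 0
#' convention, shared with the analysis side), and places spikes by
#' rejection sampling so that the phase at spike times follows a von Mises
#' distribution with mean `mu` and concentration `kappa` (kappa 0 gives
#' phases that are uniform over the oscillation).
#'
#' @param lfp An [lfp_recording()].
#' @param pass_lo,pass_hi Filter pass band in Hz.
#' @param kappa Von Mises concentration (>= 0).
#' @param mu Preferred phase in radians (trough = 0).
#' @param n_spikes Number of spikes to place.
#' @param seed Optional RNG seed.
#' @return A [spike_train()].
#' @export
simulate_phase_locked_spikes <- function(lfp, pass_lo, pass_hi, kappa, mu,
                                         n_spikes, seed = NULL) {
  if (kappa < 0) abort("kappa must be >= 0.", class = "pc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  filtered <- bandpass(lfp, pass_lo, pass_hi)
  ph <- instantaneous_phase_amplitude(filtered)
  n <- nrow(ph)
  taken <- integer(0)
  while (length(taken) < n_spikes) {
    m <- max(1000L, 4L * (n_spikes - length(taken)))
    cand <- sample.int(n, m, replace = TRUE)
    acc <- runif(m) < exp(kappa * (cos(ph$phase[cand] - mu) - 1))
    taken <- c(taken, cand[acc])
  }
  taken <- taken[seq_len(n_spikes)]
  st <- sort(ph$time[taken] + runif(n_spikes, 0, 1 / lfp$fs))
  spike_train(st, cluster_id = "phase_locked")
}

#' Simulate a full six-session experiment
#'
#' Generates, for each genotype-like group, `cells_per_genotype` cells
#' recorded across three sessions per day on two consecutive days (six
#' sessions).  Cells within a group are split across `n_animals` animals;
#' all cells of one animal share that animal's trajectory (and optional
#' LFP) per session, as in a real recording.  On day 2 the group's
#' [effect_spec()] is applied: rates and tuning widths are multiplied,
#' the preferred theta phase is shifted, and field centres are displaced
#' by `field_shift_day2` in a random direction (partial remapping).
#' Per-cell heterogeneity: peak rates are log-normal across cells, and
#' each cell-session draws an independent Poisson realisation.
#'
#' @param cells_per_genotype Number of cells per group.
#' @param effects A list of [effect_spec()] objects (one group each).
#' @param n_animals Animals per group; cells are divided evenly.
#' @param duration Session duration in s (default 600, a 10-min session).
#' @param fs Position sampling rate (Hz).
#' @param include_lfp Generate an LFP per animal-session.
#' @param lfp_fs LFP sampling rate (Hz).
#' @param mean_peak_rate Median peak rate across cells (Hz).
#' @param seed RNG seed for the whole experiment.
#' @return A list of class `"experiment"`: `datasets` (tibble with
#'   `animal`, `genotype`, `day`, `session_in_day`, `session_index` and a
#'   `dataset` list-column of [session_dataset()]s) and `cells` (ground
#'   truth tibble, one row per cell).
#' @export
simulate_experiment <- function(cells_per_genotype, effects,
                                n_animals = 2, duration = 600, fs = 50,
                                include_lfp = FALSE, lfp_fs = 4800,
                                mean_peak_rate = 4, seed = 1) {
  set.seed(seed)
  arena_radius <- 31
  groups <- purrr::map(effects, function(e) {
    stopifnot(inherits(e, "effect_spec"))
    e
  })
  cell_rows <- list(); ds_rows <- list()
  for (g in seq_along(groups)) {
    eff <- groups[[g]]
    per_animal <- rep(cells_per_genotype %/% n_animals, n_animals)
    if (cells_per_genotype %% n_animals > 0) {
      per_animal[seq_len(cells_per_genotype %% n_animals)] <-
        per_animal[seq_len(cells_per_genotype %% n_animals)] + 1
    }
    cell_counter <- 0
    for (a in seq_len(n_animals)) {
      animal_id <- sprintf("%s_rat%d", eff$genotype, a)
      # per-cell ground truth for this animal
      specs <- purrr::map(seq_len(per_animal[a]), function(j) {
        r_c <- sqrt(runif(1)) * (arena_radius - 6)
        a_c <- runif(1, 0, 2 * pi)
        cell_spec(
          field_center = c(r_c * cos(a_c), r_c * sin(a_c)),
          field_sigma = runif(1, 5, 11),
          peak_rate = stats::rlnorm(1, log(mean_peak_rate), 0.35),
          baseline_rate = runif(1, 0.02, 0.12),
          burst_doublet_prob = runif(1, 0.1, 0.3),
          phase_kappa = c(theta = stats::rgamma(1, 2, 8),
                          slow_gamma = stats::rgamma(1, 2, 12),
                          medium_gamma = stats::rgamma(1, 2, 16)),
          preferred_phase = c(theta = rvonmises(1, pi, 1),
                              slow_gamma = rvonmises(1, pi, 0.5),
                              medium_gamma = rvonmises(1, pi, 0.5)),
          arena_radius = arena_radius
        )
      })
      shift_dir <- runif(per_animal[a], 0, 2 * pi)
      for (day in 1:2) {
        for (sid in 1:3) {
          sched <- session_schedule(day, sid)
          traj <- simulate_trajectory(duration, fs = fs,
                                      arena_radius = arena_radius)
          lfp <- if (include_lfp) {
            simulate_lfp(duration, fs = lfp_fs, speed_coupling = 0.3,
                         traj = traj)
          } else NULL
          trains <- purrr::map(seq_along(specs), function(j) {
            sp <- specs[[j]]
            if (day == 2) {
              # the rate multiplier scales the cell's session-mean rate:
              # a narrower field (sigma multiplier < 1) occupies less of
              # the arena, so the tuning amplitude is renormalised by the
              # ratio of in-disc field masses to keep the scaling exact
              amp <- sp$peak_rate - sp$baseline_rate
              sigma2 <- sp$field_sigma * eff$sigma_multiplier_day2
              mass_ratio <- field_disc_mass(sp$field_center, sp$field_sigma,
                                            arena_radius) /
                field_disc_mass(sp$field_center, sigma2, arena_radius)
              sp$baseline_rate <- sp$baseline_rate * eff$rate_multiplier_day2
              sp$peak_rate <- sp$baseline_rate +
                amp * eff$rate_multiplier_day2 * mass_ratio
              sp$field_sigma <- sigma2
              sp$preferred_phase["theta"] <-
                (sp$preferred_phase["theta"] + eff$theta_phase_shift_day2) %%
                (2 * pi)
              if (eff$field_shift_day2 != 0) {
                ctr <- sp$field_center + eff$field_shift_day2 *
                  c(cos(shift_dir[j]), sin(shift_dir[j]))
                r <- sqrt(sum(ctr^2))
                if (r >= arena_radius - 2) {
                  ctr <- ctr * (arena_radius - 2) / r
                }
                sp$field_center <- ctr
              }
            }
            simulate_place_cell(traj, sp,
                                cluster_id = sprintf("%s_c%03d", animal_id,
                                                     cell_counter + j),
                                genotype = eff$genotype)
          })
          ds <- session_dataset(traj, trains, lfp = lfp,
                                animal_id = animal_id,
                                genotype = eff$genotype, session = sched)
          ds_rows[[length(ds_rows) + 1]] <- tibble::tibble(
            animal = animal_id, genotype = eff$genotype, day = day,
            session_in_day = sid, session_index = sched$session_index,
            dataset = list(ds))
        }
      }
      cell_rows[[length(cell_rows) + 1]] <- tibble::tibble(
        cell = sprintf("%s_c%03d", animal_id,
                       cell_counter + seq_len(per_animal[a])),
        animal = animal_id, genotype = eff$genotype,
        field_x = vapply(specs, function(s) s$field_center[1], 0),
        field_y = vapply(specs, function(s) s$field_center[2], 0),
        field_sigma = vapply(specs, function(s) s$field_sigma, 0),
        peak_rate = vapply(specs, function(s) s$peak_rate, 0),
        baseline_rate = vapply(specs, function(s) s$baseline_rate, 0),
        burst_doublet_prob = vapply(specs,
                                    function(s) s$burst_doublet_prob, 0))
      cell_counter <- cell_counter + per_animal[a]
    }
  }
  structure(list(datasets = dplyr::bind_rows(ds_rows),
                 cells = dplyr::bind_rows(cell_rows),
                 effects = groups, seed = seed),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment: %d session datasets, %d cells, %d group(s)>\n",
              nrow(x$datasets), nrow(x$cells), length(x$effects)))
  invisible(x)
}
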