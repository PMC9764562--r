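#' Frequency band definitions
#'
#' Analysis bands used for power estimation — theta 6-12 Hz, slow gamma
#' 30-45 Hz, medium gamma 55-100 Hz — and the wider pass bands used for
#' phase extraction (theta 4-14, slow gamma 28-47, medium gamma 58-102),
#' whose stop-band edges sit 2 Hz outside the pass band.
#'
#' @return A tibble: `band`, `analysis_lo`, `analysis_hi`, `filter_lo`,
#'   `filter_hi`.
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("theta", "slow_gamma", "medium_gamma"),
    analysis_lo = c(6, 30, 55),
    analysis_hi = c(12, 45, 100),
    filter_lo = c(4, 28, 58),
    filter_hi = c(14, 47, 102)
  )
}

#' Z-score an LFP recording
#'
#' Subtracts the mean and divides by the standard deviation of the voltage
#' series.  A (near-)constant signal is degenerate and raises an error.
#'
#' @param lfp An [lfp_recording()].
#' @return An [lfp_recording()] with mean-0, sd-1 samples.
#' @export
zscore_lfp <- function(lfp) {
  s <- sd(lfp$samples)
  if (!is.finite(s) || s < .Machine$double.eps * 100) {
    abort("LFP signal is (near-)constant: cannot z-score.",
          class = "pc_degenerate_error")
  }
  lfp_recording((lfp$samples - mean(lfp$samples)) / s, fs = lfp$fs,
                session = lfp$session)
}

# One-sided Welch PSD with Hamming windows and 50% overlap.
# Returns freq grid (Hz) and PSD (power / Hz); integral over f recovers
# the signal variance (up to window bias).
welch_psd <- function(x, fs, nperseg = NULL, nfft_factor = 4) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- max(16L, min(n, floor(n / 2)))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  u <- sum(w^2)
  nfft <- max(nperseg, nfft_factor * nperseg)
  half <- floor(nfft / 2) + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)] * w
    X <- fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(X[seq_len(half)])^2
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nfft even)
  scale <- rep(2, half); scale[1] <- 1
  if (nfft %% 2 == 0) scale[half] <- 1
  list(freq = (seq_len(half) - 1) * fs / nfft, psd = psd * scale)
}

band_power_from_psd <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq <= hi
  sum(psd$psd[sel]) * df
}

#' Session-level band power over post-immobility activity epochs
#'
#' The z-scored LFP is restricted to the supplied activity epochs (see
#' [post_immobility_activity_epochs()]), the epochs are concatenated, and
#' a spectrogram is computed over the concatenation with a long window
#' (default 20 s) stepped by 10 s; Welch PSDs within each window are
#' averaged and the mean power inside each analysis band is returned.
#'
#' @param lfp An [lfp_recording()] (z-scored internally).
#' @param epochs A tibble with `start`, `end` columns (s) on the LFP clock.
#' @param window,step Spectrogram window and step in s.
#' @param welch_window Welch sub-window in s within each spectrogram
#'   window.
#' @param bands A band table as from [band_definitions()].
#' @return A tibble: `band`, `power`, `n_windows`.
#' @export
session_band_power <- function(lfp, epochs, window = 20, step = 10,
                               welch_window = 2, bands = band_definitions()) {
  z <- zscore_lfp(lfp)
  fs <- z$fs
  pieces <- purrr::map(seq_len(nrow(epochs)), function(k) {
    i0 <- max(1L, floor(epochs$start[k] * fs) + 1L)
    i1 <- min(length(z$samples), floor(epochs$end[k] * fs))
    if (i1 <= i0) return(numeric(0))
    z$samples[i0:i1]
  })
  x <- unlist(pieces)
  win_n <- round(window * fs)
  if (length(x) < win_n) {
    abort(sprintf("Only %.1f s of activity-epoch LFP; %g s needed.",
                  length(x) / fs, window),
          class = "pc_insufficient_data_error")
  }
  starts <- seq(1L, length(x) - win_n + 1L, by = round(step * fs))
  per_band <- matrix(0, length(starts), nrow(bands))
  for (k in seq_along(starts)) {
    psd <- welch_psd(x[starts[k]:(starts[k] + win_n - 1L)], fs,
                     nperseg = round(welch_window * fs))
    per_band[k, ] <- vapply(seq_len(nrow(bands)), function(b) {
      band_power_from_psd(psd, bands$analysis_lo[b], bands$analysis_hi[b])
    }, 0)
  }
  tibble::tibble(band = bands$band, power = colMeans(per_band),
                 n_windows = length(starts))
}

#' Per-epoch band power
#'
#' Splits the z-scored LFP into consecutive epochs (default 500 ms) and
#' integrates a Welch PSD (50% overlapping Hamming windows) over each
#' analysis band within each epoch.
#'
#' @param lfp An [lfp_recording()].
#' @param epoch_duration Epoch length in s.
#' @param bands A band table as from [band_definitions()].
#' @return A tibble: `epoch` (1-based index), `epoch_start` (s), one
#'   power column per band (`theta`, `slow_gamma`, `medium_gamma`), and
#'   `total_power`.
#' @export
binned_band_power <- function(lfp, epoch_duration = 0.5,
                              bands = band_definitions()) {
  z <- zscore_lfp(lfp)
  fs <- z$fs
  ep_n <- round(epoch_duration * fs)
  n_ep <- floor(length(z$samples) / ep_n)
  if (n_ep < 1) {
    abort("LFP shorter than one epoch.", class = "pc_insufficient_data_error")
  }
  rows <- purrr::map_dfr(seq_len(n_ep), function(k) {
    seg <- z$samples[((k - 1L) * ep_n + 1L):(k * ep_n)]
    psd <- welch_psd(seg, fs, nperseg = max(16L, floor(ep_n / 2)))
    bp <- vapply(seq_len(nrow(bands)), function(b) {
      band_power_from_psd(psd, bands$analysis_lo[b], bands$analysis_hi[b])
    }, 0)
    out <- tibble::tibble(epoch = k, epoch_start = (k - 1) * epoch_duration)
    out[bands$band] <- as.list(bp)
    out$total_power <- band_power_from_psd(psd, 0, fs / 2)
    out
  })
  rows
}

#' Velocity-stratified band power
#'
#' Joins per-epoch band powers with the per-epoch speed series on the
#' common epoch grid and averages power within speed bins of fixed width
#' (default 3 cm/s).  Bins with fewer than `min_epochs` epochs are flagged.
#'
#' @param powers Output of [binned_band_power()].
#' @param speed A `speed_series` on the same epoch grid.
#' @param speed_bin Speed bin width in cm/s.
#' @param min_epochs Minimum epochs per speed bin.
#' @return A tibble: `speed_lo`, `speed_hi`, `n_epochs`, `sufficient`, one
#'   mean-power column per band.
#' @export
velocity_stratified_power <- function(powers, speed, speed_bin = 3,
                                      min_epochs = 5) {
  n <- min(nrow(powers), nrow(speed))
  band_cols <- intersect(band_definitions()$band, names(powers))
  df <- dplyr::bind_cols(powers[seq_len(n), band_cols],
                         tibble::tibble(speed = speed$speed[seq_len(n)]))
  df <- dplyr::filter(df, !is.na(.data$speed))
  df$bin <- floor(df$speed / speed_bin)
  out <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_epochs = dplyr::n(),
                     dplyr::across(dplyr::all_of(band_cols), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin)
  tibble::tibble(speed_lo = out$bin * speed_bin,
                 speed_hi = (out$bin + 1) * speed_bin,
                 n_epochs = out$n_epochs,
                 sufficient = out$n_epochs >= min_epochs) |>
    dplyr::bind_cols(out[band_cols])
}

# Zero-phase FIR band-pass: a linear-phase Hamming-window FIR is designed
# with 2-Hz transition bands; filtering is done by multiplying the signal
# spectrum with the kernel's (real, zero-phase) frequency response.
# Circular wraparound affects only the kernel-length edges.
design_fir_bandpass <- function(fs, pass_lo, pass_hi, transition = 2) {
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 1) n_taps <- n_taps + 1  # even order, odd length
  # -6 dB points midway through the transition bands
  w <- c(pass_lo - transition / 2, pass_hi + transition / 2) / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    abort("Band edges incompatible with the sampling rate.",
          class = "pc_validation_error")
  }
  signal::fir1(n_taps, w, type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Filters the LFP with a linear-phase FIR band-pass whose stop-band edges
#' sit 2 Hz outside the pass band (Hamming design: stop-band attenuation
#' about 53 dB, pass-band ripple well under 1 dB), applied with zero net
#' phase so that oscillation phase is preserved.
#'
#' @param lfp An [lfp_recording()].
#' @param pass_lo,pass_hi Pass band edges in Hz (e.g. 4 and 14 for theta).
#' @param transition Transition width to the stop bands in Hz.
#' @return An [lfp_recording()] with the filtered series.
#' @export
bandpass <- function(lfp, pass_lo, pass_hi, transition = 2) {
  b <- design_fir_bandpass(lfp$fs, pass_lo, pass_hi, transition)
  n <- length(lfp$samples)
  nb <- length(b)
  if (nb >= n) {
    abort("Signal shorter than the filter kernel.", class = "pc_validation_error")
  }
  half <- (nb - 1) / 2
  # centre the symmetric kernel at index 1 (circularly) => real response
  v <- numeric(n)
  v[1:(half + 1)] <- b[(half + 1):nb]
  v[(n - half + 1):n] <- b[1:half]
  y <- Re(fft(fft(lfp$samples) * fft(v), inverse = TRUE)) / n
  lfp_recording(y, fs = lfp$fs, session = lfp$session)
}

#' Instantaneous phase and amplitude
#'
#' Analytic signal of a (band-filtered) series via the Hilbert transform,
#' computed in the frequency domain.  Phase follows the trough = 0
#' convention: the analytic-signal argument (0 at signal maxima) is
#' shifted by pi, so minima of the oscillation map to phase 0/2*pi and
#' maxima to pi.  Amplitude is the analytic-signal modulus.
#'
#' @param lfp An [lfp_recording()] holding a band-filtered series.
#' @return A tibble: `time` (s), `phase` (radians in `[0, 2*pi)`),
#'   `amplitude`.
#' @export
instantaneous_phase_amplitude <- function(lfp) {
  x <- lfp$samples
  n <- length(x)
  X <- fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1; hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1; hmul[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * hmul, inverse = TRUE) / n
  tibble::tibble(
    time = (seq_len(n) - 1) / lfp$fs,
    phase = (Arg(z) + pi) %% (2 * pi),
    amplitude = Mod(z)
  )
}

#' Strong-oscillation epochs
#'
#' Flags 500-ms epochs whose band power exceeds the session mean by more
#' than two standard deviations of the per-epoch power distribution.
#' Spike-phase analysis is restricted to these epochs.
#'
#' @param epoch_power Numeric vector of per-epoch band power.
#' @param n_sd Threshold in standard deviations (default 2).
#' @return Logical vector over epochs.
#' @export
strong_oscillation_mask <- function(epoch_power, n_sd = 2) {
  s <- sd(epoch_power)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(epoch_power)))
  epoch_power > mean(epoch_power) + n_sd * s
}

#' Spike-LFP phase locking
#'
#' Assigns each spike the instantaneous band phase at its time, restricts
#' to spikes inside strong-oscillation epochs (if a mask is given), and
#' summarises the phase sample by the mean resultant vector
#' `r = sum(exp(i*theta_j))/N`: its length (MVL, 0 = uniform, 1 = perfect
#' locking), its argument (preferred phase, trough = 0 convention), and a
#' Rayleigh test of non-uniformity.  Results from fewer than `min_spikes`
#' contributing spikes are flagged insufficient.
#'
#' @param train A [spike_train()] or numeric spike times (s).
#' @param phase A tibble from [instantaneous_phase_amplitude()] (`time`,
#'   `phase`).
#' @param strong_mask Optional logical per-epoch mask from
#'   [strong_oscillation_mask()].
#' @param epoch_duration Epoch length the mask refers to (s).
#' @param min_spikes Minimum contributing spikes for a reliable estimate.
#' @return A one-row tibble: `mvl`, `preferred_phase`, `n_spikes`,
#'   `rayleigh_p`, `sufficient`.
#' @export
phase_locking <- function(train, phase, strong_mask = NULL,
                          epoch_duration = 0.5, min_spikes = 30) {
  st <- if (is_spike_train(train)) train$spike_times else as.numeric(train)
  t0 <- phase$time[1]
  fs <- 1 / (phase$time[2] - phase$time[1])
  idx <- round((st - t0) * fs) + 1L
  ok <- idx >= 1L & idx <= nrow(phase)
  if (!is.null(strong_mask)) {
    ep <- floor((st - t0) / epoch_duration) + 1L
    ok <- ok & ep >= 1L & ep <= length(strong_mask) & strong_mask[pmax(ep, 1L)]
  }
  theta <- phase$phase[idx[ok]]
  n <- length(theta)
  if (n == 0) {
    return(tibble::tibble(mvl = NA_real_, preferred_phase = NA_real_,
                          n_spikes = 0L, rayleigh_p = NA_real_,
                          sufficient = FALSE))
  }
  mvl <- circ_r(theta)
  pref <- circ_mean(theta)
  p <- if (n >= 3) rayleigh_test(theta)$p_value else NA_real_
  tibble::tibble(mvl = mvl, preferred_phase = pref, n_spikes = n,
                 rayleigh_p = p, sufficient = n >= min_spikes)
}

#' Fraction of significantly phase-locked cells
#'
#' Among cells with a sufficient spike sample, the proportion whose
#' Rayleigh p-value falls below `alpha`.
#'
#' @param results A tibble of [phase_locking()] rows (one per cell).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `n_cells`, `n_locked`, `fraction`.
#' @export
phase_locked_fraction <- function(results, alpha = 0.05) {
  eligible <- dplyr::filter(results, .data$sufficient, !is.na(.data$rayleigh_p))
  if (nrow(eligible) == 0) {
    abort("No cells with sufficient spikes.", class = "pc_validation_error")
  }
  n_locked <- sum(eligible$rayleigh_p < alpha)
  tibble::tibble(n_cells = nrow(eligible), n_locked = n_locked,
                 fraction = n_locked / nrow(eligible))
}
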