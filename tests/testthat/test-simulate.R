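test_that("simulated trajectories respect geometry and sampling", {
  trj <- simulate_trajectory(600, fs = 50, seed = 1)
  expect_equal(nrow(trj), 30001)
  expect_true(all(sqrt(trj$x^2 + trj$y^2) <= 31 + 1e-9))

  frozen <- simulate_trajectory(10, speed_params = list(mean = 0, sd = 0),
                                seed = 2)
  expect_equal(path_length(frozen), 0)

  # target mean speed recovered within 10 % over 600 s
  sp <- compute_speed(trj)
  expect_equal(mean(sp$speed, na.rm = TRUE), 10, tolerance = 0.1)

  expect_error(simulate_trajectory(-5), class = "pc_validation_error")
})

test_that("generator is deterministic under a fixed seed", {
  a <- simulate_trajectory(20, seed = 7)
  b <- simulate_trajectory(20, seed = 7)
  expect_identical(a$x, b$x)
  sa <- simulate_place_cell(a, cell_spec(), seed = 8)
  sb <- simulate_place_cell(b, cell_spec(), seed = 8)
  expect_identical(sa$spike_times, sb$spike_times)
  la <- simulate_lfp(5, fs = 1200, seed = 9)
  lb <- simulate_lfp(5, fs = 1200, seed = 9)
  expect_identical(la$samples, lb$samples)
})

test_that("homogeneous Poisson spike counts land in the Poisson band", {
  trj <- simulate_trajectory(1000, seed = 10)
  # peak == baseline is rejected by the spec constructor, so approximate a
  # flat 1-Hz cell with a very wide field
  spec <- cell_spec(field_sigma = 1e6, peak_rate = 1 + 1e-9,
                    baseline_rate = 1, burst_doublet_prob = 0)
  st <- simulate_place_cell(trj, spec, seed = 11)
  # 99 % Poisson band around 1000
  expect_gt(length(st$spike_times), qpois(0.005, 1000))
  expect_lt(length(st$spike_times), qpois(0.995, 1000))
})

test_that("rate-map peak recovers the injected field centre within one bin", {
  # average the recovered peak over independent realisations: the single-
  # realisation peak bin carries sampling noise of about one bin itself
  trj <- simulate_trajectory(600, seed = 12)
  spec <- cell_spec(field_center = c(10, -5), field_sigma = 8,
                    peak_rate = 10, baseline_rate = 0.05)
  peaks <- t(vapply(1:5, function(k) {
    st <- simulate_place_cell(trj, spec, seed = 12 + k)
    m <- rate_map(trj, st)
    pk <- which(m$rate == max(m$rate, na.rm = TRUE), arr.ind = TRUE)
    c(m$centers[pk[1, 1]], m$centers[pk[1, 2]])
  }, numeric(2)))
  expect_lte(abs(mean(peaks[, 1]) - 10), 2.5)
  expect_lte(abs(mean(peaks[, 2]) - (-5)), 2.5)
})

test_that("doublet injection controls burstiness", {
  trj <- simulate_trajectory(600, seed = 14)
  no_burst <- simulate_place_cell(
    trj, cell_spec(peak_rate = 3, burst_doublet_prob = 0), seed = 15)
  expect_lt(burst_probability(no_burst)$burst_probability, 0.02)
  bursty <- simulate_place_cell(
    trj, cell_spec(peak_rate = 3, burst_doublet_prob = 0.4), seed = 16)
  expect_gt(burst_probability(bursty)$burst_probability,
            burst_probability(no_burst)$burst_probability + 0.1)
})

test_that("a pure theta tone concentrates its Welch power in-band", {
  lfp <- simulate_lfp(30, fs = 1200, theta_amp = 1, sgamma_amp = 0,
                      mgamma_amp = 0, noise_sd = 0, freq_jitter_sd = 0,
                      seed = 17)
  psd_powers <- binned_band_power(lfp, epoch_duration = 30)  # one epoch
  frac <- psd_powers$theta / psd_powers$total_power
  expect_gte(frac, 0.95)
})

test_that("white-noise band powers scale with bandwidth", {
  lfp <- simulate_lfp(60, fs = 1200, theta_amp = 0, sgamma_amp = 0,
                      mgamma_amp = 0, noise_sd = 0, seed = 18)
  # replace the shaped noise with true white noise for the closed form
  set.seed(19)
  white <- lfp_recording(rnorm(180 * 1200), fs = 1200)
  bp <- binned_band_power(white, epoch_duration = 180)
  # bandwidth ratios 6 : 15 : 45
  expect_equal(bp$slow_gamma / bp$theta, 15 / 6, tolerance = 0.1)
  expect_equal(bp$medium_gamma / bp$theta, 45 / 6, tolerance = 0.1)
})

test_that("degenerate flat LFP fails z-scoring downstream", {
  flat <- lfp_recording(rep(0, 2400), fs = 1200)
  expect_error(zscore_lfp(flat), class = "pc_degenerate_error")
  expect_error(binned_band_power(flat), class = "pc_degenerate_error")
})

test_that("phase-locked spike generator honours kappa and mu", {
  lfp <- simulate_lfp(60, fs = 1200, noise_sd = 0.2, seed = 20)
  filt <- bandpass(lfp, 4, 14)
  ph <- instantaneous_phase_amplitude(filt)

  # kappa 0 -> phases uniform, MVL within sampling noise of 0
  u <- simulate_phase_locked_spikes(lfp, 4, 14, kappa = 0, mu = 0,
                                    n_spikes = 1000, seed = 21)
  expect_lt(phase_locking(u, ph)$mvl, 2 / sqrt(1000))

  # large kappa -> near-perfect locking
  tight <- simulate_phase_locked_spikes(lfp, 4, 14, kappa = 50, mu = 2,
                                        n_spikes = 1000, seed = 22)
  expect_gt(phase_locking(tight, ph)$mvl, 0.95)

  # preferred-phase recovery at kappa 4
  mid <- simulate_phase_locked_spikes(lfp, 4, 14, kappa = 4, mu = 2,
                                      n_spikes = 2000, seed = 23)
  pl <- phase_locking(mid, ph)
  expect_lt(abs(Arg(exp(1i * (pl$preferred_phase - 2)))), 0.1)

  expect_error(simulate_phase_locked_spikes(lfp, 4, 14, kappa = -1, mu = 0,
                                            n_spikes = 10),
               class = "pc_validation_error")
})

test_that("experiment generator injects recoverable day-2 effects", {
  # null effects: day means differ only by sampling error
  exp_null <- simulate_experiment(
    cells_per_genotype = 12,
    effects = list(effect_spec(genotype = "KO")),
    n_animals = 1, duration = 120, seed = 31)
  expect_equal(nrow(exp_null$datasets), 6)
  expect_equal(nrow(exp_null$cells), 12)
  res <- run_experiment(exp_null, analysis_config(compute_lfp = FALSE,
                                                  keep_maps = FALSE))
  act <- dplyr::filter(res$cells, active)
  tt <- t.test(rate ~ day, data = act)
  expect_gt(tt$p.value, 0.001)

  # every dataset passes the core validation by construction
  expect_true(all(vapply(exp_null$datasets$dataset,
                         inherits, TRUE, "session_dataset")))
})
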