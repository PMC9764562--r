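test_that("occupancy applies the 100-ms visit criterion", {
  om1 <- occupancy_map(still_traj(0.2, fs = 50))
  expect_equal(sum(om1$valid), 1)
  expect_equal(max(om1$occupancy), 0.2, tolerance = 0.05)

  om2 <- occupancy_map(still_traj(0.09, fs = 100))
  expect_equal(sum(om2$valid), 0)

  trj <- simulate_trajectory(60, seed = 3)
  om3 <- occupancy_map(trj)
  expect_lte(sum(om3$occupancy), 60 + 1e-6)
})

test_that("rate map reduces to n/T for a stationary animal", {
  trj <- still_traj(20, fs = 50, x = 3, y = -4)
  st <- spike_train(seq(0.5, 19.5, length.out = 40))  # 40 spikes in 20 s
  rm1 <- rate_map(trj, st)
  # kernel ratios cancel: rate at the occupied bin = n / T
  expect_equal(rm1$rate[which(rm1$valid)], 40 / 20, tolerance = 1e-6)
})

test_that("increasing the kernel width never raises the map maximum", {
  set.seed(4)
  for (k in 1:5) {
    trj <- simulate_trajectory(120, seed = 100 + k)
    spec <- cell_spec(field_center = c(runif(1, -10, 10), runif(1, -10, 10)),
                      peak_rate = 6)
    st <- simulate_place_cell(trj, spec, seed = 200 + k)
    m_narrow <- rate_map(trj, st, h = 2.5)
    m_wide <- rate_map(trj, st, h = 5)
    expect_lte(max(m_wide$rate, na.rm = TRUE),
               max(m_narrow$rate, na.rm = TRUE) + 1e-9)
  }
})

test_that("kernel occupancy integral matches fine-grid quadrature", {
  trj <- simulate_trajectory(60, seed = 15)
  st <- simulate_place_cell(trj, cell_spec(peak_rate = 5), seed = 16)
  rm1 <- rate_map(trj, st)
  # quadrature oracle: evaluate the denominator by direct summation at
  # 10x temporal refinement of the (piecewise-linearly interpolated) path
  t_fine <- seq(min(trj$time), max(trj$time), by = 0.002)
  xf <- approx(trj$time, trj$x, t_fine)$y
  yf <- approx(trj$time, trj$y, t_fine)$y
  centers <- rm1$centers
  # compare on adequately sampled bins: the 20-ms Riemann sum's relative
  # error is only meaningful where the kernel mass is not dominated by a
  # handful of passes
  pick <- which(rm1$valid & rm1$kernel_occupancy >= 1, arr.ind = TRUE)
  pick <- pick[seq(1, nrow(pick), length.out = 12), , drop = FALSE]
  for (b in seq_len(nrow(pick))) {
    cx <- centers[pick[b, 1]]; cy <- centers[pick[b, 2]]
    dist2 <- (xf - cx)^2 + (yf - cy)^2
    denom_fine <- sum(exp(-dist2 / (2 * 2.5^2))) * 0.002
    expect_equal(rm1$kernel_occupancy[pick[b, 1], pick[b, 2]], denom_fine,
                 tolerance = 0.01)
  }
})

test_that("rate map conserves total spike mass approximately", {
  trj <- simulate_trajectory(300, seed = 17)
  st <- simulate_place_cell(trj, cell_spec(peak_rate = 6, field_sigma = 9),
                            seed = 18)
  sp <- compute_speed(trj); mk <- movement_mask(sp)
  rm1 <- rate_map(trj, st, sp, mk)
  mass <- sum(rm1$rate[rm1$valid] * rm1$occupancy[rm1$valid])
  n_masked <- rm1$n_spikes
  expect_equal(mass, n_masked, tolerance = 0.05)
})

test_that("spatial information matches closed forms and the direct sum", {
  # uniform firing over uniform occupancy -> 0 bits/spike
  uni <- make_rate_map(matrix(1, 4, 4), matrix(2, 4, 4))
  expect_equal(spatial_information(uni), 0)
  expect_equal(sparsity(uni), 1)

  # firing confined to 1 of 4 equally occupied bins -> 2 bits/spike, 0.25
  occ <- matrix(1, 2, 2)
  rate <- matrix(c(4, 0, 0, 0), 2, 2)
  conf <- make_rate_map(occ, rate, valid = occ > 0)
  expect_equal(spatial_information(conf), 2)
  expect_equal(sparsity(conf), 0.25)

  # agreement with an independent direct summation on random maps
  set.seed(19)
  for (k in 1:1000) {
    n <- sample(3:8, 1)
    p_raw <- rexp(n * n) + 0.01
    occ <- matrix(p_raw, n, n)
    rate <- matrix(rgamma(n * n, 1.2, 0.5), n, n)
    m <- make_rate_map(occ, rate, valid = occ > 0)
    p <- p_raw / sum(p_raw)
    expect_equal(spatial_information(m), direct_si(p, as.vector(rate)),
                 tolerance = 1e-12)
    expect_equal(sparsity(m), direct_sparsity(p, as.vector(rate)),
                 tolerance = 1e-12)
    expect_lte(sparsity(m), 1 + 1e-12)  # Cauchy-Schwarz bound
    expect_gte(spatial_information(m), -1e-12)
  }

  zero <- make_rate_map(matrix(1, 2, 2), matrix(0, 2, 2),
                        valid = matrix(TRUE, 2, 2))
  expect_error(spatial_information(zero), class = "pc_validation_error")
  expect_error(sparsity(zero), class = "pc_validation_error")
})

test_that("percent active bins uses raw spike positions over visited bins", {
  trj <- simulate_trajectory(300, seed = 23)
  spec <- cell_spec(field_center = c(0, 0), field_sigma = 6, peak_rate = 5,
                    baseline_rate = 0)
  st <- simulate_place_cell(trj, spec, seed = 24)
  rm1 <- rate_map(trj, st)
  pab <- percent_active_bins(rm1, trj, st)
  expect_gte(pab, 0); expect_lte(pab, 100)
  # no spikes -> 0 %
  expect_equal(percent_active_bins(rm1, trj, numeric(0)), 0)
  # a compact field activates fewer bins than a diffuse one
  diffuse <- simulate_place_cell(trj, cell_spec(field_sigma = 20,
                                                peak_rate = 5,
                                                baseline_rate = 0.5),
                                 seed = 25)
  rm2 <- rate_map(trj, diffuse)
  expect_lt(pab, percent_active_bins(rm2, trj, diffuse))
})

test_that("place-field detection follows the 9-bin 20% rule", {
  n <- 12
  occ <- matrix(1, n, n)
  base <- matrix(0.01, n, n)

  # one 3x3 supra-threshold block -> one field of 9 bins, 56.25 cm^2
  r1 <- base; r1[4:6, 4:6] <- 10
  f1 <- detect_place_fields(make_rate_map(occ, r1))
  expect_equal(nrow(f1), 1)
  expect_equal(f1$n_bins, 9)
  expect_equal(f1$area_cm2, 56.25)
  expect_true(f1$is_main)

  # 8 contiguous bins only -> no field
  r2 <- base; r2[4:5, 4:7] <- 10
  expect_equal(nrow(detect_place_fields(make_rate_map(occ, r2))), 0)

  # two blocks, the max inside the larger one -> larger is main
  r3 <- base; r3[2:4, 2:4] <- 8; r3[7:10, 7:10] <- 10
  f3 <- detect_place_fields(make_rate_map(occ, r3))
  expect_equal(nrow(f3), 2)
  expect_equal(f3$n_bins[f3$is_main], 16)

  # threshold is relative: scaling the map changes nothing
  f3b <- detect_place_fields(make_rate_map(occ, r3 * 7.3))
  expect_equal(f3b$n_bins, f3$n_bins)
  expect_equal(f3b$is_main, f3$is_main)

  # 4- vs 8-connectivity: diagonal-only contact splits under 4
  r4 <- base; r4[2:4, 2:4] <- 10; r4[5:7, 5:7] <- 9
  f4 <- detect_place_fields(make_rate_map(occ, r4), connectivity = 4)
  f8 <- detect_place_fields(make_rate_map(occ, r4), connectivity = 8)
  expect_equal(nrow(f4), 2)
  expect_equal(nrow(f8), 1)
})

test_that("map stability computes Fisher-z Pearson r with SI gating", {
  trj <- simulate_trajectory(300, seed = 26)
  spec <- cell_spec(field_center = c(8, 0), field_sigma = 6, peak_rate = 8,
                    baseline_rate = 0.02)
  st <- simulate_place_cell(trj, spec, seed = 27)
  m <- rate_map(trj, st)

  self <- map_stability(m, m)
  expect_true(self$included)
  expect_equal(self$r, 1, tolerance = 1e-9)
  expect_equal(self$z, atanh(1 - 1e-7), tolerance = 1e-6)

  # a second realisation of the same cell correlates positively
  st2 <- simulate_place_cell(trj, spec, seed = 28)
  m2 <- rate_map(trj, st2)
  s <- map_stability(m, m2)
  expect_true(s$included)
  expect_gt(s$r, 0.5)
  expect_equal(s$z, atanh(s$r))

  # low-SI maps are excluded, not scored zero
  blur <- simulate_place_cell(trj, cell_spec(field_sigma = 25, peak_rate = 3,
                                             baseline_rate = 2), seed = 29)
  mb <- rate_map(trj, blur)
  expect_lt(spatial_information(mb), 0.5)
  s2 <- map_stability(mb, m)
  expect_false(s2$included)
  expect_true(is.na(s2$r))
})
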