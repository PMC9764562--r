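test_that("waveform energy is the sum of squared moduli", {
  expect_equal(waveform_energy(c(1, -1, 2)), 6)
  expect_equal(waveform_energy(rep(0, 10)), 0)
  expect_error(waveform_energy(numeric(0)), class = "pc_validation_error")
  set.seed(1)
  x <- rnorm(32)
  for (c0 in c(0.5, 2, -3)) {
    expect_equal(waveform_energy(c0 * x), c0^2 * waveform_energy(x))
  }
})

test_that("isolation distance matches hand enumeration in 1-D", {
  # cluster with unit variance, n_c = 2; non-cluster at distances 1, 2, 3
  cluster <- matrix(c(-1, 1), ncol = 1)  # mean 0, var 2 -> rescale
  cluster <- cluster / sqrt(2)           # mean 0, var 1
  nonc <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(isolation_distance(cluster, nonc), 4)  # (2nd closest)^2

  # all non-cluster spikes at the cluster mean -> 0
  clus2 <- matrix(rnorm(40), ncol = 2)
  at_mean <- matrix(rep(colMeans(clus2), 25), ncol = 2, byrow = TRUE)
  expect_equal(isolation_distance(clus2, at_mean), 0, tolerance = 1e-12)

  # undefined when non-cluster spikes are fewer than cluster spikes
  expect_true(is.na(isolation_distance(clus2, clus2[1:3, ])))
})

test_that("cluster metrics are invariant under joint affine maps", {
  set.seed(21)
  cluster <- matrix(rnorm(60 * 3), ncol = 3)
  nonc <- matrix(rnorm(200 * 3, mean = 2), ncol = 3)
  A <- matrix(rnorm(9), 3, 3) + diag(3)  # well-conditioned
  b <- rnorm(3)
  tx <- function(m) sweep(m %*% t(A), 2, b, `+`)
  expect_equal(isolation_distance(tx(cluster), tx(nonc)),
               isolation_distance(cluster, nonc), tolerance = 1e-8)
  expect_equal(l_ratio(tx(cluster), tx(nonc)),
               l_ratio(cluster, nonc), tolerance = 1e-8)
})

test_that("Iso-D and L-ratio agree with a brute-force loop implementation", {
  set.seed(31)
  for (k in 1:20) {
    d <- sample(2:4, 1)
    n_c <- sample(seq(d + 2, 50), 1)
    cluster <- matrix(rnorm(n_c * d, sd = runif(1, 0.5, 2)), ncol = d)
    nonc <- matrix(rnorm(sample(60:150, 1) * d, mean = runif(1, 0, 3)),
                   ncol = d)
    expect_equal(isolation_distance(cluster, nonc),
                 brute_isolation_distance(cluster, nonc), tolerance = 1e-10)
    expect_equal(l_ratio(cluster, nonc),
                 brute_l_ratio(cluster, nonc), tolerance = 1e-10)
  }
})

test_that("L-ratio behaves as the chi-square tail mass", {
  set.seed(41)
  cluster <- matrix(rnorm(30 * 2), ncol = 2)
  # one non-cluster spike at the chi-square median -> L_ratio = 0.5 / n_c
  mom_mu <- colMeans(cluster)
  ch <- chol(stats::cov(cluster))
  target_d2 <- qchisq(0.5, df = 2)
  dir <- c(1, 0)
  # construct a point at exactly that Mahalanobis distance
  v <- t(ch) %*% dir
  pt <- mom_mu + as.numeric(v) * sqrt(target_d2 / sum(dir^2))
  expect_equal(l_ratio(cluster, matrix(pt, ncol = 2), df = 2),
               0.5 / nrow(cluster), tolerance = 1e-10)

  # far non-cluster spikes -> L_ratio ~ 0
  far <- matrix(rnorm(100 * 2, mean = 100), ncol = 2)
  expect_lt(l_ratio(cluster, far), 1e-6)

  # adding a spike never decreases L (= l_ratio * n_c)
  nonc <- matrix(rnorm(50 * 2, mean = 2), ncol = 2)
  l1 <- l_ratio(cluster, nonc)
  l2 <- l_ratio(cluster, rbind(nonc, c(50, 50)))
  expect_gte(l2, l1)

  # singular covariance is an explicit error
  degen <- cbind(1:10, 1:10)
  expect_error(l_ratio(degen, nonc), class = "pc_singular_error")
})

test_that("pyramidal classification applies strict thresholds", {
  q <- function(iso, l) tibble::tibble(isolation_distance = iso, l_ratio = l)
  st <- spike_train(1:10, mean_waveform_width = 300)
  expect_true(classify_pyramidal(st, q(16, 0.1), rate = 1))
  expect_false(classify_pyramidal(st, q(15, 0.1), rate = 1))    # strict >
  expect_false(classify_pyramidal(st, q(16, 0.2), rate = 1))    # strict <
  expect_false(classify_pyramidal(st, q(16, 0.1), rate = 5))    # strict <
  narrow <- spike_train(1:10, mean_waveform_width = 250)
  expect_false(classify_pyramidal(narrow, q(16, 0.1), rate = 1))  # strict >
  # missing quality -> FALSE with a reason, not an error
  v <- classify_pyramidal(st, q(NA_real_, 0.1), rate = 1)
  expect_false(v)
  expect_match(attr(v, "reasons"), "undefined", all = FALSE)
})

test_that("pyramidal classification is monotone in each criterion", {
  set.seed(51)
  q <- function(iso, l) tibble::tibble(isolation_distance = iso, l_ratio = l)
  for (k in 1:50) {
    iso <- runif(1, 5, 30); l <- runif(1, 0, 0.4)
    w <- runif(1, 150, 400); r <- runif(1, 0, 8)
    st <- spike_train(1:5, mean_waveform_width = w)
    base <- as.logical(classify_pyramidal(st, q(iso, l), r))
    better_st <- spike_train(1:5, mean_waveform_width = w + 50)
    improved <- c(
      classify_pyramidal(st, q(iso + 5, l), r),
      classify_pyramidal(st, q(iso, l / 2), r),
      classify_pyramidal(better_st, q(iso, l), r),
      classify_pyramidal(st, q(iso, l), r / 2))
    if (base) expect_true(all(improved))
  }
})

test_that("activity criterion uses strict 0.1 and 5 Hz bounds", {
  expect_true(is_active(61 / 600))
  expect_false(is_active(60 / 600))
  expect_false(is_active(0))
  expect_false(is_active(5))
  expect_true(is_active(4.999))
})

test_that("masked mean firing rate divides masked count by masked time", {
  sp <- speed_from_vector(rep(c(10, 0), 100))  # 50 s moving, 50 s still
  mk <- movement_mask(sp)
  # one spike per second, each falling in a moving epoch -> 100 / 50 s
  st <- spike_train(seq(0.1, 99.1, by = 1))
  expect_equal(mean_firing_rate(st, sp, mk), 2)
  expect_equal(mean_firing_rate(st, session_duration = 100), 1)
  expect_error(mean_firing_rate(st, sp, rep(FALSE, 200)),
               class = "pc_validation_error")
})

test_that("burst statistics match hand enumeration", {
  st <- c(0, 5, 205, 210, 215, 415) / 1000
  bp <- burst_probability(st)
  expect_equal(bp$n_bursts, 2)
  expect_equal(bp$n_singles, 1)
  expect_equal(bp$burst_probability, 2 / 3)
  expect_equal(burst_spike_fraction(st), 5 / 6)

  sparse <- seq(0, 1, by = 0.05)
  expect_equal(burst_probability(sparse)$burst_probability, 0)
  expect_equal(burst_spike_fraction(sparse), 0)

  one_burst <- c(0, 0.005, 0.009, 0.013)
  expect_equal(burst_probability(one_burst)$burst_probability, 1)
  expect_equal(burst_spike_fraction(one_burst), 1)

  expect_equal(burst_probability(c(0.5))$n_bursts, 0)
})

test_that("burst probability is rank-stable across ISI thresholds", {
  set.seed(61)
  trj <- simulate_trajectory(300, seed = 62)
  probs <- sapply(1:40, function(k) {
    spec <- cell_spec(field_center = c(runif(1, -15, 15), runif(1, -15, 15)),
                      peak_rate = runif(1, 2, 8),
                      burst_doublet_prob = runif(1, 0, 0.5))
    st <- simulate_place_cell(trj, spec)
    vapply(c(6, 9, 10, 12),
           function(thr) burst_probability(st, thr)$burst_probability, 0)
  })
  base <- probs[3, ]
  for (row in c(1, 2, 4)) {
    expect_gt(cor(probs[row, ], base, method = "spearman"), 0.9)
  }
})
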