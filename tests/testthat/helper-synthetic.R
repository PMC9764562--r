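# Small fixture builders shared across test files.

# straight-line trajectory at constant speed (cm/s) along +x, starting at x0
straight_traj <- function(duration = 10, speed = 10, fs = 50, x0 = -25,
                          arena_radius = 31) {
  t <- seq(0, duration, by = 1 / fs)
  trajectory(tibble::tibble(time = t, x = x0 + speed * t, y = 0),
             arena_radius = arena_radius)
}

# stationary trajectory at a point
still_traj <- function(duration = 10, fs = 50, x = 0, y = 0) {
  t <- seq(0, duration, by = 1 / fs)
  trajectory(tibble::tibble(time = t, x = x, y = y), arena_radius = 31)
}

# circular trajectory of radius r at angular rate omega (rad/s)
circle_traj <- function(r = 20, omega = 0.5, n = 1000, duration = 2 * pi / 0.5,
                        arena_radius = 31) {
  t <- seq(0, duration, length.out = n)
  trajectory(tibble::tibble(time = t, x = r * cos(omega * t),
                            y = r * sin(omega * t)),
             arena_radius = arena_radius)
}

# speed series built directly from a per-epoch speed vector
speed_from_vector <- function(v, epoch_duration = 0.5) {
  tibble::new_tibble(
    list(epoch_start = (seq_along(v) - 1) * epoch_duration,
         speed = v, defined = !is.na(v)),
    nrow = length(v), class = "speed_series",
    epoch_duration = epoch_duration)
}

# a pure tone lfp
tone_lfp <- function(freq, duration = 30, fs = 1200, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  lfp_recording(amp * cos(2 * pi * freq * t), fs = fs)
}

# brute-force cluster metrics with explicit loops and an explicit inverse
brute_mahal <- function(x, cluster) {
  mu <- colMeans(cluster)
  sigma_inv <- solve(stats::cov(cluster))
  apply(x, 1, function(row) {
    d <- row - mu
    as.numeric(t(d) %*% sigma_inv %*% d)
  })
}

brute_isolation_distance <- function(cluster, noncluster) {
  if (nrow(noncluster) < nrow(cluster)) return(NA_real_)
  d2 <- brute_mahal(noncluster, cluster)
  sort(d2)[nrow(cluster)]
}

brute_l_ratio <- function(cluster, noncluster, df = ncol(cluster)) {
  d2 <- brute_mahal(noncluster, cluster)
  total <- 0
  for (v in d2) total <- total + (1 - pchisq(v, df))
  total / nrow(cluster)
}

# direct-summation spatial metrics on explicit P and R vectors
direct_si <- function(p, r) {
  R <- sum(p * r)
  s <- 0
  for (i in seq_along(p)) {
    if (r[i] > 0) s <- s + p[i] * (r[i] / R) * log2(r[i] / R)
  }
  s
}

direct_sparsity <- function(p, r) sum(p * r)^2 / sum(p * r^2)

# random valid rate map on an n x n grid
random_rate_map <- function(n = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- matrix(stats::rexp(n * n) + 0.05, n, n)
  rate <- matrix(stats::rgamma(n * n, shape = 1.2, rate = 0.5), n, n)
  make_rate_map(occ, rate, bin_size = 2.5)
}
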