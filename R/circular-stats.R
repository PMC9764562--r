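#' Circular descriptive statistics
#'
#' Mean resultant vector of a sample of angles: `r = sum(exp(i*theta))/N`.
#' `circ_r()` returns its length (0 for uniformly spread phases, 1 when
#' all angles coincide), `circ_mean()` its argument in `[0, 2*pi)`.
#'
#' @param angles Numeric vector of angles in radians.
#' @return Scalar.
#' @export
circ_r <- function(angles) {
  Mod(mean(exp(1i * angles)))
}

#' @rdname circ_r
#' @export
circ_mean <- function(angles) {
  Arg(mean(exp(1i * angles))) %% (2 * pi)
}

# signed smallest difference between two angles, in (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# maximum-likelihood-ish concentration estimate (A1 inverse approximation)
circ_kappa <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed against
#' a unimodal alternative.  The statistic is `Z = n * r^2`; the p-value
#' uses the standard small-sample-corrected exponential approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n*r`.
#'
#' @param angles Angles in radians (n >= 3).
#' @return A one-row tibble: `statistic` (Z), `r`, `n`, `p_value`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3) abort("Rayleigh test needs n >= 3.", class = "pc_validation_error")
  r <- circ_r(angles)
  R <- n * r
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble::tibble(statistic = z, r = r, n = n, p_value = min(max(p, 0), 1))
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analogue of one-way ANOVA: tests whether two or more groups of
#' angles share a common mean direction, assuming von Mises samples with
#' comparable concentration.  Uses the kappa-based correction factor
#' `1 + 3/(8*kappa_hat)`.  A low pooled concentration (kappa_hat < 1)
#' triggers a warning — the F approximation degrades — but the test is
#' still computed.
#'
#' @param angles Angles in radians.
#' @param group Group labels, same length; at least 2 groups of >= 2.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `kappa`.
#' @export
watson_williams <- function(angles, group) {
  group <- as.factor(group)
  sizes <- table(group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Watson-Williams needs >= 2 groups with >= 2 angles each.",
          class = "pc_validation_error")
  }
  if (any(sizes < 5)) warn("Group size < 5: Watson-Williams approximation is unreliable.")
  n <- length(angles)
  k <- nlevels(group)
  Ri <- vapply(split(angles, group), function(a) length(a) * circ_r(a), 0)
  R <- n * circ_r(angles)
  rw <- sum(Ri) / n
  kappa <- circ_kappa(rw)
  if (kappa < 1) {
    warn("Pooled concentration kappa < 1: Watson-Williams assumptions are strained.")
  }
  Fstat <- ((n - k) * (sum(Ri) - R)) / ((k - 1) * (n - sum(Ri)))
  Fstat <- Fstat * (1 + 3 / (8 * kappa))
  df1 <- k - 1
  df2 <- n - k
  tibble::tibble(statistic = Fstat, df1 = df1, df2 = df2,
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
                 kappa = kappa)
}

#' Harrison-Kanji two-factor test for circular data
#'
#' Two-way ANOVA analogue for angular data (e.g. genotype x day effects on
#' preferred phase), returning p-values for both main effects and their
#' interaction.  Implements the high-concentration F approximation with
#' the `1/(1 - 1/(5k) - 1/(10k^2))` correction; for pooled concentration
#' estimates below 2 the approximation degrades and a warning is issued.
#'
#' @param angles Angles in radians.
#' @param factor_a,factor_b Factors (2 or more levels each); every cell of
#'   the design must be non-empty.
#' @return A tibble with rows `factor_a`, `factor_b`, `interaction`:
#'   columns `term`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
harrison_kanji <- function(angles, factor_a, factor_b) {
  fa <- as.factor(factor_a); fb <- as.factor(factor_b)
  p <- nlevels(fa); q <- nlevels(fb)
  if (p < 2 || q < 2) {
    abort("Both factors need >= 2 levels.", class = "pc_validation_error")
  }
  if (any(table(fa, fb) == 0)) {
    abort("Empty cell in the factorial design.", class = "pc_validation_error")
  }
  n <- length(angles)
  R_of <- function(a) length(a) * circ_r(a)
  pr <- vapply(split(angles, fa), R_of, 0)
  pn <- as.numeric(table(fa))
  qr <- vapply(split(angles, fb), R_of, 0)
  qn <- as.numeric(table(fb))
  cells <- split(angles, interaction(fa, fb, drop = TRUE))
  cr <- vapply(cells, R_of, 0)
  cn <- vapply(cells, length, 0L)
  tr <- n * circ_r(angles)
  kk <- circ_kappa(tr / n)
  if (kk <= 2) {
    warn("Pooled concentration kappa <= 2: Harrison-Kanji high-concentration approximation is unreliable here.")
  }
  eff_a <- sum(pr^2 / pn) - tr^2 / n
  eff_b <- sum(qr^2 / qn) - tr^2 / n
  eff_ab <- sum(cr^2 / cn) - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n
  eff_r <- n - sum(cr^2 / cn)
  df_a <- p - 1; df_b <- q - 1; df_ab <- (p - 1) * (q - 1)
  df_r <- n - p * q
  beta <- 1 / (1 - 1 / (5 * kk) - 1 / (10 * kk^2))
  ms_r <- eff_r / df_r
  f_of <- function(eff, df) beta * (eff / df) / ms_r
  Fa <- f_of(eff_a, df_a); Fb <- f_of(eff_b, df_b); Fab <- f_of(eff_ab, df_ab)
  tibble::tibble(
    term = c("factor_a", "factor_b", "interaction"),
    statistic = c(Fa, Fb, Fab),
    df1 = c(df_a, df_b, df_ab),
    df2 = df_r,
    p_value = pf(c(Fa, Fb, Fab), c(df_a, df_b, df_ab), df_r,
                 lower.tail = FALSE)
  )
}

#' Two-proportion z-test
#'
#' Two-sided test of equality of two binomial proportions using the pooled
#' variance estimate: `z = (p1 - p2) / sqrt(p_hat (1 - p_hat) (1/n1 + 1/n2))`.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A one-row tibble: `statistic` (z), `p1`, `p2`, `p_value`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) abort("Trial counts must be positive.",
                                class = "pc_validation_error")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) {
    abort("Successes must lie in [0, n].", class = "pc_validation_error")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(statistic = z, p1 = p1, p2 = p2,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `alpha`; adjusted p-values via
#' `stats::p.adjust(method = "BH")`.  BH rejections always contain the
#' Bonferroni rejections.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A tibble: `p_value`, `p_adjusted`, `rejected` (in input order).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "pc_validation_error")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 rejected = adj <= alpha)
}

#' Fisher z transformation
#'
#' Variance-stabilising transform for Pearson correlations:
#' `z = 0.5 * ln((1 + r)/(1 - r)) = atanh(r)`; `fisher_z_inverse()` is
#' `tanh`.  `|r| >= 1` is clipped to `1 - 1e-7` with a warning so that
#' self-correlations remain finite.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1 - 1e-7
  if (any(clip, na.rm = TRUE)) {
    warn("|r| at or above 1 - 1e-7 clipped before Fisher z.")
    r[which(clip)] <- sign(r[which(clip)]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Draw von Mises random angles
#'
#' Best-Fisher (1979) rejection sampler; with `kappa = 0` angles are
#' uniform on `[0, 2*pi)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("kappa must be >= 0.", class = "pc_validation_error")
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    c0 <- kappa * (r0 - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    good <- theta[ok]
    take <- min(length(good), m)
    if (take > 0) out[(filled + 1):(filled + take)] <- good[seq_len(take)]
    filled <- filled + take
  }
  (out + mu) %% (2 * pi)
}
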