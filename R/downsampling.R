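#' Firing-rate-constrained subsamples
#'
#' Draws `reps` subsamples of `n` cells uniformly at random *with
#' replacement*, keeping only draws whose mean firing rate falls within
#' `tol` (default 5%) of `target_rate` — e.g. the overall mean rate of the
#' reference population.  Rejection sampling with an attempt budget; if
#' the constraint cannot be satisfied, a feasibility error reports the
#' achieved acceptance rate.
#'
#' @param rates Numeric vector of per-cell firing rates (Hz).
#' @param target_rate Target mean rate (Hz).
#' @param n Subsample size (default 30, the typical per-rat cell count).
#' @param reps Number of accepted subsamples required (default 1000).
#' @param tol Relative tolerance on the subsample mean (default 0.05).
#' @param seed Optional RNG seed.
#' @param max_attempts Attempt budget across the whole draw.
#' @return A list of class `"constrained_subsamples"`: `index_sets`
#'   (reps x n integer matrix), `accepted_means`, `n_attempts`,
#'   `acceptance_rate`, `target_rate`, `tol`.
#' @export
constrained_subsample <- function(rates, target_rate, n = 30, reps = 1000,
                                  tol = 0.05, seed = NULL,
                                  max_attempts = 1e6 * reps) {
  if (length(rates) < 1) abort("Empty population.", class = "pc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  lo <- target_rate * (1 - tol); hi <- target_rate * (1 + tol)
  idx <- matrix(NA_integer_, reps, n)
  means <- numeric(reps)
  accepted <- 0L; attempts <- 0L
  batch <- 500L
  while (accepted < reps) {
    if (attempts >= max_attempts) {
      abort(sprintf(
        "Rate constraint unattainable: %d accepted in %d attempts (rate %.2e).",
        accepted, attempts, accepted / attempts),
        class = "pc_feasibility_error")
    }
    draws <- matrix(sample.int(length(rates), batch * n, replace = TRUE),
                    batch, n)
    m <- rowMeans(matrix(rates[draws], batch, n))
    ok <- which(m >= lo & m <= hi)
    take <- head(ok, reps - accepted)
    # count only draws examined up to the last one we needed
    attempts <- attempts +
      if (length(take) == reps - accepted) take[length(take)] else batch
    if (length(take) > 0) {
      idx[(accepted + 1):(accepted + length(take)), ] <- draws[take, ,
                                                               drop = FALSE]
      means[(accepted + 1):(accepted + length(take))] <- m[take]
      accepted <- accepted + length(take)
    }
  }
  structure(list(index_sets = idx, accepted_means = means,
                 n_attempts = attempts, acceptance_rate = reps / attempts,
                 target_rate = target_rate, tol = tol),
            class = "constrained_subsamples")
}

#' Probability that a metric difference is rate-driven
#'
#' For each rate-constrained subsample, the subsample's values of a metric
#' are tested against the full population's values (Welch two-sample
#' t-test, or Watson-Williams for a circular metric such as preferred
#' theta phase).  The fraction of subsamples that differ significantly at
#' `alpha` is the modulation probability: near the test's type-I level
#' (0.05) when the metric is unrelated to rate, near 1 when the metric is
#' strongly rate-driven.
#'
#' @param subsamples A `"constrained_subsamples"` object.
#' @param metric Numeric vector of the metric, one value per cell, aligned
#'   with the `rates` used for the draw (may contain `NA`).
#' @param circular Treat the metric as angles and use [watson_williams()].
#' @param alpha Significance level (default 0.05).
#' @return A list of class `"downsampling_result"`: `modulation_probability`,
#'   `subsample_means`, `n_tested`, `n_skipped`, `alpha`, `circular`, plus
#'   the draw diagnostics.
#' @export
modulation_probability <- function(subsamples, metric, circular = FALSE,
                                   alpha = 0.05) {
  idx <- subsamples$index_sets
  pop <- metric[!is.na(metric)]
  p_vals <- rep(NA_real_, nrow(idx))
  means <- rep(NA_real_, nrow(idx))
  skipped <- 0L
  for (k in seq_len(nrow(idx))) {
    vals <- metric[idx[k, ]]
    if (mean(is.na(vals)) > 0.5) {
      skipped <- skipped + 1L
      next
    }
    vals <- vals[!is.na(vals)]
    if (circular) {
      means[k] <- circ_mean(vals)
      p_vals[k] <- tryCatch(
        watson_williams(c(vals, pop),
                        c(rep("sub", length(vals)),
                          rep("pop", length(pop))))$p_value,
        error = function(e) NA_real_)
    } else {
      means[k] <- mean(vals)
      p_vals[k] <- tryCatch(
        suppressWarnings(t.test(vals, pop)$p.value),
        error = function(e) NA_real_)
    }
  }
  tested <- !is.na(p_vals)
  if (!any(tested)) {
    abort("No subsample could be tested.", class = "pc_validation_error")
  }
  if (skipped > 0) {
    inform(sprintf("%d subsample(s) skipped (metric undefined for > 50%%).",
                   skipped))
  }
  structure(list(
    modulation_probability = mean(p_vals[tested] < alpha),
    subsample_means = means,
    n_tested = sum(tested), n_skipped = skipped,
    alpha = alpha, circular = circular,
    target_rate = subsamples$target_rate,
    acceptance_rate = subsamples$acceptance_rate),
    class = "downsampling_result")
}

#' @export
print.downsampling_result <- function(x, ...) {
  cat(sprintf(
    "<downsampling_result: modulation probability %.3f over %d subsamples%s>\n",
    x$modulation_probability, x$n_tested,
    if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Rate-change-matched subsamples for between-day stability
#'
#' Controls the session 3 to session 4 (last of day 1 to first of day 2)
#' stability comparison for firing-rate change: subsamples of cells are
#' constrained on their mean rate *decrease* between the two sessions —
#' either matched to a reference decrease (e.g. the WT population's mean
#' S3-S4 decrease, within 5% of it) or constrained to no change (within
#' 5% of the same reference scale) — and each subsample's Fisher-z S3-S4
#' map-correlation distribution is tested against the full population.
#'
#' @param rate_s3,rate_s4 Per-cell mean rates in sessions 3 and 4 (Hz).
#' @param stability_z Per-cell Fisher-z S3-S4 rate-map correlations
#'   (`NA` allowed for excluded cells).
#' @param reference_decrease Reference mean decrease in Hz (S3 - S4).
#' @param mode `"matched-decrease"` (target = reference) or
#'   `"null-decrease"` (target = 0).
#' @param n,reps,tol,seed,max_attempts As in [constrained_subsample()];
#'   `tol` is relative to `reference_decrease` in both modes.
#' @param alpha Significance level for the per-subsample t-test.
#' @return A `"downsampling_result"` (see [modulation_probability()]),
#'   with the accepted decrease means in `accepted_decreases`.
#' @export
rate_change_matched_subsample <- function(rate_s3, rate_s4, stability_z,
                                          reference_decrease,
                                          mode = c("matched-decrease",
                                                   "null-decrease"),
                                          n = 30, reps = 1000, tol = 0.05,
                                          seed = NULL,
                                          max_attempts = 1e6 * reps,
                                          alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(rate_s3) != length(rate_s4) ||
      length(rate_s3) != length(stability_z)) {
    abort("Per-cell vectors must align.", class = "pc_format_error")
  }
  decrease <- rate_s3 - rate_s4
  target <- if (mode == "matched-decrease") reference_decrease else 0
  slack <- tol * abs(reference_decrease)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(NA_integer_, reps, n)
  dec_means <- numeric(reps)
  accepted <- 0L; attempts <- 0L; batch <- 500L
  while (accepted < reps) {
    if (attempts >= max_attempts) {
      abort(sprintf(
        "Decrease constraint unattainable: %d accepted in %d attempts.",
        accepted, attempts),
        class = "pc_feasibility_error")
    }
    draws <- matrix(sample.int(length(decrease), batch * n, replace = TRUE),
                    batch, n)
    m <- rowMeans(matrix(decrease[draws], batch, n))
    ok <- which(abs(m - target) <= slack)
    take <- head(ok, reps - accepted)
    attempts <- attempts +
      if (length(take) == reps - accepted) take[length(take)] else batch
    if (length(take) > 0) {
      idx[(accepted + 1):(accepted + length(take)), ] <-
        draws[take, , drop = FALSE]
      dec_means[(accepted + 1):(accepted + length(take))] <- m[take]
      accepted <- accepted + length(take)
    }
  }
  subs <- structure(list(index_sets = idx, accepted_means = dec_means,
                         n_attempts = attempts,
                         acceptance_rate = reps / attempts,
                         target_rate = target, tol = tol),
                    class = "constrained_subsamples")
  out <- modulation_probability(subs, stability_z, circular = FALSE,
                                alpha = alpha)
  out$accepted_decreases <- dec_means
  out$mode <- mode
  out
}
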