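#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a down-sampling result
#'
#' @param x A `"downsampling_result"`.
#' @param ... Unused.
#' @return One row per subsample: `subsample`, `mean`.
#' @exportS3Method generics::tidy
tidy.downsampling_result <- function(x, ...) {
  tibble::tibble(subsample = seq_along(x$subsample_means),
                 mean = x$subsample_means)
}

#' @rdname tidy.downsampling_result
#' @exportS3Method generics::glance
glance.downsampling_result <- function(x, ...) {
  tibble::tibble(modulation_probability = x$modulation_probability,
                 n_tested = x$n_tested, n_skipped = x$n_skipped,
                 alpha = x$alpha, circular = x$circular,
                 acceptance_rate = x$acceptance_rate)
}

#' Tidy a rate map
#'
#' @param x A `"rate_map"`.
#' @param ... Unused.
#' @return One row per bin: `x`, `y` (bin centres, cm), `occupancy` (s),
#'   `rate` (Hz), `valid`.
#' @exportS3Method generics::tidy
tidy.rate_map <- function(x, ...) {
  grid <- expand.grid(x = x$centers, y = x$centers)
  occ <- as.vector(x$occupancy)
  rate <- as.vector(x$rate)
  valid <- as.vector(x$valid)
  tibble::tibble(x = grid$x, y = grid$y, occupancy = occ,
                 rate = rate, valid = valid)
}

#' @rdname tidy.rate_map
#' @exportS3Method generics::glance
glance.rate_map <- function(x, ...) {
  tibble::tibble(
    n_valid_bins = sum(x$valid),
    peak_rate = if (any(x$valid)) max(x$rate[x$valid]) else NA_real_,
    mean_rate = if (any(x$valid)) {
      sum(x$rate[x$valid] * x$occupancy[x$valid]) / sum(x$occupancy[x$valid])
    } else NA_real_,
    bin_size = x$bin_size, h = x$h, n_spikes = x$n_spikes)
}

#' Tidy an experiment result
#'
#' @param x An `"experiment_result"`.
#' @param ... Unused.
#' @return The per-cell per-session metric tibble.
#' @exportS3Method generics::tidy
tidy.experiment_result <- function(x, ...) x$cells

#' @rdname tidy.experiment_result
#' @exportS3Method generics::glance
glance.experiment_result <- function(x, ...) {
  tibble::tibble(n_cell_sessions = nrow(x$cells),
                 n_active = sum(x$cells$active),
                 n_stability_pairs = nrow(x$stability),
                 n_log_lines = length(x$log))
}
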