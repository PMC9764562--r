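#' Analysis configuration
#'
#' Bundles every analysis constant with its conventional default: 2.5-cm
#' bins, 2.5-cm kernel width, 3 cm/s locomotion threshold, 100-ms bin
#' occupancy criterion, 10-ms burst ISI, place fields of at least 9 bins
#' above 20% of the map peak, SI > 0.5 bits/spike for stability
#' inclusion, 500-ms epochs, 2-SD strong-oscillation criterion, 30-spike
#' minimum for phase locking, and 30-cell / 1000-rep / 5% down-sampling.
#' The config is attached to every pipeline result for provenance.
#'
#' @param ... Overrides of any default (name = value).
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- utils::modifyList(c(.pc_defaults, list(
    strong_sd = 2,
    min_phase_spikes = 30,
    run_duration = 4,
    spectrogram_window = 20,
    spectrogram_step = 10,
    subsample_n = 30,
    subsample_reps = 1000,
    subsample_tol = 0.05,
    lratio_df = NULL,          # NULL: feature dimensionality
    connectivity = 4,
    compute_lfp = TRUE,
    keep_maps = TRUE
  )), list(...))
  stopifnot(cfg$bin_size > 0, cfg$speed_threshold >= 0,
            cfg$min_occupancy > 0, cfg$isi_threshold > 0,
            cfg$min_field_bins >= 1,
            cfg$field_threshold_frac > 0, cfg$field_threshold_frac < 1)
  structure(cfg, class = "analysis_config")
}

# pooled features of all clusters except `id` (for cluster quality)
other_features <- function(trains, id) {
  mats <- purrr::map(trains[names(trains) != id], "features")
  mats <- mats[!vapply(mats, is.null, TRUE)]
  if (length(mats) == 0) return(NULL)
  do.call(rbind, mats)
}

#' Run the full analysis on one session
#'
#' Applies the analysis stages in order — speed and locomotion mask,
#' cluster quality and pyramidal classification, activity filter, rate and
#' burst statistics, rate maps with spatial information / sparsity /
#' place fields / percent active bins, then (when an LFP is present) band
#' power over post-immobility activity epochs and per-cell phase locking
#' per band.  Every exclusion is recorded with its criterion in the
#' result's `log`.
#'
#' @param dataset A [session_dataset()].
#' @param config An [analysis_config()].
#' @return A list of class `"session_result"`: `cells` (one tibble row per
#'   cluster), `maps` (named list of rate maps, if `keep_maps`),
#'   `band_power` (session band power or `NULL`), `log` (character).
#' @export
run_session <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "session_dataset"))
  traj <- dataset$trajectory
  sched <- dataset$session %||% session_schedule(1, 1)
  speed <- compute_speed(traj, config$epoch_duration)
  mask <- movement_mask(speed, config$speed_threshold)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # LFP stage prepared first so per-cell phase locking can reuse it
  band_power <- NULL; phase_ctx <- NULL
  if (!is.null(dataset$lfp) && isTRUE(config$compute_lfp)) {
    epochs <- post_immobility_activity_epochs(speed, config$run_duration,
                                              config$speed_threshold)
    band_power <- tryCatch(
      session_band_power(dataset$lfp, epochs,
                         window = config$spectrogram_window,
                         step = config$spectrogram_step),
      error = function(e) {
        note("session band power skipped: %s", conditionMessage(e))
        NULL
      })
    bands <- band_definitions()
    epoch_pow <- binned_band_power(dataset$lfp, config$epoch_duration)
    phase_ctx <- purrr::map(seq_len(nrow(bands)), function(b) {
      filt <- bandpass(dataset$lfp, bands$filter_lo[b], bands$filter_hi[b])
      list(band = bands$band[b],
           phase = instantaneous_phase_amplitude(filt),
           strong = strong_oscillation_mask(epoch_pow[[bands$band[b]]],
                                            config$strong_sd))
    })
  }

  denom_cache <- NULL
  rows <- list(); maps <- list()
  for (st in dataset$spike_trains) {
    id <- st$cluster_id
    quality <- if (!is.null(st$features)) {
      nonc <- other_features(dataset$spike_trains, id)
      if (is.null(nonc)) {
        note("%s: no non-cluster spikes; quality undefined", id)
        tibble::tibble(isolation_distance = NA_real_, l_ratio = NA_real_,
                       n_spikes = length(st$spike_times),
                       feature_dim = ncol(st$features))
      } else {
        df <- config$lratio_df %||% ncol(st$features)
        tryCatch(cluster_quality(st$features, nonc, df = df),
                 pc_singular_error = function(e) {
                   note("%s: singular feature covariance; quality undefined",
                        id)
                   tibble::tibble(isolation_distance = NA_real_,
                                  l_ratio = NA_real_,
                                  n_spikes = length(st$spike_times),
                                  feature_dim = ncol(st$features))
                 })
      }
    } else {
      tibble::tibble(isolation_distance = NA_real_, l_ratio = NA_real_,
                     n_spikes = length(st$spike_times),
                     feature_dim = NA_integer_)
    }
    rate <- tryCatch(mean_firing_rate(st, speed, mask),
                     error = function(e) NA_real_)
    pyramidal <- if (!is.null(st$features)) {
      v <- classify_pyramidal(st, quality, rate)
      if (!v) note("%s: not pyramidal (%s)", id,
                   paste(attr(v, "reasons"), collapse = "; "))
      as.logical(v)
    } else TRUE  # no features: classification not applicable (synthetic)
    active <- is_active(rate)
    if (!active) note("%s: not active (rate %.3g Hz)", id, rate)

    masked_spikes <- st$spike_times[mask_at_times(st$spike_times, speed, mask)]
    bp <- burst_probability(masked_spikes, config$isi_threshold)
    bf <- burst_spike_fraction(masked_spikes, config$isi_threshold)

    si <- sp <- pab <- fsize <- NA_real_
    if (active) {
      rm <- rate_map(traj, st, speed, mask, bin_size = config$bin_size,
                     h = config$smoothing_h,
                     min_occupancy = config$min_occupancy,
                     denominator = denom_cache)
      denom_cache <- rm$kernel_occupancy
      si <- tryCatch(spatial_information(rm), error = function(e) NA_real_)
      sp <- tryCatch(sparsity(rm), error = function(e) NA_real_)
      pab <- percent_active_bins(rm, traj, st, speed, mask)
      flds <- detect_place_fields(rm, config$min_field_bins,
                                  config$field_threshold_frac,
                                  config$connectivity)
      if (nrow(flds) > 0) fsize <- flds$area_cm2[flds$is_main][1]
      if (isTRUE(config$keep_maps)) maps[[id]] <- rm
    }

    row <- tibble::tibble(
      cell = id, animal = dataset$animal_id,
      genotype = st$genotype %||% dataset$genotype,
      day = sched$day, session = sched$session_index,
      n_spikes = length(st$spike_times),
      isolation_distance = quality$isolation_distance,
      l_ratio = quality$l_ratio,
      waveform_width = st$mean_waveform_width,
      rate = rate, pyramidal = pyramidal, active = active,
      burst_probability = bp$burst_probability,
      burst_spike_fraction = bf,
      spatial_information = si, sparsity = sp,
      percent_active_bins = pab, field_size_cm2 = fsize)

    if (!is.null(phase_ctx)) {
      for (ctx in phase_ctx) {
        pl <- phase_locking(st, ctx$phase, ctx$strong,
                            config$epoch_duration, config$min_phase_spikes)
        row[[paste0("mvl_", ctx$band)]] <- pl$mvl
        row[[paste0("preferred_phase_", ctx$band)]] <- pl$preferred_phase
        row[[paste0("rayleigh_p_", ctx$band)]] <- pl$rayleigh_p
        row[[paste0("n_phase_spikes_", ctx$band)]] <- pl$n_spikes
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  structure(list(cells = dplyr::bind_rows(rows), maps = maps,
                 band_power = band_power, log = log_lines,
                 config = config),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result: %d cells, %d active, %d log line(s)>\n",
              nrow(x$cells), sum(x$cells$active), length(x$log)))
  invisible(x)
}

#' Run the full analysis on a multi-session experiment
#'
#' Runs [run_session()] on every session dataset, assembles the per-cell
#' per-session metric table, computes rate-map stability for the five
#' successive session pairs (S1-S2 through S5-S6) for cells passing the
#' SI inclusion criterion in both sessions of a pair, and summarises
#' metrics by genotype and day over active cells.
#'
#' @param experiment An `"experiment"` from [simulate_experiment()], or a
#'   tibble like its `datasets` component (list-column `dataset`).
#' @param config An [analysis_config()].
#' @return A list of class `"experiment_result"`: `cells` (all per-cell
#'   rows), `stability` (per cell x session pair), `summary` (genotype x
#'   day means over active cells), `band_power`, `log`.
#' @export
run_experiment <- function(experiment, config = analysis_config()) {
  datasets <- if (inherits(experiment, "experiment")) {
    experiment$datasets
  } else {
    tibble::as_tibble(experiment)
  }
  results <- purrr::map(datasets$dataset, run_session, config = config)
  cells <- purrr::map_dfr(results, "cells")
  bp <- purrr::imap_dfr(results, function(r, i) {
    if (is.null(r$band_power)) return(tibble::tibble())
    dplyr::mutate(r$band_power, animal = datasets$animal[i],
                  session = datasets$session_index[i])
  })

  # stability over successive-session pairs, per animal and cell
  stab_rows <- list()
  for (animal in unique(datasets$animal)) {
    rows_a <- which(datasets$animal == animal)
    ord <- rows_a[order(datasets$session_index[rows_a])]
    for (k in seq_len(length(ord) - 1)) {
      ra <- results[[ord[k]]]; rb <- results[[ord[k + 1]]]
      common <- intersect(names(ra$maps), names(rb$maps))
      for (id in common) {
        stab <- map_stability(ra$maps[[id]], rb$maps[[id]],
                              config$si_stability_threshold)
        stab_rows[[length(stab_rows) + 1]] <- dplyr::mutate(
          stab, cell = id, animal = animal,
          pair = sprintf("S%d-S%d", datasets$session_index[ord[k]],
                         datasets$session_index[ord[k + 1]]),
          session_a = datasets$session_index[ord[k]],
          session_b = datasets$session_index[ord[k + 1]],
          .before = 1)
      }
    }
  }
  stability <- dplyr::bind_rows(stab_rows)

  summary <- cells |>
    dplyr::filter(.data$active) |>
    dplyr::group_by(.data$genotype, .data$day) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      dplyr::across(dplyr::any_of(c("rate", "burst_probability",
                                    "spatial_information", "sparsity",
                                    "percent_active_bins",
                                    "field_size_cm2")),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")

  structure(list(cells = cells, stability = stability, summary = summary,
                 band_power = bp,
                 log = unlist(purrr::map(results, "log")),
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result: %d cell-session rows, %d stability pairs>\n",
    nrow(x$cells), nrow(x$stability)))
  invisible(x)
}

#' Export an experiment result as a tidy metrics table
#'
#' Pivots the per-cell metric columns to the long (cell, metric, value)
#' schema consumed by [write_metrics_table()] and external mixed-model
#' software.
#'
#' @param result An `"experiment_result"`.
#' @return A tibble with columns `cell`, `animal`, `genotype`, `day`,
#'   `session`, `metric`, `value`.
#' @export
metrics_long <- function(result) {
  keys <- c("cell", "animal", "genotype", "day", "session")
  num_cols <- setdiff(names(result$cells)[vapply(result$cells, is.numeric,
                                                 TRUE)],
                      c("day", "session"))
  result$cells |>
    dplyr::select(dplyr::all_of(c(keys, num_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(day = as.integer(.data$day),
                  session = as.integer(.data$session))
}
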