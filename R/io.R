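#' Read and write position tables
#'
#' Position tables are UTF-8 comma-delimited files with a mandatory header
#' `time,x,y` (seconds, cm, cm in the arena-centred frame).  Reading
#' validates the trajectory invariants; writing round-trips losslessly at
#' full double precision.
#'
#' @param path File path.
#' @param arena_radius Arena radius in cm passed to [trajectory()].
#' @return `read_position_table()` returns a [trajectory()];
#'   `write_position_table()` returns `path` invisibly.
#' @export
read_position_table <- function(path, arena_radius = 31) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("time", "x", "y"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Position table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pc_format_error")
  }
  trajectory(df, arena_radius = arena_radius)
}

#' @rdname read_position_table
#' @param traj A [trajectory()].
#' @export
write_position_table <- function(traj, path) {
  if (!is_trajectory(traj)) {
    abort("`traj` must be a trajectory.", class = "pc_format_error")
  }
  readr::write_csv(tibble::as_tibble(traj)[c("time", "x", "y")], path)
  invisible(path)
}

#' Read a spike table into spike trains
#'
#' Spike tables are comma-delimited with header
#' `cluster_id,spike_time[,f1..fd]`; feature columns are optional but must
#' be complete (no ragged rows).  One [spike_train()] is returned per
#' distinct `cluster_id`, spikes sorted ascending.
#'
#' @param path File path.
#' @return A named list of [spike_train()] objects (possibly empty).
#' @export
read_spike_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warn("Spike table is empty; returning no spike trains.")
    return(list())
  }
  missing_cols <- setdiff(c("cluster_id", "spike_time"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Spike table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pc_format_error")
  }
  feat_cols <- setdiff(names(df), c("cluster_id", "spike_time"))
  if (length(feat_cols) > 0 && anyNA(df[feat_cols])) {
    abort("Ragged feature columns: every spike needs all feature values.",
          class = "pc_format_error")
  }
  split_df <- split(df, df$cluster_id)
  trains <- purrr::map(split_df, function(d) {
    feats <- if (length(feat_cols) > 0) as.matrix(d[feat_cols]) else NULL
    spike_train(d$spike_time, cluster_id = d$cluster_id[1], features = feats)
  })
  trains[order(names(trains))]
}

#' @rdname read_spike_table
#' @param trains A list of [spike_train()] objects.
#' @export
write_spike_table <- function(trains, path) {
  rows <- purrr::map(trains, function(st) {
    d <- tibble::tibble(cluster_id = st$cluster_id, spike_time = st$spike_times)
    if (!is.null(st$features)) {
      f <- tibble::as_tibble(st$features, .name_repair = "minimal")
      names(f) <- paste0("f", seq_len(ncol(f)))
      d <- dplyr::bind_cols(d, f)
    }
    d
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Write (and re-read) tidy per-cell metric tables
#'
#' The long format — one row per (cell, metric) with the identifying keys
#' `cell`, `animal`, `genotype`, `day`, `session`, `metric`, `value` — is
#' the hand-off contract to external mixed-model software (lme4 and
#' friends).  All rows must carry the same schema.
#'
#' @param records A data frame with the seven columns above.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  schema <- c("cell", "animal", "genotype", "day", "session", "metric", "value")
  records <- tibble::as_tibble(records)
  if (!setequal(names(records), schema)) {
    abort(paste0("Metrics records must have exactly the columns: ",
                 paste(schema, collapse = ", ")),
          class = "pc_schema_error")
  }
  readr::write_csv(records[schema], path)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    cell = readr::col_character(),
                    animal = readr::col_character(),
                    genotype = readr::col_character(),
                    day = readr::col_integer(),
                    session = readr::col_integer(),
                    metric = readr::col_character(),
                    value = readr::col_double()))
}

#' Write and read single-channel LFP tables
#'
#' Plain CSV with columns `time,voltage`; the sampling rate is recovered
#' from the median inter-sample interval on read.
#'
#' @param lfp An [lfp_recording()].
#' @param path File path.
#' @export
write_lfp_table <- function(lfp, path) {
  readr::write_csv(tibble::tibble(time = (seq_along(lfp$samples) - 1) / lfp$fs,
                                  voltage = lfp$samples), path)
  invisible(path)
}

#' @rdname write_lfp_table
#' @export
read_lfp_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("time", "voltage"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("LFP table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pc_format_error")
  }
  fs <- 1 / median(diff(df$time))
  lfp_recording(df$voltage, fs = fs)
}
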