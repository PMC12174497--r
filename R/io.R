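TRIAL_CSV_COLS <- c("t_ms", "gf_thumb", "gf_index", "lf_thumb", "lf_index",
                    "tx_thumb", "tx_index", "marker_height")

#' Write one trial's channels as CSV
#'
#' One row per force-clock sample, columns `t_ms, gf_thumb, gf_index,
#' lf_thumb, lf_index, tx_thumb, tx_index, marker_height`; the marker
#' channel is linearly interpolated onto the force clock (its native 150 Hz
#' grid does not subdivide the 2 ms force grid). Trial-level timestamps and
#' design labels travel in the manifest, see [write_cohort()].
#'
#' @param trial A `trial_ts`.
#' @param path Output CSV path.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(
    t_ms = trial$time_ms,
    gf_thumb = trial$gf_thumb, gf_index = trial$gf_index,
    lf_thumb = trial$lf_thumb, lf_index = trial$lf_index,
    tx_thumb = trial$tx_thumb, tx_index = trial$tx_index,
    marker_height = align_to_master(trial$kin_time_ms, trial$marker_height,
                                    trial$time_ms))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' One CSV per trial plus a tab-separated manifest (`manifest.tsv`: file,
#' subject, task, start side, schedule labels, timestamps) and the
#' generator's ground-truth planned metrics (`ground_truth.tsv`).
#'
#' @param cohort Result of [simulate_cohort()] (with time series).
#' @param outdir Existing output directory.
#' @export
write_cohort <- function(cohort, outdir) {
  if (is.null(cohort$trials)) {
    stop("write_cohort: cohort has no time series", call. = FALSE)
  }
  if (!dir.exists(outdir)) {
    stop("write_cohort: no such directory: ", outdir, call. = FALSE)
  }
  rows <- lapply(seq_along(cohort$trials), function(k) {
    tr <- cohort$trials[[k]]
    f <- sprintf("trial_s%02d_t%03d.csv", tr$subject %||% 1L,
                 tr$plan$trial_index)
    write_trial_csv(tr, file.path(outdir, f))
    ts <- tr$timestamps
    data.frame(file = f, subject = tr$subject %||% 1L, task = tr$task,
               start_side = tr$plan$start_side %||% NA_character_,
               trial_index = tr$plan$trial_index, side = tr$plan$side,
               phase = tr$plan$phase,
               run_length = tr$plan$run_length,
               position_in_run = tr$plan$position_in_run,
               cue_time = ts$cue_time, go_beep_time = ts$go_beep_time,
               home_release_time = ts$home_release_time,
               button_press_time = ts$button_press_time,
               release_beep_time = ts$release_beep_time)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(outdir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Ingest externally recorded trials
#'
#' Reads a manifest TSV and its per-trial CSVs back into `trial_ts` objects,
#' validating the documented schema. All violations (missing files, missing
#' or misnamed columns, non-numeric data) are collected and reported
#' together.
#'
#' @param manifest_path Path to `manifest.tsv` (columns as written by
#'   [write_cohort()]); trial CSVs are resolved relative to its directory.
#' @param kinematics_rate_hz Declared marker rate recorded in the CSVs'
#'   marker column (stored on the force clock; retained for provenance).
#' @return List of `trial_ts`.
#' @export
ingest_external <- function(manifest_path, kinematics_rate_hz = 150) {
  if (!file.exists(manifest_path)) {
    stop("ingest_external: no such manifest: ", manifest_path,
         call. = FALSE)
  }
  root <- dirname(manifest_path)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "subject", "task", "trial_index", "side", "phase",
            "run_length", "position_in_run", "go_beep_time",
            "home_release_time", "release_beep_time")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("ingest_external: manifest missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  trials <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    path <- file.path(root, row$file)
    if (!file.exists(path)) {
      problems <- c(problems, sprintf("%s: file not found", row$file))
      next
    }
    df <- utils::read.csv(path)
    missc <- setdiff(TRIAL_CSV_COLS, names(df))
    if (length(missc)) {
      problems <- c(problems, sprintf("%s: missing column(s) %s", row$file,
                                      paste(missc, collapse = ", ")))
      next
    }
    bad <- TRIAL_CSV_COLS[!vapply(df[TRIAL_CSV_COLS], is.numeric,
                                  logical(1))]
    if (length(bad)) {
      problems <- c(problems, sprintf("%s: non-numeric column(s) %s",
                                      row$file, paste(bad, collapse = ", ")))
      next
    }
    plan <- tibble::tibble(trial_index = row$trial_index, side = row$side,
                           phase = row$phase, run_length = row$run_length,
                           position_in_run = row$position_in_run,
                           start_side = row$start_side %||% NA_character_)
    ts_obj <- list(cue_time = row$cue_time %||% 0,
                   go_beep_time = row$go_beep_time,
                   home_release_time = row$home_release_time,
                   button_press_time = row$button_press_time %||% NA_real_,
                   release_beep_time = row$release_beep_time)
    tr <- new_trial_ts(df$t_ms, df$gf_thumb, df$gf_index, df$lf_thumb,
                       df$lf_index, df$tx_thumb, df$tx_index,
                       kin_time_ms = df$t_ms,
                       marker_height = df$marker_height,
                       timestamps = ts_obj, scripted = NULL, plan = plan,
                       task = row$task)
    tr$subject <- row$subject
    trials[[k]] <- tr
  }
  if (length(problems)) {
    stop("ingest_external: schema violations:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  trials
}
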