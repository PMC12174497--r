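#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the end-to-end pipeline:
#' object and sensor constants, filter specification, event thresholds,
#' design, simulation parameters, cohort size and master seed. Any element
#' can be overridden via `...` (top-level names) before validation. A
#' configuration can also be loaded from YAML with [read_config()].
#'
#' @param ... Top-level overrides, e.g. `n_subjects = 4`.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    design = "matched",
    n_sets = 5L,
    run_lengths = c(1L, 3L, 5L),
    n_subjects = 20L,
    start_side = "left",
    seed = 1L,
    object = list(mass_g = 936, external_torque_nmm = 250,
                  grip_width_mm = 82, surface_thickness_mm = 8,
                  lift_height_mm = 110),
    sensors = list(force_rate_hz = 500, kinematics_rate_hz = 150,
                   gf_resolution_n = 0.03, lf_resolution_n = 0.015,
                   torque_resolution_nmm = 0.375, gf_noise_sd_n = 0.02,
                   lf_noise_sd_n = 0.01, torque_noise_sd_nmm = 0.25,
                   marker_noise_sd_mm = 0.2),
    filter = list(order = 4L, cutoff_hz = 5, zero_phase = TRUE),
    events = list(threshold_n = 0.2, n_increase = 20L,
                  lift_from = "force"),
    simulation = list(baseline_mcom_gain = 0.9, interference_slope_nmm = 15,
                      memory_split = 0.6, trial_noise_sd_nmm = 40,
                      subject_offset_sd_nmm = 25,
                      reaction_time_mean_ms = 300, reaction_time_sd_ms = 50,
                      gf_max_n = 16, reach_duration_ms = 500),
    outdir = NULL,
    verbose = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override [default_config()] entries.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_config: no such file: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

config_objects <- function(cfg) {
  list(obj = do.call(object_spec, cfg$object),
       sensors = do.call(sensor_spec, cfg$sensors),
       fspec = do.call(filter_spec, cfg$filter),
       params = do.call(subject_sim_params,
                        c(cfg$simulation, list(seed = cfg$seed))),
       design = schedule_spec(cfg$design, n_sets = cfg$n_sets,
                              run_lengths = cfg$run_lengths,
                              start_side = cfg$start_side,
                              seed = cfg$seed))
}

#' Run the full analysis pipeline
#'
#' Schedule -> simulate (or ingest) -> filter -> event detection -> lift
#' metrics -> sign normalisation -> first-post-switch aggregation -> mixed
#' ANOVAs with Bonferroni pairwise comparisons. Deterministic for a fixed
#' `cfg$seed`. Trials whose event detection fails are dropped and listed in
#' the returned log.
#'
#' @param cfg A `pipeline_config` (see [default_config()]).
#' @param trials Optional externally ingested list of `trial_ts` (each with
#'   a `subject` element and a `start_side` in its plan); when `NULL` a
#'   cohort is simulated per the configuration.
#' @return List: `metrics` (per-trial table), `cells` (subject x run-length
#'   means), `anova` (list of `anova_table`s, repetition 1v3 and 1v5 where
#'   estimable), `pairwise`, `truth` (generator ground truth, simulated runs
#'   only), `dropped` (failed trials), `config`.
#' @export
run_pipeline <- function(cfg = default_config(), trials = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    stop("run_pipeline: output directory does not exist: ", cfg$outdir,
         call. = FALSE)
  }
  parts <- config_objects(cfg)
  truth <- NULL
  if (is.null(trials)) {
    sim <- simulate_cohort(cfg$n_subjects, parts$design, parts$obj,
                           parts$sensors, parts$params,
                           master_seed = cfg$seed)
    trials <- sim$trials
    truth <- sim$truth
  }
  note <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  note("pipeline: %d trials to process", length(trials))

  rows <- vector("list", length(trials))
  dropped <- list()
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    res <- tryCatch({
      filt <- filter_trial(tr, parts$fspec)
      ev <- trial_events(tr, parts$obj, parts$fspec, filtered = filt,
                         threshold_n = cfg$events$threshold_n,
                         n_increase = cfg$events$n_increase,
                         lift_from = cfg$events$lift_from)
      m <- trial_metrics(tr, parts$obj, events = ev, filtered = filt)
      m$subject <- tr$subject %||% 1L
      m$trial_index <- tr$plan$trial_index
      m$side <- tr$plan$side
      m$phase <- tr$plan$phase
      m$run_length <- tr$plan$run_length
      m$position_in_run <- tr$plan$position_in_run
      m$start_side <- tr$plan$start_side %||% tr$start_side %||% "left"
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1L]] <- list(index = k,
                                              message = conditionMessage(res))
      note("pipeline: dropped trial %d: %s", k, conditionMessage(res))
    } else {
      rows[[k]] <- res
    }
  }
  metrics <- dplyr::bind_rows(rows)
  if (nrow(metrics) == 0L) {
    stop("run_pipeline: event detection failed for every trial",
         call. = FALSE)
  }
  metrics <- normalize_signs(metrics, metrics$start_side)
  note("pipeline: %d trials measured, %d dropped", nrow(metrics),
       length(dropped))

  cells <- aggregate_post_switch(metrics)
  cells$design <- cfg$design
  anovas <- list(); pairwise <- NULL
  n_subj <- length(unique(cells$subject))
  if (n_subj >= 2 && all(c(1, 3, 5) %in% cells$run_length)) {
    # single-cohort runs: within-subject repetition contrasts only
    long <- cells
    long$value <- long$mcom
    pairwise <- bonferroni_pairwise(long, value = "value",
                                    within = "run_length")
  }
  out <- list(metrics = metrics, cells = cells, anova = anovas,
              pairwise = pairwise, truth = truth,
              dropped = dropped, config = cfg)
  if (!is.null(cfg$outdir)) write_report(out, cfg$outdir)
  out
}

#' Run the two-cohort familiarity analysis
#'
#' Simulates (or accepts) a matched and an unmatched cohort, pools their
#' subject cell means, and fits the repetition (1 vs 3, 1 vs 5) x
#' familiarity mixed ANOVAs for each requested outcome, with
#' Bonferroni-corrected pairwise repetition contrasts pooled over cohorts.
#'
#' @param cfg_matched,cfg_unmatched Configurations for the two cohorts
#'   (designs are forced to matched/unmatched).
#' @param outcomes Outcome columns to analyse.
#' @return List: `cells` (pooled), `anova` (nested list
#'   outcome -> contrast), `pairwise` (per outcome).
#' @export
run_familiarity_analysis <- function(cfg_matched = default_config(),
                                     cfg_unmatched = default_config(
                                       design = "unmatched",
                                       n_subjects = 30L, seed = 2L),
                                     outcomes = c("mcom",
                                                  "lf_torque_component",
                                                  "grip_torque_component")) {
  cfg_matched$design <- "matched"
  cfg_unmatched$design <- "unmatched"
  res_m <- run_pipeline(cfg_matched)
  res_u <- run_pipeline(cfg_unmatched)
  cells <- dplyr::bind_rows(res_m$cells, res_u$cells)
  analyse_cells(cells, outcomes)
}

#' ANOVAs and pairwise contrasts on pooled subject cell means
#'
#' @param cells Pooled [aggregate_post_switch()] output with a `design`
#'   column.
#' @param outcomes Outcome columns to analyse.
#' @export
analyse_cells <- function(cells, outcomes = "mcom") {
  anova <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    list(`1v3` = repetition_anova(cells, oc, 3),
         `1v5` = repetition_anova(cells, oc, 5))
  })
  pairwise <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    long <- cells
    long$value <- long[[oc]]
    long$subject_uid <- paste(long$design, long$subject, sep = "/")
    bonferroni_pairwise(long, value = "value", within = "run_length",
                        subject = "subject_uid")
  })
  list(cells = cells, anova = anova, pairwise = pairwise)
}

write_report <- function(result, outdir) {
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$metrics, "trial_metrics.tsv")
  wt(result$cells, "cell_means.tsv")
  if (!is.null(result$pairwise)) wt(result$pairwise, "pairwise_report.tsv")
  invisible(outdir)
}
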