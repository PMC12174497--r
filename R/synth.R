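#' @importFrom stats rnorm runif uniroot approx coef complete.cases
NULL

logistic <- function(x) 1 / (1 + exp(-x))

# ---- planned per-trial metrics ---------------------------------------------

# Magnitude of the planned compensatory torque for one trial type, before
# noise. Pre-switch trials sit at the practised baseline; the first trial
# after a switch is degraded in proportion to the preceding run length
# (anterograde interference); later post-switch trials recover geometrically.
planned_mcom_magnitude <- function(phase, run_length, position_in_run,
                                   obj, params) {
  base <- params$baseline_mcom_gain * obj$external_torque_nmm
  mag <- rep(base, length(phase))
  novel <- phase == "post_switch" & is.na(run_length)
  mag[novel] <- 0.6 * base
  post <- phase == "post_switch" & !is.na(run_length)
  mag[post] <- base - params$interference_slope_nmm * run_length[post] *
    0.5^(position_in_run[post] - 1)
  mag
}

# profile time constants (ms), shared by the waveform synthesis and the
# scripted-event arithmetic
PROFILE <- list(
  go_beep_ms = 1250,        # go beep follows the side cue by 1.25 s
  release_beep_ms = 3750,   # release beep 2.5 s after the go beep
  gf_tau_ms = 80,           # grip-force logistic rise constant
  load_offset_ms = 350,     # load-ramp midpoint after grasp contact
  load_tau_ms = 60,         # load-ramp rise constant
  settle_offset_ms = 400,   # overshoot-settle midpoint after load midpoint
  settle_tau_ms = 50,       # settle constant (hold converges to weight)
  overshoot = 0.15,         # peak net lift force overshoot fraction
  lift_rise_ms = 200,       # marker rise midpoint after lift onset
  lift_tau_ms = 80,         # marker logistic constant
  release_ramp_mid_ms = 500,  # force ramp-down midpoint after release beep
  release_ramp_tau_ms = 60, # force ramp-down constant
  trial_pad_ms = 1000       # recording continues past the release beep
)

# Offsets (ms, relative to grasp contact) of the scripted load onset
# (net lift force = 0.2 N) and lift onset (net lift force = weight),
# computed on the continuous profile by root finding.
scripted_force_offsets <- function(weight_n) {
  p <- PROFILE
  a <- (1 + p$overshoot) * weight_n
  b <- p$overshoot * weight_n
  net <- function(dt) {
    a * logistic((dt - p$load_offset_ms) / p$load_tau_ms) -
      b * logistic((dt - p$load_offset_ms - p$settle_offset_ms) /
                     p$settle_tau_ms)
  }
  load <- uniroot(function(dt) net(dt) - 0.2,
                  c(p$load_offset_ms - 10 * p$load_tau_ms,
                    p$load_offset_ms), tol = 1e-8)$root
  lift <- uniroot(function(dt) net(dt) - weight_n,
                  c(p$load_offset_ms,
                    p$load_offset_ms + p$settle_offset_ms), tol = 1e-8)$root
  list(load_onset = load, lift_onset = lift, net_fun = net)
}

# Grip force (one digit) on the continuous profile, dt relative to the
# scripted 0.2 N grasp-contact crossing.
gf_profile_fun <- function(gf_max) {
  mid <- PROFILE$gf_tau_ms * log(gf_max / 0.2 - 1)
  function(dt) gf_max * logistic((dt - mid) / PROFILE$gf_tau_ms)
}

#' Planned per-trial lift metrics for a scheduled session
#'
#' Draws the planned compensatory torque of every trial in a schedule (the
#' generator's ground truth) and splits it into its digit-placement and
#' lift-force components via `memory_split`. The torque sign is fixed by the
#' subject's starting side (left-start positive, right-start negative), so a
#' mirrored subject with the same seed is the exact negation.
#'
#' @param schedule Tibble from [build_schedule()].
#' @param obj An [object_spec()].
#' @param params A [subject_sim_params()].
#' @param start_side `"left"` or `"right"`.
#' @return Tibble: schedule columns plus `planned_mcom`, `planned_lf_diff`,
#'   `planned_cop_diff`, `planned_gf_at_lift` (all before sensor noise) and
#'   `rt_ms`.
#' @export
plan_metrics <- function(schedule, obj, params,
                         start_side = c("left", "right")) {
  start_side <- match.arg(start_side)
  if (params$gf_max_n <= 0) {
    stop("plan_metrics: grip force is zero while lift force is nonzero; ",
         "centre of pressure undefined", call. = FALSE)
  }
  n <- nrow(schedule)
  draws <- withr_seed(params$seed, {
    list(offset = rnorm(1, 0, params$subject_offset_sd_nmm),
         trial = rnorm(n, 0, params$trial_noise_sd_nmm),
         rt = pmax(120, rnorm(n, params$reaction_time_mean_ms,
                              params$reaction_time_sd_ms)))
  })
  mag <- planned_mcom_magnitude(schedule$phase, schedule$run_length,
                                schedule$position_in_run, obj, params) +
    draws$offset + draws$trial
  sgn <- if (start_side == "left") 1 else -1
  mcom <- sgn * mag

  weight <- object_weight_n(obj)
  offs <- scripted_force_offsets(weight)
  gf_at_lift <- gf_profile_fun(params$gf_max_n)(offs$lift_onset)
  lf_diff <- (1 - params$memory_split) * mcom * 2 / obj$grip_width_mm
  cop_diff <- params$memory_split * mcom / gf_at_lift

  out <- schedule
  out$start_side <- start_side
  out$planned_mcom <- mcom
  out$planned_lf_diff <- lf_diff
  out$planned_cop_diff <- cop_diff
  out$planned_gf_at_lift <- gf_at_lift
  out$rt_ms <- draws$rt
  out
}

# ---- waveform synthesis -----------------------------------------------------

#' Simulate the raw recording of one trial
#'
#' Synthesises the multichannel recording of a reach-grasp-lift-hold-release
#' trial: logistic grip-force rise after grasp contact, a load ramp whose net
#' lift force crosses the object weight at lift onset and settles on the
#' weight during the hold, per-digit lift forces and frontal-plane torques
#' consistent with the planned compensatory torque, and the object-height
#' marker at the kinematic rate. Digit torque is built as
#' `Tx = COP * GF + LF * thickness`, the algebraic inverse of the
#' centre-of-pressure estimator, so metric recovery is exact at zero noise.
#' Gaussian sensor noise is added and each channel is floor-quantized at its
#' transducer resolution (both disabled by [sensor_spec_ideal()]).
#'
#' @param plan One row of a [build_schedule()] tibble.
#' @param obj An [object_spec()].
#' @param sensors A [sensor_spec()].
#' @param params A [subject_sim_params()].
#' @param planned Optional one-row planned-metrics tibble (from
#'   [plan_metrics()]); if `NULL`, computed for this trial alone.
#' @param start_side Subject starting side (sign convention of planned
#'   torque); used only when `planned` is `NULL`.
#' @param task `"object_use"` or `"reach_to_button"`.
#' @return A `trial_ts` object: force-clock channels `gf_thumb`, `gf_index`,
#'   `lf_thumb`, `lf_index`, `tx_thumb`, `tx_index` on `time_ms`; marker
#'   channel `marker_height` on `kin_time_ms`; `timestamps` (cue, go beep,
#'   home release, button press, release beep); `scripted` ground-truth event
#'   times and planned metrics; `plan`, `task`.
#' @export
simulate_trial <- function(plan, obj, sensors, params, planned = NULL,
                           start_side = c("left", "right"),
                           task = c("object_use", "reach_to_button")) {
  task <- match.arg(task)
  start_side <- match.arg(start_side)
  if (is.null(planned)) {
    planned <- plan_metrics(plan, obj, params, start_side)
  }
  weight <- object_weight_n(obj)
  if (params$gf_max_n <= 0 && weight > 0 && task == "object_use") {
    stop("simulate_trial: grip force is zero while lift force is nonzero; ",
         "centre of pressure undefined", call. = FALSE)
  }
  p <- PROFILE
  rt <- planned$rt_ms
  go <- p$go_beep_ms
  home_release <- go + rt
  contact <- home_release + params$reach_duration_ms
  rel_beep <- p$release_beep_ms
  dur <- rel_beep + p$trial_pad_ms

  dt_force <- 1000 / sensors$force_rate_hz
  t <- seq(0, dur, by = dt_force)
  kin_t <- seq(0, dur, by = 1000 / sensors$kinematics_rate_hz)

  trial_seed <- (params$seed + 7919 * plan$trial_index) %% 2147483647L

  if (task == "reach_to_button") {
    z <- numeric(length(t))
    ts_obj <- list(cue_time = 0, go_beep_time = go,
                   home_release_time = home_release,
                   button_press_time = contact,
                   release_beep_time = rel_beep)
    return(new_trial_ts(t, z, z, z, z, z, z, kin_t,
                        numeric(length(kin_t)), ts_obj,
                        scripted = list(rt_ms = rt,
                                        reach_phase_ms = contact - home_release),
                        plan = plan, task = task))
  }

  offs <- scripted_force_offsets(weight)
  gf_fun <- gf_profile_fun(params$gf_max_n)
  ramp_down <- 1 - logistic((t - (rel_beep + p$release_ramp_mid_ms)) /
                              p$release_ramp_tau_ms)

  gf <- gf_fun(t - contact) * ramp_down
  net <- offs$net_fun(t - contact) * ramp_down
  lf_diff_t <- planned$planned_lf_diff * net / weight
  lf_thumb <- (net + lf_diff_t) / 2
  lf_index <- (net - lf_diff_t) / 2
  cop_thumb <- planned$planned_cop_diff / 2
  cop_index <- -planned$planned_cop_diff / 2
  th <- obj$surface_thickness_mm
  tx_thumb <- cop_thumb * gf + lf_thumb * th
  tx_index <- cop_index * gf + lf_index * th

  lift_time <- contact + offs$lift_onset
  height <- obj$lift_height_mm *
    logistic((kin_t - (lift_time + p$lift_rise_ms)) / p$lift_tau_ms) *
    (1 - logistic((kin_t - (rel_beep + 300)) / p$lift_tau_ms))

  chans <- withr_seed(trial_seed, {
    q <- function(x, sd, res, clamp0 = FALSE) {
      if (sd > 0) x <- x + rnorm(length(x), 0, sd)
      if (clamp0) x <- pmax(x, 0)
      if (res > 0) x <- floor(x / res) * res
      x
    }
    list(gf_thumb = q(gf, sensors$gf_noise_sd_n, sensors$gf_resolution_n,
                      clamp0 = TRUE),
         gf_index = q(gf, sensors$gf_noise_sd_n, sensors$gf_resolution_n,
                      clamp0 = TRUE),
         lf_thumb = q(lf_thumb, sensors$lf_noise_sd_n,
                      sensors$lf_resolution_n),
         lf_index = q(lf_index, sensors$lf_noise_sd_n,
                      sensors$lf_resolution_n),
         tx_thumb = q(tx_thumb, sensors$torque_noise_sd_nmm,
                      sensors$torque_resolution_nmm),
         tx_index = q(tx_index, sensors$torque_noise_sd_nmm,
                      sensors$torque_resolution_nmm),
         marker = q(height, sensors$marker_noise_sd_mm, 0))
  })

  ts_obj <- list(cue_time = 0, go_beep_time = go,
                 home_release_time = home_release,
                 button_press_time = NA_real_,
                 release_beep_time = rel_beep)
  scripted <- list(
    rt_ms = rt,
    reach_phase_ms = contact - home_release,
    grasp_contact_ms = contact,
    load_onset_ms = contact + offs$load_onset,
    lift_onset_ms = lift_time,
    hold_window_ms = c(lift_time + 700, rel_beep - 200),
    planned_mcom = planned$planned_mcom,
    planned_lf_diff = planned$planned_lf_diff,
    planned_cop_diff = planned$planned_cop_diff,
    planned_gf_at_lift = planned$planned_gf_at_lift)
  new_trial_ts(t, chans$gf_thumb, chans$gf_index, chans$lf_thumb,
               chans$lf_index, chans$tx_thumb, chans$tx_index,
               kin_t, chans$marker, ts_obj, scripted, plan, task)
}

new_trial_ts <- function(time_ms, gf_thumb, gf_index, lf_thumb, lf_index,
                         tx_thumb, tx_index, kin_time_ms, marker_height,
                         timestamps, scripted, plan, task) {
  structure(list(time_ms = time_ms, gf_thumb = gf_thumb,
                 gf_index = gf_index, lf_thumb = lf_thumb,
                 lf_index = lf_index, tx_thumb = tx_thumb,
                 tx_index = tx_index, kin_time_ms = kin_time_ms,
                 marker_height = marker_height, timestamps = timestamps,
                 scripted = scripted, plan = plan, task = task),
            class = "trial_ts")
}

#' @export
print.trial_ts <- function(x, ...) {
  cat(sprintf("<trial_ts> %s trial %s (%s, %s), %d force samples @%.0f ms\n",
              x$task, x$plan$trial_index %||% "?",
              x$plan$side %||% "?", x$plan$phase %||% "?",
              length(x$time_ms), diff(x$time_ms[1:2])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Present generator ground truth as an analyzable metrics table
#'
#' Renames the planned per-trial quantities of a [simulate_cohort()] truth
#' table to the measured-metric names (`mcom`, `lf_diff`, `cop_diff`,
#' `gf_mean`, torque components) and sign-normalizes them by starting side,
#' so the group-level statistics can run directly on planned values. Used
#' for statistical calibration studies where synthesising waveforms adds
#' nothing.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param obj The [object_spec()] the cohort was generated with (supplies
#'   the grip width for the torque components).
#' @return Sign-normalized per-trial metrics table with schedule labels.
#' @export
truth_metrics <- function(truth, obj = object_spec()) {
  stopifnot(all(c("planned_mcom", "planned_lf_diff", "planned_cop_diff",
                  "start_side") %in% names(truth)))
  m <- truth
  m$mcom <- m$planned_mcom
  m$lf_diff <- m$planned_lf_diff
  m$cop_diff <- m$planned_cop_diff
  m$gf_mean <- m$planned_gf_at_lift
  m$lf_torque_component <- m$planned_lf_diff * obj$grip_width_mm / 2
  m$grip_torque_component <- m$planned_gf_at_lift * m$planned_cop_diff
  m$sign_normalized <- FALSE
  normalize_signs(m, m$start_side)
}

# ---- cohorts ----------------------------------------------------------------

#' Simulate a cohort of subjects
#'
#' Builds each subject's schedule, draws their planned per-trial metrics, and
#' (optionally) synthesises the full raw recordings. Starting sides are
#' counterbalanced: odd-numbered subjects start on the design's `start_side`,
#' even-numbered subjects on the other side. All randomness derives
#' deterministically from `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param design A [schedule_spec()].
#' @param obj An [object_spec()].
#' @param sensors A [sensor_spec()].
#' @param params A [subject_sim_params()] template (per-subject seeds and
#'   offsets are derived internally).
#' @param master_seed Integer master seed.
#' @param time_series If `FALSE`, only the ground-truth planned metrics are
#'   generated (fast path for statistical calibration studies).
#' @param task Task simulated for every trial.
#' @return List with `truth` (one row per subject x trial: schedule columns,
#'   `subject`, `start_side`, planned metrics, `rt_ms`) and `trials` (list of
#'   `trial_ts`, or `NULL` when `time_series = FALSE`).
#' @export
simulate_cohort <- function(n_subjects, design, obj = object_spec(),
                            sensors = sensor_spec(),
                            params = subject_sim_params(),
                            master_seed = 1L, time_series = TRUE,
                            task = c("object_use", "reach_to_button")) {
  task <- match.arg(task)
  if (n_subjects < 2) {
    stop("simulate_cohort: `n_subjects` must be >= 2", call. = FALSE)
  }
  truth <- vector("list", n_subjects)
  trials <- if (time_series) vector("list", 0L) else NULL
  for (i in seq_len(n_subjects)) {
    subj_seed <- (master_seed + 104729 * i) %% 2147483647L
    side_i <- if (i %% 2 == 1) design$start_side else
      other_side(design$start_side)
    spec_i <- schedule_spec(design$design, design$n_sets, design$run_lengths,
                            start_side = side_i, seed = subj_seed)
    sched <- build_schedule(spec_i)
    sched$start_side <- side_i
    params_i <- params
    params_i$seed <- subj_seed
    pm <- plan_metrics(sched, obj, params_i, side_i)
    pm$subject <- i
    truth[[i]] <- pm
    if (time_series) {
      for (k in seq_len(nrow(sched))) {
        tr <- simulate_trial(sched[k, ], obj, sensors, params_i,
                             planned = pm[k, ], task = task)
        tr$subject <- i
        trials[[length(trials) + 1L]] <- tr
      }
    }
  }
  list(truth = dplyr::bind_rows(truth), trials = trials)
}
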