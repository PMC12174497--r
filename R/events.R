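#' Reaction time of a trial
#'
#' Time from the go beep (movement cue) to release of the home keyboard
#' button.
#'
#' @param trial A `trial_ts`.
#' @return Reaction time in ms.
#' @export
detect_reaction_time <- function(trial) {
  ts <- trial$timestamps
  if (is.null(ts$go_beep_time) || is.null(ts$home_release_time) ||
      is.na(ts$go_beep_time) || is.na(ts$home_release_time)) {
    stop(event_msg(trial, "missing go-beep or home-release timestamp"),
         call. = FALSE)
  }
  rt <- ts$home_release_time - ts$go_beep_time
  if (rt < 0) {
    stop(event_msg(trial, "home release precedes the go beep"),
         call. = FALSE)
  }
  rt
}

#' Grasp contact time
#'
#' First time both digits' grip force exceeds the contact threshold
#' (a grasp requires opposition, so both digits must engage).
#'
#' @param gf_thumb,gf_index Filtered grip-force channels, N.
#' @param time_ms Sample times.
#' @param threshold_n Contact threshold, default 0.2 N.
#' @return Time (ms) of the first sample with both digits above threshold.
#' @export
detect_grasp_contact <- function(gf_thumb, gf_index, time_ms,
                                 threshold_n = 0.2) {
  hit <- which(gf_thumb > threshold_n & gf_index > threshold_n)
  if (length(hit) == 0L) {
    stop(sprintf("detect_grasp_contact: grip force never exceeds %.2f N",
                 threshold_n), call. = FALSE)
  }
  time_ms[hit[1L]]
}

#' Load onset time
#'
#' Earliest sample at which the net lift force exceeds the threshold and
#' then increases strictly over the following `n_increase` consecutive
#' samples (sustained loading, not a transient).
#'
#' @param net_lf Filtered net lift force (thumb + index), N.
#' @param time_ms Sample times.
#' @param threshold_n Threshold, default 0.2 N.
#' @param n_increase Number of consecutive strictly increasing samples
#'   required after the crossing, default 20.
#' @export
detect_load_onset <- function(net_lf, time_ms, threshold_n = 0.2,
                              n_increase = 20L) {
  n <- length(net_lf)
  if (n <= n_increase) {
    stop("detect_load_onset: series shorter than the increase window",
         call. = FALSE)
  }
  steps <- c(0, cumsum(diff(net_lf) > 0))
  idx <- seq_len(n - n_increase)
  # strictly increasing over samples i .. i + n_increase
  sustained <- (steps[idx + n_increase] - steps[idx]) == n_increase
  cand <- idx[net_lf[idx] > threshold_n & sustained]
  if (length(cand) == 0L) {
    stop("detect_load_onset: no sustained loading above threshold",
         call. = FALSE)
  }
  time_ms[cand[1L]]
}

#' Lift onset time
#'
#' First time the net lift force reaches the object weight (the force-based
#' operationalisation of the object leaving the support surface).
#'
#' @param net_lf Filtered net lift force, N.
#' @param time_ms Sample times.
#' @param object_weight_n Object weight, N.
#' @export
detect_lift_onset <- function(net_lf, time_ms, object_weight_n) {
  hit <- which(net_lf >= object_weight_n)
  if (length(hit) == 0L) {
    stop(sprintf(
      "detect_lift_onset: net lift force never reaches the %.2f N weight",
      object_weight_n), call. = FALSE)
  }
  i <- hit[1L]
  if (i == 1L) return(time_ms[1L])
  # locate the crossing between the bracketing samples so the onset is not
  # quantized to the sample grid
  t0 <- time_ms[i - 1L]; t1 <- time_ms[i]
  y0 <- net_lf[i - 1L]; y1 <- net_lf[i]
  if (y1 == y0) return(t1)
  t0 + (object_weight_n - y0) / (y1 - y0) * (t1 - t0)
}

#' Lift onset from the object-height marker
#'
#' Kinematic alternative to [detect_lift_onset()]: first time the marker
#' rises above `threshold_mm` from rest. Coarser than the force-based
#' definition because the marker channel is sampled at 150 Hz.
#'
#' @param marker_height Filtered marker height on the master clock, mm.
#' @param time_ms Sample times.
#' @param threshold_mm Height threshold, default 0.5 mm.
#' @export
detect_lift_onset_kinematic <- function(marker_height, time_ms,
                                        threshold_mm = 0.5) {
  hit <- which(marker_height > threshold_mm)
  if (length(hit) == 0L) {
    stop("detect_lift_onset_kinematic: marker never leaves rest",
         call. = FALSE)
  }
  time_ms[hit[1L]]
}

#' Reach phase of a trial
#'
#' Time from home-button release to the task endpoint: the button press
#' (reach-to-button task) or grasp contact (object-use task).
#'
#' @param trial A `trial_ts`.
#' @param grasp_contact_ms Grasp contact time for object-use trials (from
#'   [detect_grasp_contact()]).
#' @export
detect_reach_phase <- function(trial, grasp_contact_ms = NULL) {
  ts <- trial$timestamps
  if (is.null(ts$home_release_time) || is.na(ts$home_release_time)) {
    stop(event_msg(trial, "missing home-release timestamp"), call. = FALSE)
  }
  endpoint <- if (trial$task == "reach_to_button") {
    ts$button_press_time
  } else {
    grasp_contact_ms
  }
  if (is.null(endpoint) || is.na(endpoint)) {
    stop(event_msg(trial, "missing reach endpoint (button press/grasp)"),
         call. = FALSE)
  }
  endpoint - ts$home_release_time
}

#' Detect all temporal landmarks of one trial
#'
#' Runs the full event chain on filtered channels: reaction time, grasp
#' contact, reach phase, load onset, lift onset and the derived load phase.
#'
#' @param trial A `trial_ts`.
#' @param obj An [object_spec()].
#' @param fspec A [filter_spec()].
#' @param filtered Optional pre-computed [filter_trial()] result.
#' @param threshold_n Force threshold for contact/load onset.
#' @param n_increase Consecutive-increase requirement for load onset.
#' @param lift_from `"force"` (net lift force reaches object weight) or
#'   `"marker"` (object height leaves rest).
#' @return A `trial_events` list: `reaction_time_ms`, `reach_phase_ms`,
#'   `grasp_contact_ms`, `load_onset_ms`, `lift_onset_ms`, `load_phase_ms`.
#' @export
trial_events <- function(trial, obj, fspec = filter_spec(),
                         filtered = NULL, threshold_n = 0.2,
                         n_increase = 20L,
                         lift_from = c("force", "marker")) {
  lift_from <- match.arg(lift_from)
  rt <- detect_reaction_time(trial)
  if (trial$task == "reach_to_button") {
    return(structure(list(reaction_time_ms = rt,
                          reach_phase_ms = detect_reach_phase(trial),
                          grasp_contact_ms = NA_real_,
                          load_onset_ms = NA_real_,
                          lift_onset_ms = NA_real_,
                          load_phase_ms = NA_real_),
                     class = "trial_events"))
  }
  if (is.null(filtered)) filtered <- filter_trial(trial, fspec)
  contact <- detect_grasp_contact(filtered$gf_thumb, filtered$gf_index,
                                  filtered$time_ms, threshold_n)
  load_on <- detect_load_onset(filtered$net_lf, filtered$time_ms,
                               threshold_n, n_increase)
  lift_on <- if (lift_from == "force") {
    detect_lift_onset(filtered$net_lf, filtered$time_ms,
                      object_weight_n(obj))
  } else {
    detect_lift_onset_kinematic(filtered$marker_height, filtered$time_ms)
  }
  ev <- list(reaction_time_ms = rt,
             reach_phase_ms = detect_reach_phase(trial, contact),
             grasp_contact_ms = contact,
             load_onset_ms = load_on,
             lift_onset_ms = lift_on,
             load_phase_ms = lift_on - load_on)
  if (!(contact <= load_on && load_on <= lift_on)) {
    stop(event_msg(trial, "event ordering violated (contact <= load onset <= lift onset)"),
         call. = FALSE)
  }
  structure(ev, class = "trial_events")
}

event_msg <- function(trial, msg) {
  idx <- tryCatch(trial$plan$trial_index, error = function(e) NA)
  sprintf("trial %s: %s", idx %||% "?", msg)
}
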