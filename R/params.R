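#' Physical constants of the T-shaped manipulandum
#'
#' Defaults reproduce the instrumented object used in precision-grip lifting
#' studies of anticipatory torque control: total mass 936 g with a concealed
#' load producing a 250 N mm external torque about the frontal-plane roll
#' axis, 82 mm between the two grip surfaces, 8 mm grip-surface depth, and an
#' 11 cm lift-height target.
#'
#' @param mass_g Object mass in grams.
#' @param external_torque_nmm External torque in N mm.
#' @param grip_width_mm Distance `d` between the grip surfaces, mm.
#' @param surface_thickness_mm Grip-surface depth, mm (moment arm of the
#'   digit lift force about the transducer axis).
#' @param com_side `"left"` or `"right"` centre-of-mass side (label only;
#'   trial-level sides come from the schedule).
#' @param lift_height_mm Target lift height, mm.
#' @return An `object_spec`.
#' @export
object_spec <- function(mass_g = 936, external_torque_nmm = 250,
                        grip_width_mm = 82, surface_thickness_mm = 8,
                        com_side = c("left", "right"),
                        lift_height_mm = 110) {
  com_side <- match.arg(com_side)
  if (mass_g <= 0) stop("object_spec: `mass_g` must be > 0", call. = FALSE)
  if (grip_width_mm <= 0) {
    stop("object_spec: `grip_width_mm` must be > 0", call. = FALSE)
  }
  if (external_torque_nmm < 0) {
    stop("object_spec: `external_torque_nmm` must be >= 0", call. = FALSE)
  }
  structure(list(mass_g = mass_g, external_torque_nmm = external_torque_nmm,
                 grip_width_mm = grip_width_mm,
                 surface_thickness_mm = surface_thickness_mm,
                 com_side = com_side, lift_height_mm = lift_height_mm),
            class = "object_spec")
}

#' Gravitational acceleration used throughout (m/s^2)
#' @keywords internal
GRAVITY <- 9.81

#' Object weight in newtons
#' @param obj An [object_spec()].
#' @export
object_weight_n <- function(obj) obj$mass_g / 1000 * GRAVITY

#' Acquisition characteristics of the force and kinematic channels
#'
#' Defaults match force/torque transducers sampled at 500 Hz with least-
#' significant-bit resolutions of 0.03 N (grip force), 0.015 N (lift force)
#' and 0.375 N mm (torque), and a 150 fps motion-capture channel for object
#' height. Setting a resolution to 0 disables quantization for that channel;
#' setting a noise SD to 0 disables sensor noise.
#'
#' @param force_rate_hz Force/torque sampling rate, Hz.
#' @param kinematics_rate_hz Marker sampling rate, Hz.
#' @param gf_resolution_n,lf_resolution_n,torque_resolution_nmm Quantization
#'   steps per channel (0 = off).
#' @param gf_noise_sd_n,lf_noise_sd_n,torque_noise_sd_nmm,marker_noise_sd_mm
#'   Gaussian sensor-noise SDs per channel (0 = off).
#' @return A `sensor_spec`.
#' @export
sensor_spec <- function(force_rate_hz = 500, kinematics_rate_hz = 150,
                        gf_resolution_n = 0.03, lf_resolution_n = 0.015,
                        torque_resolution_nmm = 0.375,
                        gf_noise_sd_n = 0.02, lf_noise_sd_n = 0.01,
                        torque_noise_sd_nmm = 0.25,
                        marker_noise_sd_mm = 0.2) {
  if (force_rate_hz <= 0 || kinematics_rate_hz <= 0) {
    stop("sensor_spec: sampling rates must be > 0", call. = FALSE)
  }
  res <- c(gf_resolution_n, lf_resolution_n, torque_resolution_nmm)
  if (any(res < 0)) stop("sensor_spec: resolutions must be >= 0",
                         call. = FALSE)
  sds <- c(gf_noise_sd_n, lf_noise_sd_n, torque_noise_sd_nmm,
           marker_noise_sd_mm)
  if (any(sds < 0)) stop("sensor_spec: noise SDs must be >= 0",
                         call. = FALSE)
  structure(list(force_rate_hz = force_rate_hz,
                 kinematics_rate_hz = kinematics_rate_hz,
                 gf_resolution_n = gf_resolution_n,
                 lf_resolution_n = lf_resolution_n,
                 torque_resolution_nmm = torque_resolution_nmm,
                 gf_noise_sd_n = gf_noise_sd_n,
                 lf_noise_sd_n = lf_noise_sd_n,
                 torque_noise_sd_nmm = torque_noise_sd_nmm,
                 marker_noise_sd_mm = marker_noise_sd_mm),
            class = "sensor_spec")
}

#' Convenience: a noiseless, unquantized sensor model
#'
#' Used for parameter-recovery checks where the analytic equilibrium must be
#' reproduced exactly.
#' @param ... Passed on to [sensor_spec()].
#' @export
sensor_spec_ideal <- function(...) {
  sensor_spec(gf_resolution_n = 0, lf_resolution_n = 0,
              torque_resolution_nmm = 0, gf_noise_sd_n = 0,
              lf_noise_sd_n = 0, torque_noise_sd_nmm = 0,
              marker_noise_sd_mm = 0, ...)
}

#' Behavioural parameters of a simulated subject
#'
#' Governs the planned compensatory torque of each trial and how repetition
#' degrades it after a switch. On well-practised pre-switch trials the
#' subject plans `baseline_mcom_gain` of the object's external torque; the
#' first trial after a switch loses `interference_slope_nmm` N mm of planned
#' torque per pre-switch repetition (the anterograde-interference effect the
#' generator plants). `memory_split` partitions the planned torque between
#' the digit-placement component (grip force x centre-of-pressure
#' difference) and the lift-force partitioning component.
#'
#' @param baseline_mcom_gain Fraction of the external torque planned on
#'   pre-switch trials (0..1.2).
#' @param interference_slope_nmm Planned-torque loss per pre-switch
#'   repetition on the first post-switch trial, N mm per trial.
#' @param memory_split Fraction of planned torque realised through digit
#'   placement (the remainder through lift-force partitioning), in `[0, 1]`.
#' @param trial_noise_sd_nmm Trial-to-trial SD of planned torque, N mm.
#' @param subject_offset_sd_nmm Between-subject SD of a constant planned-
#'   torque offset, N mm.
#' @param reaction_time_mean_ms,reaction_time_sd_ms Reaction-time
#'   distribution (go beep to home-button release), ms.
#' @param gf_max_n Grip-force plateau per digit, N.
#' @param reach_duration_ms Mean reach time (home release to grasp contact).
#' @param seed Integer seed for this subject's trial-level randomness.
#' @return A `subject_sim_params`.
#' @export
subject_sim_params <- function(baseline_mcom_gain = 0.9,
                               interference_slope_nmm = 15,
                               memory_split = 0.6,
                               trial_noise_sd_nmm = 40,
                               subject_offset_sd_nmm = 25,
                               reaction_time_mean_ms = 300,
                               reaction_time_sd_ms = 50,
                               gf_max_n = 16,
                               reach_duration_ms = 500,
                               seed = 1L) {
  if (baseline_mcom_gain < 0 || baseline_mcom_gain > 1.2) {
    stop("subject_sim_params: `baseline_mcom_gain` must lie in [0, 1.2]",
         call. = FALSE)
  }
  if (memory_split < 0 || memory_split > 1) {
    stop("subject_sim_params: `memory_split` must lie in [0, 1]",
         call. = FALSE)
  }
  sds <- c(trial_noise_sd_nmm, subject_offset_sd_nmm, reaction_time_sd_ms)
  if (any(sds < 0)) {
    stop("subject_sim_params: SDs must be >= 0", call. = FALSE)
  }
  if (gf_max_n < 0) {
    stop("subject_sim_params: `gf_max_n` must be >= 0", call. = FALSE)
  }
  structure(list(baseline_mcom_gain = baseline_mcom_gain,
                 interference_slope_nmm = interference_slope_nmm,
                 memory_split = memory_split,
                 trial_noise_sd_nmm = trial_noise_sd_nmm,
                 subject_offset_sd_nmm = subject_offset_sd_nmm,
                 reaction_time_mean_ms = reaction_time_mean_ms,
                 reaction_time_sd_ms = reaction_time_sd_ms,
                 gf_max_n = gf_max_n,
                 reach_duration_ms = reach_duration_ms,
                 seed = as.integer(seed)),
            class = "subject_sim_params")
}
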