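#' Mean grip force at lift onset
#'
#' Instantaneous average of the two digits' grip forces,
#' `(GF_thumb + GF_index) / 2`.
#'
#' @param gf_thumb,gf_index Grip forces at lift onset, N (non-negative).
#' @export
compute_gf_mean <- function(gf_thumb, gf_index) {
  if (any(gf_thumb < 0) || any(gf_index < 0)) {
    stop("compute_gf_mean: grip forces must be non-negative", call. = FALSE)
  }
  (gf_thumb + gf_index) / 2
}

#' Lift force difference at lift onset
#'
#' `LF_thumb - LF_index`: positive when the thumb carries more of the load,
#' zero for a symmetric force-sharing pattern.
#'
#' @param lf_thumb,lf_index Digit lift forces, N.
#' @export
compute_lf_diff <- function(lf_thumb, lf_index) lf_thumb - lf_index

#' Digit centre of pressure
#'
#' Point of application of a digit's force on the grip surface relative to
#' the transducer centre:
#' `COP = (Tx - LF * thickness) / GF`, where `Tx` is the digit torque in the
#' frontal plane and `thickness` the grip-surface depth (the lift-force
#' moment arm).
#'
#' @param tx Digit frontal-plane torque, N mm.
#' @param lf Digit lift force, N.
#' @param gf Digit grip force, N (must be > 0).
#' @param thickness_mm Grip-surface depth, mm.
#' @return COP in mm.
#' @export
compute_cop <- function(tx, lf, gf, thickness_mm) {
  if (any(gf <= 0)) {
    stop("compute_cop: centre of pressure undefined for grip force <= 0",
         call. = FALSE)
  }
  (tx - lf * thickness_mm) / gf
}

#' Compensatory torque and its components
#'
#' `M_Com = LF_diff * d/2 + GF_mean * COP_diff`: the anticipatory moment the
#' digits generate at lift onset to counter the object's external torque.
#' The first term is the lift-force partitioning component (moment arm half
#' the grip width `d`), the second the grip-force-by-digit-placement
#' component. Positive values are clockwise moments.
#'
#' @param lf_diff Lift-force difference, N.
#' @param gf_mean Mean grip force, N.
#' @param cop_diff Thumb-minus-index centre-of-pressure difference, mm.
#' @param d_mm Width between grip surfaces, mm (> 0).
#' @return List with `mcom`, `lf_torque_component`, `grip_torque_component`
#'   (N mm); the components sum to `mcom` exactly.
#' @export
compute_mcom <- function(lf_diff, gf_mean, cop_diff, d_mm) {
  if (d_mm <= 0) stop("compute_mcom: `d_mm` must be > 0", call. = FALSE)
  lf_comp <- lf_diff * d_mm / 2
  grip_comp <- gf_mean * cop_diff
  list(mcom = lf_comp + grip_comp,
       lf_torque_component = lf_comp,
       grip_torque_component = grip_comp)
}

#' Grip-lift rate coupling (peak lagged correlation)
#'
#' Cross-correlates the grip-force rate against the lift-force rate over the
#' load phase: both rate channels are linearly interpolated onto a 2.5 ms
#' grid, the grip-force rate is shifted in 2.5 ms steps from 100 ms before
#' to 100 ms after the lift-force rate (81 lags), and the Pearson
#' correlation `r(tau) = cor(GF_rate(t + tau), LF_rate(t))` is evaluated at
#' each shift. The peak signed correlation and its lag are returned; with
#' this convention a grip-force rate *delayed* by `D` ms relative to the
#' lift-force rate peaks at `tau = +D`.
#'
#' @param time_ms Sample times of both rate channels, ms.
#' @param gf_rate,lf_rate Rate-of-change channels (N/s), full trial.
#' @param window_ms Length-2 vector: the data window (load-phase onset to
#'   lift onset) over which the correlation is computed.
#' @param max_lag_ms Half-width of the lag range, default 100 ms.
#' @param lag_step_ms Lag step, default 2.5 ms.
#' @return List with `r` (peak correlation), `lag_ms`, and `lags` (tibble of
#'   all lag/correlation pairs).
#' @export
compute_coupling <- function(time_ms, gf_rate, lf_rate, window_ms,
                             max_lag_ms = 100, lag_step_ms = 2.5) {
  stopifnot(length(window_ms) == 2L, window_ms[2] > window_ms[1])
  grid <- seq(window_ms[1], window_ms[2], by = lag_step_ms)
  if (length(grid) < 3L) {
    stop("compute_coupling: correlation window too short", call. = FALSE)
  }
  lags <- seq(-max_lag_ms, max_lag_ms, by = lag_step_ms)
  lf_w <- approx(time_ms, lf_rate, xout = grid, rule = 2)$y
  if (stats::sd(lf_w) == 0) {
    stop("compute_coupling: zero-variance lift-force rate over the window",
         call. = FALSE)
  }
  r <- vapply(lags, function(tau) {
    gf_w <- approx(time_ms, gf_rate, xout = grid + tau, rule = 2)$y
    if (stats::sd(gf_w) == 0) return(NA_real_)
    stats::cor(gf_w, lf_w)
  }, numeric(1))
  if (all(is.na(r))) {
    stop("compute_coupling: zero-variance grip-force rate at every lag",
         call. = FALSE)
  }
  k <- which.max(r)
  list(r = r[k], lag_ms = lags[k],
       lags = tibble::tibble(lag_ms = lags, r = r))
}

#' Per-trial lift metrics at lift onset
#'
#' Evaluates every lift-onset scalar for one trial: mean grip force,
#' lift-force difference, per-digit centres of pressure and their
#' difference, the compensatory torque with its two components, and the
#' grip-lift rate coupling over the load phase. Values are taken at the
#' detected lift-onset sample of the filtered channels.
#'
#' @param trial A `trial_ts`.
#' @param obj An [object_spec()].
#' @param events A `trial_events` (from [trial_events()]); computed if
#'   `NULL`.
#' @param fspec A [filter_spec()].
#' @param filtered Optional pre-computed [filter_trial()] result.
#' @return A one-row tibble (class keeps a `sign_normalized` column, `FALSE`
#'   here): `gf_mean`, `lf_diff`, `cop_thumb`, `cop_index`, `cop_diff`,
#'   `mcom`, `lf_torque_component`, `grip_torque_component`, `coupling_r`,
#'   `coupling_lag_ms`, plus the event times.
#' @export
trial_metrics <- function(trial, obj, events = NULL,
                          fspec = filter_spec(), filtered = NULL) {
  if (is.null(filtered)) filtered <- filter_trial(trial, fspec)
  if (is.null(events)) {
    events <- trial_events(trial, obj, fspec, filtered = filtered)
  }
  # instantaneous channel values at the detected lift onset (linearly
  # interpolated; the onset is located between samples)
  at_lift <- function(x) {
    approx(filtered$time_ms, x, xout = events$lift_onset_ms, rule = 2)$y
  }
  gf_t <- at_lift(filtered$gf_thumb); gf_i <- at_lift(filtered$gf_index)
  lf_t <- at_lift(filtered$lf_thumb); lf_i <- at_lift(filtered$lf_index)
  gf_mean <- compute_gf_mean(gf_t, gf_i)
  lf_diff <- compute_lf_diff(lf_t, lf_i)
  cop_t <- compute_cop(at_lift(filtered$tx_thumb), lf_t, gf_t,
                       obj$surface_thickness_mm)
  cop_i <- compute_cop(at_lift(filtered$tx_index), lf_i, gf_i,
                       obj$surface_thickness_mm)
  cop_diff <- cop_t - cop_i
  mc <- compute_mcom(lf_diff, gf_mean, cop_diff, obj$grip_width_mm)
  rate <- filtered$rate_hz
  gf_rate <- rate_of_change((filtered$gf_thumb + filtered$gf_index) / 2,
                            rate)
  lf_rate <- rate_of_change(filtered$net_lf, rate)
  cpl <- compute_coupling(filtered$time_ms, gf_rate, lf_rate,
                          c(events$load_onset_ms, events$lift_onset_ms))
  tibble::tibble(
    gf_mean = gf_mean, lf_diff = lf_diff,
    cop_thumb = cop_t, cop_index = cop_i, cop_diff = cop_diff,
    mcom = mc$mcom,
    lf_torque_component = mc$lf_torque_component,
    grip_torque_component = mc$grip_torque_component,
    coupling_r = cpl$r, coupling_lag_ms = cpl$lag_ms,
    reaction_time_ms = events$reaction_time_ms,
    reach_phase_ms = events$reach_phase_ms,
    load_phase_ms = events$load_phase_ms,
    lift_onset_ms = events$lift_onset_ms,
    sign_normalized = FALSE)
}

#' Normalise metric signs across starting sides
#'
#' Subjects who begin the session with the centre of mass on the right
#' generate mirror-image torques; their `mcom`, `lf_diff`, `cop_diff` (and
#' both torque components and per-digit COPs) are multiplied by -1 so that
#' successful anticipatory torque is positive for every subject. Grip force
#' and coupling are side-invariant and unchanged. Refuses to normalise
#' twice.
#'
#' @param metrics Tibble of trial metrics containing a `sign_normalized`
#'   column (e.g. rows from [trial_metrics()]).
#' @param subject_start_side `"left"` or `"right"`; may be a vector matching
#'   the rows of `metrics`.
#' @export
normalize_signs <- function(metrics, subject_start_side) {
  if (!"sign_normalized" %in% names(metrics)) {
    stop("normalize_signs: metrics lack a `sign_normalized` column",
         call. = FALSE)
  }
  if (any(metrics$sign_normalized)) {
    stop("normalize_signs: metrics already sign-normalized", call. = FALSE)
  }
  if (!all(subject_start_side %in% c("left", "right"))) {
    stop("normalize_signs: `subject_start_side` must be left/right",
         call. = FALSE)
  }
  sgn <- ifelse(subject_start_side == "right", -1, 1)
  for (col in intersect(c("mcom", "lf_diff", "cop_diff", "cop_thumb",
                          "cop_index", "lf_torque_component",
                          "grip_torque_component"), names(metrics))) {
    metrics[[col]] <- metrics[[col]] * sgn
  }
  metrics$sign_normalized <- TRUE
  metrics
}
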