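#' Low-pass filter specification
#'
#' Default: fourth-order low-pass Butterworth with a 5 Hz cutoff, applied
#' forward and backward (zero phase) so detected event times are not
#' lag-shifted. Zero-phase application doubles the effective attenuation
#' order.
#'
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist rate of
#'   the channel it is applied to.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or forward
#'   only.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 5, zero_phase = TRUE) {
  if (order < 1 || order != round(order)) {
    stop("filter_spec: `order` must be a positive integer", call. = FALSE)
  }
  if (cutoff_hz <= 0) {
    stop("filter_spec: `cutoff_hz` must be > 0", call. = FALSE)
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

#' Low-pass filter a uniformly sampled channel
#'
#' Butterworth low-pass with unit DC gain; output length equals input length.
#'
#' @param series Numeric vector, uniformly sampled.
#' @param spec A [filter_spec()].
#' @param rate_hz Sampling rate of `series`.
#' @return Filtered numeric vector.
#' @export
lowpass <- function(series, spec = filter_spec(), rate_hz) {
  min_len <- 3L * spec$order + 1L
  if (length(series) < min_len) {
    stop(sprintf("lowpass: series too short (%d samples; need >= %d)",
                 length(series), min_len), call. = FALSE)
  }
  if (spec$cutoff_hz >= rate_hz / 2) {
    stop("lowpass: cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (rate_hz / 2),
                       type = "low")
  if (spec$zero_phase) {
    filtfilt_ss(bf$b, bf$a, series)
  } else {
    as.numeric(signal::filter(bf, series))
  }
}

# One forward IIR pass started in steady state for an input held at x[1]
# (held past inputs and outputs), removing the zero-state start-up
# transient for signals that begin near rest or any constant level.
iir_steady <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init = rep(x[1] * dc, length(a) - 1L)))
}

# Zero-phase filtering: odd-reflection padding plus steady-state starts,
# forward then backward (the edge handling of standard filtfilt
# implementations).
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 8L)
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(front, x, back)
  y <- iir_steady(b, a, ext)
  y <- rev(iir_steady(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Rate of change of a channel (units per second)
#'
#' Central differences on interior samples, one-sided at the endpoints.
#'
#' @param series Numeric vector (filter first).
#' @param rate_hz Sampling rate.
#' @export
rate_of_change <- function(series, rate_hz) {
  n <- length(series)
  if (n < 3L) stop("rate_of_change: need at least 3 samples", call. = FALSE)
  dt <- 1 / rate_hz
  d <- numeric(n)
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * dt)
  d[1] <- (series[2] - series[1]) / dt
  d[n] <- (series[n] - series[n - 1]) / dt
  d
}

#' Interpolate a kinematic channel onto the force master clock
#'
#' Linear interpolation; times outside the kinematic range are held at the
#' nearest sample.
#'
#' @param kin_time_ms,kin_values Kinematic sample times (ms) and values.
#' @param master_time_ms Force-clock sample times (ms).
#' @export
align_to_master <- function(kin_time_ms, kin_values, master_time_ms) {
  if (length(kin_time_ms) == 0L || length(kin_values) == 0L) {
    stop("align_to_master: empty kinematic input", call. = FALSE)
  }
  approx(kin_time_ms, kin_values, xout = master_time_ms, rule = 2)$y
}

# Filter every force channel of a trial (and the marker channel, aligned to
# the master clock) in one pass; returns a list of filtered channels.
filter_trial <- function(trial, spec = filter_spec()) {
  rate <- 1000 / diff(trial$time_ms[1:2])
  f <- function(x) lowpass(x, spec, rate)
  marker_master <- align_to_master(trial$kin_time_ms, trial$marker_height,
                                   trial$time_ms)
  list(time_ms = trial$time_ms,
       gf_thumb = f(trial$gf_thumb), gf_index = f(trial$gf_index),
       lf_thumb = f(trial$lf_thumb), lf_index = f(trial$lf_index),
       tx_thumb = f(trial$tx_thumb), tx_index = f(trial$tx_index),
       net_lf = f(trial$lf_thumb + trial$lf_index),
       marker_height = f(marker_master),
       rate_hz = rate)
}
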