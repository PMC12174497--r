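make_trial_stub <- function(go = 0, release = 310, button = NA,
                            task = "reach_to_button") {
  structure(list(timestamps = list(go_beep_time = go,
                                   home_release_time = release,
                                   button_press_time = button),
                 plan = tibble::tibble(trial_index = 1L),
                 task = task),
            class = "trial_ts")
}

test_that("reaction time is the go-beep to home-release interval and rejects impossible orders", {
  expect_equal(detect_reaction_time(make_trial_stub(0, 310)), 310)
  expect_error(detect_reaction_time(make_trial_stub(500, 200)),
               "precedes")
  expect_error(detect_reaction_time(make_trial_stub(NA, 200)), "missing")
})

test_that("grasp contact requires both digits above threshold", {
  t <- seq(0, 2000, by = 2)
  ramp <- pmax(0, (t - 880) / 99)  # crosses 0.2 N just before 900 ms
  expect_equal(detect_grasp_contact(ramp, ramp, t), 900)
  # index finger never engages: no grasp
  expect_error(detect_grasp_contact(ramp, rep(0, length(t)), t),
               "never exceeds")
  # late index contact delays the detected grasp
  late <- pmax(0, (t - 1180) / 99)
  expect_equal(detect_grasp_contact(ramp, late, t), 1200)
})

test_that("load onset takes the earliest sustained crossing, skipping transients", {
  t <- seq(0, 4000, by = 2)
  ramp <- 0.01 * (seq_along(t) - 400)  # crosses 0.2 N around sample 421
  naive <- which(ramp > 0.2)[1]
  expect_equal(detect_load_onset(ramp, t), t[naive])

  # a crossing followed by a dip within the 20-sample window must be skipped
  x <- rep(0.0, 900)
  x[100:110] <- seq(0, 0.5, length.out = 11)   # rises above 0.2 ...
  x[111:200] <- seq(0.5, 0.05, length.out = 90) # ... dips within 20 samples
  x[300:900] <- seq(0.05, 6, length.out = 601)  # clean sustained rise
  tt <- seq_along(x) * 2
  got <- detect_load_onset(x, tt)
  # independent oracle: direct double-loop scan
  oracle <- NA
  for (i in seq_len(length(x) - 20)) {
    if (x[i] > 0.2 && all(diff(x[i:(i + 20)]) > 0)) { oracle <- tt[i]; break }
  }
  expect_equal(got, oracle)
  expect_gt(got, 400)  # the transient at ~200-300 ms is rejected

  expect_error(detect_load_onset(rep(0.1, 500), seq_len(500) * 2),
               "no sustained loading")
})

test_that("lift onset is the first crossing of the object weight", {
  t <- seq(0, 3000, by = 2)
  w <- object_weight_n(object_spec())  # 0.936 kg x 9.81
  expect_equal(w, 9.18216, tolerance = 1e-6)
  net <- w * t / 1500  # linear ramp reaching the weight at 1500 ms
  expect_equal(detect_lift_onset(net, t, w), 1500)
  expect_error(detect_lift_onset(0.9 * w * t / max(t), t, w),
               "never reaches")
})

test_that("reach phase ends at the button press or at grasp contact by task", {
  tr <- make_trial_stub(0, 500, button = 1100)
  expect_equal(detect_reach_phase(tr), 600)
  tr2 <- make_trial_stub(0, 500, task = "object_use")
  expect_equal(detect_reach_phase(tr2, grasp_contact_ms = 1050), 550)
  expect_error(detect_reach_phase(tr2), "endpoint")
})

test_that("zero-noise synthetic trials round-trip every event within one sample", {
  tr <- equilibrium_trial()
  ev <- trial_events(tr, object_spec())
  tol <- one_force_sample_ms()
  expect_lt(abs(ev$grasp_contact_ms - tr$scripted$grasp_contact_ms), tol)
  expect_lt(abs(ev$load_onset_ms - tr$scripted$load_onset_ms), tol)
  expect_lt(abs(ev$lift_onset_ms - tr$scripted$lift_onset_ms), tol)
  expect_equal(ev$reaction_time_ms, tr$scripted$rt_ms)
  expect_equal(ev$reach_phase_ms, tr$scripted$reach_phase_ms)
  expect_equal(ev$load_phase_ms, ev$lift_onset_ms - ev$load_onset_ms)
  # kinematic fallback agrees with the force definition to marker precision
  ev_kin <- trial_events(tr, object_spec(), lift_from = "marker")
  expect_lt(abs(ev_kin$lift_onset_ms - ev$lift_onset_ms), 300)
})

test_that("detection is stable under sub-resolution sensor noise", {
  tr <- equilibrium_trial()
  ev0 <- trial_events(tr, object_spec())
  sensors <- sensor_spec()
  tr2 <- tr
  set.seed(99)
  half <- function(res) res / 2 * 0.9
  jit <- function(x, res) x + runif(length(x), -half(res), half(res))
  tr2$gf_thumb <- jit(tr2$gf_thumb, sensors$gf_resolution_n)
  tr2$gf_index <- jit(tr2$gf_index, sensors$gf_resolution_n)
  tr2$lf_thumb <- jit(tr2$lf_thumb, sensors$lf_resolution_n)
  tr2$lf_index <- jit(tr2$lf_index, sensors$lf_resolution_n)
  ev2 <- trial_events(tr2, object_spec())
  tol <- one_force_sample_ms()
  expect_lte(abs(ev2$grasp_contact_ms - ev0$grasp_contact_ms), tol)
  expect_lte(abs(ev2$load_onset_ms - ev0$load_onset_ms), tol)
  expect_lte(abs(ev2$lift_onset_ms - ev0$lift_onset_ms), tol)
})

test_that("simulated reaction times recover the generator mean", {
  cohort <- simulate_cohort(6, schedule_spec("matched"),
                            time_series = FALSE, master_seed = 3L)
  rt <- cohort$truth$rt_ms
  se <- sd(rt) / sqrt(length(rt))
  expect_lt(abs(mean(rt) - 300), 3 * se)
})
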